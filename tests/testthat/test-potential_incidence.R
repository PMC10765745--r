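test_that("pattern proportions are the observed pattern frequencies", {
  cov <- data.frame(
    X1 = rep(c(0, 0, 1, 1), times = c(42, 28, 18, 12)),
    X2 = rep(c(0, 1, 0, 1), times = c(42, 28, 18, 12)))
  s <- crsample(time = rep(1, 100), status = rep(1, 100),
                cause = rep(1, 100), covariates = cov)
  w <- pattern_proportions(s, c("X1", "X2"))
  expect_equal(sum(w), 1)
  expect_equal(as.numeric(w[c("X1=0,X2=0", "X1=0,X2=1", "X1=1,X2=0", "X1=1,X2=1")]),
               c(0.42, 0.28, 0.18, 0.12))
  # single-pattern sample
  w1 <- pattern_proportions(s[s$X1 == 1 & s$X2 == 1, ], c("X1", "X2"))
  expect_equal(as.numeric(w1), 1)
  expect_error(pattern_proportions(s, "nope"), "unknown covariate")
  # proportions sum to 1 on random samples
  for (seed in 1:3) {
    d <- simulate_dataset(scenario_registry()[["4"]], 100, seed = seed)
    expect_equal(sum(pattern_proportions(d, c("X1", "X2"))), 1)
  }
})

test_that("weighted average survival is a pointwise convex combination", {
  f <- step_function(c(0.5, 1), c(0.8, 0.4), 1)
  g <- step_function(c(0.7, 1.5), c(0.6, 0.2), 1)
  curves <- list(a = f, b = g, c = f, d = g)
  w <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  avg <- weighted_average_survival(curves, w)
  tt <- c(0, 0.5, 0.7, 1, 1.5, 3)
  expect_equal(step_eval(avg, tt),
               0.6 * step_eval(f, tt) + 0.4 * step_eval(g, tt))
  # identical curves in all strata reproduce that curve
  same <- weighted_average_survival(list(a = f, b = f), c(a = 0.5, b = 0.5))
  expect_equal(step_eval(same, tt), step_eval(f, tt))
  # degenerate weights pick out one stratum
  one <- weighted_average_survival(curves, c(a = 1, b = 0, c = 0, d = 0))
  expect_equal(step_eval(one, tt), step_eval(f, tt))
  expect_error(weighted_average_survival(curves[1:2], w), "pattern")
  expect_error(weighted_average_survival(curves, c(a = 0.5, b = 0.2)), "sum to 1")
})

test_that("with a single pattern the weighted KM equals the naive KM", {
  d <- simulated_censored(n = 150, seed = 7)
  df <- as.data.frame(d); df$G <- 1
  d2 <- as_crsample(df)
  sk <- stratified_km(d2, CAUSE_AE, "G")
  avg <- weighted_average_survival(sk, pattern_proportions(d2, "G"))
  nk <- naive_km_incidence(build_life_table(d), CAUSE_AE)
  expect_equal(step_eval(avg, nk$times), 1 - nk$values, tolerance = 1e-12)
})

test_that("IPCW weights reduce to 1 without competing events and are monotone", {
  pure <- crsample(time = c(1, 2, 3, 4), status = c(1, 1, 0, 1),
                   cause = c(1, 1, NA, 1),
                   covariates = data.frame(X1 = c(0, 1, 0, 1), X2 = c(1, 0, 0, 1)))
  w <- ipcw_weights(pure, "cox", c("X1", "X2"))
  expect_true(all(w$W == 1))
  ik <- ipcw_km_incidence(pure, w)
  nk <- naive_km_incidence(build_life_table(pure), CAUSE_AE)
  expect_equal(ik$values, nk$values)
  # with competing events: weights >= 1, non-decreasing per subject
  d <- simulate_dataset(scenario_registry()[["4"]], 500, seed = 8)
  for (wm in c("cox", "km")) {
    w <- ipcw_weights(d, wm, c("X1", "X2"))
    expect_true(all(w$W >= 1 - 1e-12))
    # monotone per subject (a stratum whose competing-cause survival reaches
    # 0 yields infinite trailing weights; cap before differencing)
    expect_true(all(apply(pmin(w$W, 1e12), 1,
                          function(r) all(diff(r) >= -1e-9))))
  }
})

test_that("Cox-based weights recover the inverse competing-cause survival", {
  s4 <- scenario_registry()[["4"]]
  d <- simulate_dataset(s4, 5000, seed = 9)
  w <- ipcw_weights(d, "cox", c("X1", "X2"))
  j <- which.min(abs(w$times - 0.2))
  i <- which(d$X1 == 0 & d$X2 == 0)[1]
  # stratum (0,0): S_RL = exp(-2t), so the weight near t = 0.2 is ~ e^0.4
  expect_equal(w$W[i, j], exp(2 * w$times[j]), tolerance = 0.05)
})

test_that("the weighted product-limit estimate matches its definition", {
  # hand-computable case: 4 subjects, constant weights per subject
  d <- crsample(time = c(1, 2, 3, 4), status = c(1, 1, 1, 1),
                cause = c(1, 2, 1, 1),
                covariates = data.frame(X1 = c(0, 0, 1, 1), X2 = c(0, 0, 0, 0)))
  w <- structure(list(times = c(1, 3, 4),
                      W = matrix(c(1, 1, 1,
                                   1, 1, 1,
                                   2, 2, 2,
                                   1, 3, 3), nrow = 4, byrow = TRUE),
                      model = list(type = "unit"), cause = 1, n_truncated = 0L),
                 class = "ipc_weights")
  ik <- ipcw_km_incidence(d, w)
  # hazards: t=1: 1/(1+1+2+1); t=3: 2/(2+3); t=4: 3/3
  s_exp <- cumprod(1 - c(1 / 5, 2 / 5, 1))
  expect_equal(ik$values, 1 - s_exp, tolerance = 1e-12)
})

test_that("weight truncation caps extreme weights and is reported", {
  # single stratum with competing events at 0.5, 1, 1.5 and an AE at 2:
  # S_RL(2-) = 3/4 * 2/3 * 1/2 = 1/4, so the untruncated weight at the AE
  # time is 4
  d <- crsample(time = c(0.5, 1, 1.5, 2), status = rep(1, 4),
                cause = c(2, 2, 2, 1),
                covariates = data.frame(X1 = c(0, 0, 0, 0)))
  w0 <- ipcw_weights(d, "km", "X1")
  expect_equal(w0$W[4, 1], 4)
  expect_message(w <- ipcw_weights(d, "km", "X1", truncate = 3), "truncated")
  expect_true(all(w$W <= 3))
  expect_gt(w$n_truncated, 0)
  # interactions have no meaning for the stratified weight model
  expect_error(ipcw_weights(d, "km", c("X1", "X1:X1")), "interaction")
})

test_that("large-sample weighted KM approaches the closed-form incidence", {
  s4 <- scenario_registry()[["4"]]
  d <- simulate_dataset(s4, 20000, seed = 10)
  sk <- stratified_km(d, CAUSE_AE, c("X1", "X2"))
  avg <- weighted_average_survival(sk, pattern_proportions(d, c("X1", "X2")))
  expect_equal(step_eval(avg, 0.2), potential_survival(s4, 0.2), tolerance = 0.02)
  expect_equal(step_eval(avg, 0.3), potential_survival(s4, 0.3), tolerance = 0.02)
})
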