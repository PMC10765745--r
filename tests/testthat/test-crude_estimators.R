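test_that("the worked-example estimator columns are reproduced", {
  lt <- build_life_table(table_one_sample())
  tp <- table_one_printed
  km <- overall_km(lt)
  h <- cause_specific_hazard(lt, CAUSE_AE)
  ci <- aj_crude_incidence(lt, CAUSE_AE)
  an <- aalen_nelson(lt, CAUSE_AE)
  nk <- naive_km_incidence(lt, CAUSE_AE)
  # per-row columns agree with the printed cells exactly at 3 decimals
  expect_equal(round(km$values, 3), tp$S)
  expect_equal(round(h$hazard, 3), tp$h)
  expect_equal(round(step_left_limit(km, lt$time) * h$hazard, 3), tp$hS)
  # cumulative columns: the printed table accumulated the rounded per-row
  # values, so exact computation agrees within one unit in the last digit
  expect_true(all(abs(ci$values - tp$CI) <= 1.5e-3))
  expect_true(all(abs(an$values - tp$AN) <= 1.5e-3))
  expect_true(all(abs(nk$values - tp$KM) <= 1.5e-3))
  # cells that do round exactly
  expect_equal(round(step_eval(km, 0.1), 3), 0.383)
  expect_equal(round(step_eval(ci, 0.4), 3), 0.237)
  expect_equal(round(step_eval(an, 2.1), 3), 2.189)
  expect_equal(round(step_eval(nk, 1.3), 3), 0.730)
  expect_equal(step_eval(km, 2.1), 0)
  expect_equal(step_eval(nk, 2.1), 1)
})

test_that("crude proportion matches the worked examples", {
  expect_equal(round(crude_proportion(table_one_sample()), 2), 0.27)
  # osteonecrosis cohort margins: 99 AEs among 3691 children
  on <- crsample(time = rep(1, 3691),
                 status = c(rep(1, 99), rep(0, 3592)),
                 cause = c(rep(1, 99), rep(NA, 3592)))
  expect_equal(round(crude_proportion(on), 3), 0.027)
  # all failures competing -> zero AE proportion
  s <- crsample(time = 1:3, status = rep(1, 3), cause = rep(2, 3))
  expect_equal(crude_proportion(s, CAUSE_AE), 0)
  expect_equal(crude_proportion(s, CAUSE_COMPETING), 1)
})

test_that("epidemiological rate matches the worked examples", {
  r <- ae_rate(table_one_sample())
  expect_equal(r, 80 / 56.4)
  expect_equal(round(r / 12, 2), 0.12)   # per person-month
  # osteonecrosis cohort: 99 events over 19940.96 person-years
  n <- 3691
  tfu <- c(rep(1, n - 1), 19940.96 - (n - 1))
  on <- crsample(time = tfu, status = c(rep(1, 99), rep(0, n - 99)),
                 cause = c(rep(1, 99), rep(NA, n - 99)))
  expect_equal(round(ae_rate(on), 3), 0.005)
  # single subject failing at t = 2
  expect_equal(ae_rate(crsample(2, 1, 1)), 0.5)
  expect_error(ae_rate(crsample(0, 0)), "positive")
})

test_that("overall KM agrees with survival::survfit", {
  d <- simulated_censored(n = 400, seed = 2)
  km <- overall_km(build_life_table(d))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = as.data.frame(d))
  expect_equal(step_eval(km, fit$time), fit$surv, tolerance = 1e-12)
})

test_that("Aalen-Johansen incidence agrees with cmprsk::cuminc", {
  d <- simulated_censored(n = 400, seed = 3)
  ci1 <- aj_crude_incidence(build_life_table(d), CAUSE_AE)
  ci2 <- aj_crude_incidence(build_life_table(d), CAUSE_COMPETING)
  fstatus <- ifelse(d$status == 1, d$cause, 0)
  cum <- cmprsk::cuminc(d$time, fstatus)
  at <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  tp <- cmprsk::timepoints(cum, at)$est
  expect_equal(step_eval(ci1, at), unname(tp["1 1", ]), tolerance = 1e-12)
  expect_equal(step_eval(ci2, at), unname(tp["1 2", ]), tolerance = 1e-12)
})

test_that("naive KM incidence equals survfit censoring the competing cause", {
  d <- simulated_censored(n = 400, seed = 4)
  nk <- naive_km_incidence(build_life_table(d), CAUSE_AE)
  df <- as.data.frame(d)
  df$ev <- as.integer(df$status == 1 & df$cause == CAUSE_AE)
  fit <- survival::survfit(survival::Surv(time, ev) ~ 1, data = df)
  expect_equal(step_eval(nk, fit$time), 1 - fit$surv, tolerance = 1e-12)
})

test_that("degenerate life tables give the expected constants", {
  none <- build_life_table(crsample(time = c(1, 2), status = c(0, 0)))
  expect_equal(step_eval(overall_km(none), c(0, 5)), c(1, 1))
  expect_equal(step_eval(aalen_nelson(none, CAUSE_AE), 5), 0)
  one <- build_life_table(crsample(1, 1, 1))
  expect_equal(cause_specific_hazard(one, CAUSE_AE)$hazard, 1)
  # two subjects: AE at 1, censored at 2
  two <- build_life_table(crsample(c(1, 2), c(1, 0), c(1, NA)))
  expect_equal(step_eval(aj_crude_incidence(two, CAUSE_AE), 1), 0.5)
  # without competing events or censoring AJ and naive KM coincide
  pure <- build_life_table(crsample(1:5, rep(1, 5), rep(1, 5)))
  expect_equal(aj_crude_incidence(pure, CAUSE_AE)$values,
               naive_km_incidence(pure, CAUSE_AE)$values)
})

test_that("incidence decomposition and estimator ordering hold on any sample", {
  samples <- c(list(table_one_sample()),
               lapply(1:4, function(s) simulated_censored(n = 200, seed = s)))
  for (d in samples) {
    lt <- build_life_table(d)
    km <- overall_km(lt)
    ci_ae <- aj_crude_incidence(lt, CAUSE_AE)
    ci_rl <- aj_crude_incidence(lt, CAUSE_COMPETING)
    an <- aalen_nelson(lt, CAUSE_AE)
    nk <- naive_km_incidence(lt, CAUSE_AE)
    tt <- c(lt$time, max(lt$time) + 1)
    expect_equal(step_eval(ci_ae, tt) + step_eval(ci_rl, tt),
                 1 - step_eval(km, tt), tolerance = 1e-12)
    v_ci <- step_eval(ci_ae, tt); v_an <- step_eval(an, tt)
    v_nk <- step_eval(nk, tt)
    expect_true(all(v_ci <= v_nk + 1e-12))
    expect_true(all(1 - exp(-v_an) <= v_nk + 1e-12))
    expect_true(all(v_nk <= v_an + 1e-12))
  }
  # once the competing cause has depleted the risk sets the crude incidence
  # also drops below the exponential transform of the cumulative hazard, as
  # in the worked example at its last failure time
  lt1 <- build_life_table(table_one_sample())
  v <- c(step_eval(aj_crude_incidence(lt1, CAUSE_AE), 2.1),
         1 - exp(-step_eval(aalen_nelson(lt1, CAUSE_AE), 2.1)),
         step_eval(naive_km_incidence(lt1, CAUSE_AE), 2.1),
         step_eval(aalen_nelson(lt1, CAUSE_AE), 2.1))
  expect_equal(round(v, 3), c(0.267, 0.888, 1.000, 2.189))
  expect_true(all(diff(v) >= 0))
})

test_that("the rate is the constant-hazard ML estimate of the AE rate", {
  # single stratum: the rate converges to the generative AE hazard
  sc <- scenario(0, 0, c(1.5, 1, 1, 1), c(2.5, 1, 1, 1))
  d <- simulate_dataset(sc, n = 40000, seed = 9)
  r <- ae_rate(d, CAUSE_AE)
  n_ev <- sum(d$cause == CAUSE_AE)
  expect_lt(abs(r - 1.5), 3 * 1.5 / sqrt(n_ev))
})
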