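# ---- estimator registry -----------------------------------------------
#
# Each study estimator maps a simulated sample to a potential-incidence
# step function for the AE cause.  Ids follow the covariate set used:
# "_X1" adjusts for X1 only (X2 treated as unobserved), "_X1X2" for both,
# "_int" adds the X1:X2 interaction to the model terms.

wavg_km_incidence <- function(x, strata) {
  curves <- stratified_km(x, cause = CAUSE_AE, strata = strata)
  w <- pattern_proportions(x, strata)
  s <- weighted_average_survival(curves, w)
  step_function(s$times, 1 - s$values, 1 - s$initial)
}

wavg_cox_incidence <- function(x, terms) {
  m <- fit_cox(x, cause = CAUSE_AE, terms = terms)
  bases <- term_bases(terms)
  w <- pattern_proportions(x, bases)
  pats <- attr(w, "patterns")
  curves <- lapply(seq_len(nrow(pats)), function(i)
    predict_survival(m, as.list(pats[i, , drop = FALSE])))
  names(curves) <- names(w)
  s <- weighted_average_survival(curves, w)
  step_function(s$times, 1 - s$values, 1 - s$initial)
}

ipcw_incidence <- function(x, terms) {
  w <- ipcw_weights(x, weight_model = "cox", terms = terms, cause = CAUSE_AE)
  ipcw_km_incidence(x, w, cause = CAUSE_AE)
}

.estimator_registry <- list(
  naive_km = function(x) naive_km_incidence(build_life_table(x), CAUSE_AE),
  wkm_X1 = function(x) wavg_km_incidence(x, "X1"),
  wkm_X1X2 = function(x) wavg_km_incidence(x, c("X1", "X2")),
  wcox_X1 = function(x) wavg_cox_incidence(x, "X1"),
  wcox_X1X2 = function(x) wavg_cox_incidence(x, c("X1", "X2")),
  wcox_X1X2_int = function(x) wavg_cox_incidence(x, c("X1", "X2", "X1:X2")),
  ipcw_X1 = function(x) ipcw_incidence(x, "X1"),
  ipcw_X1X2 = function(x) ipcw_incidence(x, c("X1", "X2")),
  ipcw_X1X2_int = function(x) ipcw_incidence(x, c("X1", "X2", "X1:X2"))
)

#' Available study estimators
#'
#' Identifiers accepted by [run_study()]: the naive Kaplan-Meier incidence
#' (`naive_km`), the weighted average survival estimators based on
#' stratified KM (`wkm_*`) or on the cause-specific Cox model (`wcox_*`),
#' and the Cox-based IPCW estimators (`ipcw_*`); `*_X1` adjusts for `X1`
#' only, `*_X1X2` for both covariates, `*_int` adds the `X1:X2` interaction.
#'
#' @return Character vector of estimator ids.
#' @export
study_estimators <- function() names(.estimator_registry)

#' Apply one study estimator to a sample
#'
#' @param x a [crsample] with covariates `X1`, `X2`.
#' @param estimator one id from [study_estimators()].
#' @param times evaluation times.
#' @return Potential-incidence estimates at `times`.
#' @export
estimate_incidence <- function(x, estimator, times) {
  if (!estimator %in% names(.estimator_registry))
    stop("unknown estimator id: ", estimator)
  step_eval(.estimator_registry[[estimator]](x), times)
}

#' Run the estimator bias study
#'
#' Replicates the generative scenario, applies each requested
#' potential-incidence estimator to every replicate, evaluates it at the
#' requested times and subtracts the closed-form potential incidence
#' ([potential_incidence()]), so the bias is exact up to estimator noise.
#' Replicate `r` uses the child seed `seed + r`, making any single
#' replicate re-runnable in isolation.  Estimator failures on a replicate
#' (e.g. a degenerate stratum) are recorded as `NA` with the condition
#' message, not dropped.
#'
#' @param s a [scenario()].
#' @param n subjects per replicate.
#' @param reps number of replicates.
#' @param times evaluation times.
#' @param estimators ids from [study_estimators()].
#' @param seed root integer seed.
#' @return A data frame of class `study_result` with one row per
#'   `replicate x estimator x time`: columns `scenario`, `replicate`,
#'   `estimator`, `time`, `estimate`, `truth`, `bias`, `note`.
#' @examples
#' \donttest{
#' res <- run_study(scenario_registry()[["1"]], n = 300, reps = 50,
#'                  times = 0.2, estimators = "naive_km", seed = 1)
#' summarize_bias(res)
#' }
#' @export
run_study <- function(s, n = 300, reps = 1000, times = c(0.2, 0.3),
                      estimators = c("naive_km", "wkm_X1", "wkm_X1X2",
                                     "wcox_X1", "wcox_X1X2",
                                     "ipcw_X1", "ipcw_X1X2"),
                      seed = 1) {
  stopifnot(inherits(s, "scenario"), reps >= 1)
  bad <- setdiff(estimators, names(.estimator_registry))
  if (length(bad)) stop("unknown estimator id(s): ", paste(bad, collapse = ", "))
  truth <- potential_incidence(s, times)
  ne <- length(estimators); nt <- length(times)
  blocks <- vector("list", reps)
  for (r in seq_len(reps)) {
    d <- simulate_dataset(s, n = n, seed = seed + r)
    est <- matrix(NA_real_, nrow = ne, ncol = nt)
    note <- character(ne)
    for (k in seq_len(ne)) {
      res <- tryCatch(
        suppressWarnings(step_eval(.estimator_registry[[estimators[k]]](d), times)),
        error = function(e) conditionMessage(e))
      if (is.character(res)) note[k] <- res else est[k, ] <- res
    }
    blocks[[r]] <- data.frame(
      scenario = s$name, replicate = r,
      estimator = rep(estimators, each = nt),
      time = rep(times, times = ne),
      estimate = as.numeric(t(est)),
      truth = rep(truth, times = ne),
      bias = as.numeric(t(est)) - rep(truth, times = ne),
      note = rep(note, each = nt))
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("study_result", "data.frame")
  out
}

#' Summarize the bias distribution of a study
#'
#' Per (scenario, estimator, time): the median, quartiles, interquartile
#' range and whisker ends (1.5 IQR rule) of the bias across replicates, and
#' the number of failed replicates.
#'
#' @param r a `study_result` from [run_study()].
#' @return A data frame with one row per (scenario, estimator, time).
#' @export
summarize_bias <- function(r) {
  stopifnot(inherits(r, "study_result") || is.data.frame(r))
  if (nrow(r) == 0L) stop("empty study result")
  key <- interaction(r$scenario, r$estimator, r$time, drop = TRUE)
  parts <- split(r, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    b <- p$bias[!is.na(p$bias)]
    q <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(scenario = p$scenario[1], estimator = p$estimator[1],
               time = p$time[1],
               median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
               whisker_low = min(b[b >= q[1] - 1.5 * iqr]),
               whisker_high = max(b[b <= q[3] + 1.5 * iqr]),
               n = nrow(p), n_failed = sum(is.na(p$bias)))
  }))
  out <- out[order(out$scenario, out$time, out$estimator), ]
  rownames(out) <- NULL
  out
}

#' Boxplot of study bias distributions
#'
#' One box per estimator at each evaluation time, with a horizontal
#' reference line at zero bias.
#'
#' @param x a `study_result`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.study_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(unique(x$time))))
  on.exit(graphics::par(op))
  for (tt in sort(unique(x$time))) {
    sub <- x[x$time == tt & !is.na(x$bias), ]
    graphics::boxplot(bias ~ estimator, data = sub,
                      main = sprintf("scenario %s, t = %g", sub$scenario[1], tt),
                      ylab = "bias", las = 2, ...)
    graphics::abline(h = 0, col = "grey50")
  }
  invisible(x)
}
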