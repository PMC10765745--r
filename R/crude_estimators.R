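#' Crude proportion of failures from a cause
#'
#' The count of subjects observed to fail from the given cause over the whole
#' follow-up, divided by the sample size N.  A naive summary: it is not a
#' function of time and does not account for right censoring (the numerator
#' is affected by censoring while N is fixed).
#'
#' @param x a [crsample].
#' @param cause `CAUSE_AE` (default) or `CAUSE_COMPETING`.
#' @return A single proportion.
#' @examples
#' crude_proportion(table_one_sample())  # 80/300
#' @export
crude_proportion <- function(x, cause = CAUSE_AE) {
  x <- as_crsample(x)
  sum(x$status == 1L & x$cause == cause, na.rm = TRUE) / nrow(x)
}

#' Epidemiological event rate
#'
#' The count of subjects failing from the given cause divided by the total
#' time spent free from treatment failure (the sum of all observed follow-up
#' times), i.e. events per person-time unit of the input.  Any unit
#' conversion (e.g. person-years to person-months by dividing by 12) is left
#' to the caller.  This is the maximum-likelihood rate of a constant-hazard
#' model for the cause.
#'
#' @inheritParams crude_proportion
#' @return Events per person-time unit.
#' @examples
#' ae_rate(table_one_sample())        # 80 / 56.4 per person-year
#' ae_rate(table_one_sample()) / 12   # per person-month
#' @export
ae_rate <- function(x, cause = CAUSE_AE) {
  x <- as_crsample(x)
  total <- sum(x$time)
  if (total <= 0) stop("total follow-up time must be positive")
  sum(x$status == 1L & x$cause == cause, na.rm = TRUE) / total
}

#' Overall Kaplan-Meier survival
#'
#' Product-limit estimate of the probability of being free from treatment
#' failure of either cause: \eqn{\hat S(t) = \prod_{t_j \le t}
#' (1 - (d_{jAE} + d_{jRL})/n_j)}.
#'
#' @param x a `life_table` or a [crsample] (tabulated on the fly).
#' @return A [step_function()] starting at 1, non-increasing.
#' @export
overall_km <- function(x) {
  lt <- as_life_table(x)
  step_function(lt$time, cumprod(1 - (lt$d_ae + lt$d_rl) / lt$n_risk), 1)
}

#' Cause-specific hazard
#'
#' The non-parametric estimate of the instantaneous rate of the cause at each
#' distinct failure time: \eqn{\hat h(t_j) = d_j / n_j}, the proportion of
#' subjects failing from the cause at \eqn{t_j} among those still at risk
#' (free from failure of any cause and from censoring).  Rows with zero
#' events of the cause are retained so that derived step functions jump at
#' every failure time.
#'
#' @inheritParams overall_km
#' @param cause `CAUSE_AE` (default) or `CAUSE_COMPETING`.
#' @return A data frame of class `hazard_table` with columns `time`, `n_risk`,
#'   `d`, `hazard`.
#' @export
cause_specific_hazard <- function(x, cause = CAUSE_AE) {
  lt <- as_life_table(x)
  d <- if (cause == CAUSE_AE) lt$d_ae else lt$d_rl
  out <- data.frame(time = lt$time, n_risk = lt$n_risk, d = d,
                    hazard = ifelse(lt$n_risk > 0, d / lt$n_risk, 0))
  class(out) <- c("hazard_table", "data.frame")
  out
}

#' Aalen-Johansen crude cumulative incidence
#'
#' The non-parametric maximum-likelihood estimate of the probability of
#' failing from the given cause by time t in the presence of the competing
#' cause: \eqn{\hat{CI}(t) = \sum_{t_j \le t} \hat S(t_j-)\,\hat h(t_j)},
#' where \eqn{\hat S} is the overall Kaplan-Meier survival from failure of
#' any cause.  The competing event indirectly protects: its occurrence
#' lowers \eqn{\hat S(t_j-)}.
#'
#' @inheritParams cause_specific_hazard
#' @return A non-decreasing [step_function()] starting at 0, bounded by 1.
#' @export
aj_crude_incidence <- function(x, cause = CAUSE_AE) {
  lt <- as_life_table(x)
  h <- cause_specific_hazard(lt, cause)$hazard
  s_all <- cumprod(1 - (lt$d_ae + lt$d_rl) / lt$n_risk)
  s_left <- c(1, s_all[-length(s_all)])
  if (length(h) == 0L) s_left <- numeric(0)
  step_function(lt$time, cumsum(s_left * h), 0)
}

#' Nelson-Aalen cumulative cause-specific hazard
#'
#' The cumulative sum of the cause-specific hazard increments,
#' \eqn{\hat{AN}(t) = \sum_{t_j \le t} \hat h(t_j)}: an estimate of the
#' integrated cause-specific hazard.  Unlike the crude incidence there is no
#' indirect protection from the competing event (the \eqn{\hat S(t_j-)}
#' factor is replaced by 1), and the curve is unbounded above.
#'
#' @inheritParams cause_specific_hazard
#' @return A non-decreasing [step_function()] starting at 0.
#' @export
aalen_nelson <- function(x, cause = CAUSE_AE) {
  ht <- cause_specific_hazard(x, cause)
  step_function(ht$time, cumsum(ht$hazard), 0)
}

#' Naive Kaplan-Meier incidence
#'
#' One minus the product-limit survival that treats the competing cause as
#' plain censoring: \eqn{\hat{KM}(t) = 1 - \prod_{t_j \le t}
#' (1 - \hat h(t_j))}.  Its complement is the naive "AE-free survival
#' curve".  This estimates the potential incidence (the incidence in the
#' hypothetical absence of the competing event) only when the two latent
#' event times are independent; under dependence induced by shared
#' covariates it is biased, which the covariate-adjusted estimators in
#' [weighted_average_survival()] and [ipcw_km_incidence()] correct.
#'
#' @inheritParams cause_specific_hazard
#' @return A non-decreasing [step_function()] starting at 0, bounded by 1.
#' @export
naive_km_incidence <- function(x, cause = CAUSE_AE) {
  ht <- cause_specific_hazard(x, cause)
  step_function(ht$time, 1 - cumprod(1 - ht$hazard), 0)
}
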