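#' Simulate a competing-risks dataset from a scenario
#'
#' Generates subject-level data from the covariate-conditional exponential
#' model by the inversion method: per subject, draw `X1 ~ Bern(p1)` and
#' `X2 ~ Bern(p2)`, then independent uniforms `U`, `V` and set
#' `T_AE = -log(U)/lambda_AE[stratum]`, `T_RL = -log(V)/lambda_RL[stratum]`.
#' The observed time is the minimum of the two latent times (and of an
#' optional independent exponential censoring time), the cause is the
#' argmin, and only the observable data `(time, status, cause, X1, X2)` are
#' returned unless `keep_latent = TRUE`.
#'
#' @param s a [scenario()].
#' @param n number of subjects.
#' @param seed optional integer seed (set via [set.seed()] for
#'   reproducibility; the same seed yields the identical sample).
#' @param censoring_rate optional rate of an independent exponential
#'   censoring time; `NULL` (default) means no censoring.
#' @param keep_latent retain the latent pair as columns `T_AE`, `T_RL`
#'   (debugging/validation only; they are never observable).
#' @return A [crsample] with covariates `X1`, `X2`.
#' @examples
#' d <- simulate_dataset(scenario_registry()[["4"]], n = 300, seed = 1)
#' crude_proportion(d)
#' @export
simulate_dataset <- function(s, n, seed = NULL, censoring_rate = NULL,
                             keep_latent = FALSE) {
  stopifnot(inherits(s, "scenario"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x1 <- stats::rbinom(n, 1, s$p1)
  x2 <- stats::rbinom(n, 1, s$p2)
  idx <- 1L + 2L * x1 + x2  # stratum order 00, 01, 10, 11
  t_ae <- -log(stats::runif(n)) / s$lambda_ae[idx]
  t_rl <- -log(stats::runif(n)) / s$lambda_rl[idx]
  tt <- pmin(t_ae, t_rl)
  cause <- ifelse(t_ae <= t_rl, CAUSE_AE, CAUSE_COMPETING)
  status <- rep(1L, n)
  if (!is.null(censoring_rate)) {
    stopifnot(censoring_rate > 0)
    cc <- -log(stats::runif(n)) / censoring_rate
    status <- as.integer(tt <= cc)
    cause <- ifelse(status == 1L, cause, NA_integer_)
    tt <- pmin(tt, cc)
  }
  cov <- data.frame(X1 = x1, X2 = x2)
  if (keep_latent) { cov$T_AE <- t_ae; cov$T_RL <- t_rl }
  out <- crsample(time = tt, status = status, cause = cause, covariates = cov)
  attr(out, "covariates") <- c("X1", "X2")
  out
}

#' Registry of simulation scenarios
#'
#' The eight configurations of the simulation study.  All share the AE rate
#' grid `lambda_AE = (1, 3, 3, 9)` and, unless stated, prevalences
#' `P(X1=1) = 0.3`, `P(X2=1) = 0.4`; they differ in the competing-event
#' rates or the prevalences:
#' \describe{
#'   \item{`"1"`}{`lambda_RL = (2,2,2,2)`: the competing hazard is free of
#'     the covariates, so the latent times are marginally independent.}
#'   \item{`"2"`}{`lambda_RL = (2,2,5,5)`: only `X1` affects the competing
#'     hazard.}
#'   \item{`"3"`}{`lambda_RL = (2,6,5,5)`: both covariates, with an
#'     interaction (`X2` acts only when `X1=0`).}
#'   \item{`"4"`}{`lambda_RL = (2,6,5,15)`: both covariates,
#'     multiplicatively (no interaction).}
#'   \item{`"prevA"`, `"prevB"`}{scenario-4 rates with prevalences
#'     `0.5/0.5` and `0.3/0.1`.}
#'   \item{`"hazA"`, `"hazB"`}{competing rates `(2,4,5,10)` and
#'     `(2,3,5,7.5)`: the `X2` effect on the competing hazard reduced to
#'     2-fold and 1.5-fold.}
#' }
#'
#' @return A named list of [scenario()] objects.
#' @export
scenario_registry <- function() {
  lam_ae <- c(1, 3, 3, 9)
  list(
    "1" = scenario(0.3, 0.4, lam_ae, c(2, 2, 2, 2), name = "1"),
    "2" = scenario(0.3, 0.4, lam_ae, c(2, 2, 5, 5), name = "2"),
    "3" = scenario(0.3, 0.4, lam_ae, c(2, 6, 5, 5), name = "3"),
    "4" = scenario(0.3, 0.4, lam_ae, c(2, 6, 5, 15), name = "4"),
    "prevA" = scenario(0.5, 0.5, lam_ae, c(2, 6, 5, 15), name = "prevA"),
    "prevB" = scenario(0.3, 0.1, lam_ae, c(2, 6, 5, 15), name = "prevB"),
    "hazA" = scenario(0.3, 0.4, lam_ae, c(2, 4, 5, 10), name = "hazA"),
    "hazB" = scenario(0.3, 0.4, lam_ae, c(2, 3, 5, 7.5), name = "hazB")
  )
}
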