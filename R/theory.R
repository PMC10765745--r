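#' Define a generative scenario
#'
#' A scenario of the covariate-conditional exponential model: two independent
#' Bernoulli covariates with prevalences `p1 = P(X1=1)` and `p2 = P(X2=1)`,
#' and within each of the four strata `(X1=k, X2=l)` independent exponential
#' latent times for the AE and the competing event with rates
#' `lambda_ae[kl]`, `lambda_rl[kl]` (per time unit).  Rates are supplied in
#' the stratum order `00, 01, 10, 11`.
#'
#' @param p1,p2 covariate prevalences in `[0, 1]`.
#' @param lambda_ae,lambda_rl positive rate vectors of length 4 (order
#'   `00, 01, 10, 11`).
#' @param name optional label.
#' @return An object of class `scenario`.
#' @examples
#' sc <- scenario(0.3, 0.4, c(1, 3, 3, 9), c(2, 6, 5, 15), name = "4")
#' potential_incidence(sc, 0.2)
#' @export
scenario <- function(p1, p2, lambda_ae, lambda_rl, name = "") {
  stopifnot(length(p1) == 1, length(p2) == 1, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1,
            length(lambda_ae) == 4, length(lambda_rl) == 4,
            all(lambda_ae > 0), all(lambda_rl > 0))
  kl <- c("00", "01", "10", "11")
  structure(list(p1 = p1, p2 = p2,
                 lambda_ae = stats::setNames(as.numeric(lambda_ae), kl),
                 lambda_rl = stats::setNames(as.numeric(lambda_rl), kl),
                 name = as.character(name)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: P(X1=1)=%g, P(X2=1)=%g\n", x$name, x$p1, x$p2))
  print(rbind(lambda_AE = x$lambda_ae, lambda_RL = x$lambda_rl))
  invisible(x)
}

# P(X1=k, X2=l) in stratum order 00, 01, 10, 11 (independent Bernoullis).
stratum_probs <- function(s) {
  c((1 - s$p1) * (1 - s$p2), (1 - s$p1) * s$p2,
    s$p1 * (1 - s$p2), s$p1 * s$p2)
}

#' Closed-form potential survival and incidence
#'
#' The marginal survival of the latent time to the given cause in the
#' hypothetical absence of the other cause: a mixture of the four stratum
#' exponentials weighted by the stratum probabilities,
#' \eqn{pS(t) = \sum_{k,l} P(X_1=k)P(X_2=l)\, e^{-\lambda_{kl} t}}.
#' `potential_incidence()` is its complement and
#' `potential_cumulative_hazard()` is \eqn{-\log pS(t)}.
#'
#' @param s a [scenario()].
#' @param t non-negative times (vectorised).
#' @param cause `CAUSE_AE` (default) or `CAUSE_COMPETING`.
#' @return Numeric vector of the same length as `t`.
#' @export
potential_survival <- function(s, t, cause = CAUSE_AE) {
  stopifnot(inherits(s, "scenario"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be non-negative")
  lam <- if (cause == CAUSE_AE) s$lambda_ae else s$lambda_rl
  as.numeric(exp(-outer(t, lam)) %*% stratum_probs(s))
}

#' @rdname potential_survival
#' @export
potential_incidence <- function(s, t, cause = CAUSE_AE) {
  1 - potential_survival(s, t, cause)
}

#' @rdname potential_survival
#' @export
potential_cumulative_hazard <- function(s, t, cause = CAUSE_AE) {
  -log(potential_survival(s, t, cause))
}

#' Expected number of subjects at risk
#'
#' The expected size of the risk set (free from both events) at time `t` in
#' a sample of `n` subjects:
#' \eqn{n \sum_{k,l} P(X_1=k)P(X_2=l)\, e^{-\lambda_{klRL} t}\, e^{-\lambda_{klAE} t}},
#' the within-stratum joint survival factorising by conditional independence.
#'
#' @param s a [scenario()].
#' @param t non-negative times (vectorised).
#' @param n sample size.
#' @return Expected at-risk counts.
#' @export
expected_at_risk <- function(s, t, n) {
  stopifnot(inherits(s, "scenario"), n > 0)
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be non-negative")
  n * as.numeric(exp(-outer(t, s$lambda_ae + s$lambda_rl)) %*% stratum_probs(s))
}
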