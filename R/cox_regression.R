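# Term handling: a term is either a covariate name or an interaction
# "X1:X2"; interaction values are products of the base covariate values.
term_bases <- function(terms) unique(unlist(strsplit(terms, ":", fixed = TRUE)))

term_values <- function(terms, data) {
  vapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
  }, numeric(nrow(data)))
}

pattern_key <- function(values, names) {
  paste(sprintf("%s=%s", names, unlist(values)), collapse = ",")
}

#' Fit a cause-specific proportional-hazards model
#'
#' Fits a Cox model for the cause-specific hazard of one cause, treating
#' failures from the other cause as censoring:
#' \eqn{CSH(t \mid x) = CSH_0(t) \exp(\beta' x)}.  Fitting is by partial
#' likelihood with the Breslow tie approximation (so that with no covariates
#' the baseline reduces exactly to the Nelson-Aalen estimator), delegated to
#' [survival::coxph()]; the baseline cumulative hazard is the Breslow
#' estimator at covariate value zero.  Interaction terms are written
#' `"X1:X2"` and enter as products of the named covariates.
#'
#' @param x a [crsample] with the covariates named in `terms`.
#' @param cause the cause whose hazard is modelled (`CAUSE_AE` or
#'   `CAUSE_COMPETING`).
#' @param terms character vector of model terms, e.g. `c("X1", "X2")` or
#'   `c("X1", "X2", "X1:X2")`; may be empty for a null model.
#' @return An object of class `cox_csh`: list with `coefficients`, `terms`,
#'   `baseline` (the Breslow cumulative-hazard [step_function()]), `cause`,
#'   `n_events`, `iter`, and the underlying `coxph` fit.
#' @seealso [predict_survival()], [stratified_km()]
#' @export
fit_cox <- function(x, cause = CAUSE_AE, terms = character(0)) {
  x <- as_crsample(x)
  miss <- setdiff(term_bases(terms), attr(x, "covariates"))
  if (length(miss)) stop("unknown covariate(s) in terms: ", paste(miss, collapse = ", "))
  event <- as.integer(x$status == 1L & !is.na(x$cause) & x$cause == cause)
  if (sum(event) == 0L) stop("no events of the requested cause; cannot fit")
  df <- data.frame(.time = x$time, .event = event)
  for (b in term_bases(terms)) df[[b]] <- as.numeric(x[[b]])
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow", control = ctrl),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|Ran out of iterations|did not converge", msg))
        stop("Cox fit failed: ", msg, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (length(cf) && any(!is.finite(cf)))
    stop("Cox fit failed: non-finite coefficient")
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(coefficients = if (length(terms)) stats::setNames(as.numeric(cf), terms) else numeric(0),
                 terms = terms,
                 baseline = step_function(bh$time, bh$hazard, 0),
                 cause = cause,
                 n_events = sum(event),
                 iter = fit$iter,
                 fit = fit),
            class = "cox_csh")
}

#' @export
print.cox_csh <- function(x, ...) {
  cat(sprintf("Cause-specific Cox model (cause %d, %d events, %d iterations)\n",
              x$cause, x$n_events, x$iter))
  if (length(x$coefficients)) {
    print(data.frame(term = names(x$coefficients),
                     estimate = as.numeric(x$coefficients)), row.names = FALSE)
  } else cat("(null model: Breslow baseline only)\n")
  invisible(x)
}

#' Predict conditional survival from a cause-specific Cox model
#'
#' \eqn{S(t \mid x) = \exp(-H_0(t)\,e^{\beta' x})} on the event-time grid of
#' the fitted baseline.  The pattern must supply a value for every base
#' covariate of the model terms; interaction terms are evaluated as products.
#'
#' @param model a `cox_csh` from [fit_cox()].
#' @param pattern named list or vector of covariate values, e.g.
#'   `c(X1 = 1, X2 = 0)`.
#' @return A non-increasing [step_function()] starting at 1.
#' @export
predict_survival <- function(model, pattern) {
  stopifnot(inherits(model, "cox_csh"))
  pattern <- as.list(pattern)
  miss <- setdiff(term_bases(model$terms), names(pattern))
  if (length(miss)) stop("pattern is missing covariate(s): ", paste(miss, collapse = ", "))
  lp <- 0
  if (length(model$terms)) {
    tv <- term_values(model$terms, as.data.frame(pattern))
    lp <- sum(model$coefficients * as.numeric(tv))
  }
  h0 <- model$baseline
  step_function(h0$times, exp(-h0$values * exp(lp)), 1)
}

#' Stratified Kaplan-Meier survival for one cause
#'
#' Within each stratum defined by the (categorical) covariates, the
#' product-limit survival for time to the given cause, treating the other
#' cause as censoring.  Under conditional independence of the two latent
#' event times given the strata this estimates the potential conditional
#' survival \eqn{P(T_{cause} > t \mid X)}.  A stratum with no events of the
#' cause yields the constant-1 curve with a warning.
#'
#' @param x a [crsample].
#' @param cause `CAUSE_AE` or `CAUSE_COMPETING`.
#' @param strata character vector of covariate names defining the strata.
#' @return A named list of [step_function()]s, one per observed covariate
#'   pattern (names like `"X1=0,X2=1"`), with attributes `patterns` (data
#'   frame of pattern values) and `n` (stratum sizes).
#' @export
stratified_km <- function(x, cause = CAUSE_AE, strata) {
  x <- as_crsample(x)
  if (missing(strata) || length(strata) == 0L)
    stop("at least one stratifying covariate is required")
  miss <- setdiff(strata, attr(x, "covariates"))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  pats <- unique(as.data.frame(x)[strata])
  pats <- pats[do.call(order, pats), , drop = FALSE]
  rownames(pats) <- NULL
  curves <- vector("list", nrow(pats))
  sizes <- integer(nrow(pats))
  keys <- character(nrow(pats))
  for (i in seq_len(nrow(pats))) {
    keep <- rep(TRUE, nrow(x))
    for (v in strata) keep <- keep & x[[v]] == pats[i, v]
    sub <- x[keep, , drop = FALSE]
    sizes[i] <- nrow(sub)
    keys[i] <- pattern_key(pats[i, , drop = FALSE], strata)
    ht <- cause_specific_hazard(build_life_table(sub), cause)
    if (sum(ht$d) == 0L) {
      warning("stratum ", keys[i], " has no events of cause ", cause,
              "; returning the constant-1 survival curve")
      curves[[i]] <- step_function(numeric(0), numeric(0), 1)
    } else {
      curves[[i]] <- step_function(ht$time, cumprod(1 - ht$hazard), 1)
    }
  }
  names(curves) <- keys
  attr(curves, "patterns") <- pats
  attr(curves, "n") <- stats::setNames(sizes, keys)
  curves
}
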