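#' Covariate-pattern proportions
#'
#' Empirical frequencies of the observed covariate patterns, the weights of
#' the weighted average survival: the proportion of subjects with each
#' combination of the (categorical) covariate values.
#'
#' @param x a [crsample].
#' @param covariates covariate names defining the patterns.
#' @return An object of class `pattern_weights`: a named numeric vector of
#'   proportions (names like `"X1=0,X2=1"`, summing to 1) with attribute
#'   `patterns` (data frame of pattern values).
#' @export
pattern_proportions <- function(x, covariates) {
  x <- as_crsample(x)
  if (missing(covariates) || length(covariates) == 0L)
    stop("at least one covariate is required")
  miss <- setdiff(covariates, attr(x, "covariates"))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  keys <- apply(as.data.frame(x)[covariates], 1, function(r)
    pattern_key(as.list(r), covariates))
  tab <- table(keys)
  prop <- as.numeric(tab) / nrow(x)
  names(prop) <- names(tab)
  pats <- unique(as.data.frame(x)[covariates])
  rownames(pats) <- NULL
  pats <- pats[match(names(prop),
                     apply(pats, 1, function(r) pattern_key(as.list(r), covariates))), ,
               drop = FALSE]
  structure(prop, patterns = pats, class = c("pattern_weights", "numeric"))
}

#' Weighted average survival
#'
#' The marginal "AE-free" survival obtained as the convex combination of
#' per-pattern conditional survival curves, weighted by the proportion of
#' subjects carrying each covariate pattern.  The per-pattern curves may come
#' from [stratified_km()] or from [predict_survival()] on a fitted Cox
#' model.  The complement to 1 is the potential-incidence estimate.
#'
#' @param per_pattern named list of [step_function()] survival curves, keyed
#'   by covariate pattern.
#' @param weights a `pattern_weights` object (or named non-negative vector
#'   summing to 1) whose names are a subset of `names(per_pattern)`.
#' @return A [step_function()] on the union of the per-pattern jump grids.
#' @export
weighted_average_survival <- function(per_pattern, weights) {
  w <- as.numeric(weights)
  names(w) <- names(weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  miss <- setdiff(names(w), names(per_pattern))
  if (length(miss)) stop("no survival curve for pattern(s): ", paste(miss, collapse = "; "))
  curves <- per_pattern[names(w)]
  step_combine(curves, function(m) as.numeric(m %*% w))
}

#' Inverse-probability-of-censoring weights
#'
#' Builds the IPCW weight trajectories that undo the informative removal of
#' subjects from the AE risk sets by the competing event: each subject's
#' unit contribution at time \eqn{t_j} is replaced by
#' \eqn{w_i(t_j) = 1 / \hat S_{RL}(t_j- \mid X_i)}, the inverse of the
#' subject's estimated probability of still being free of the competing
#' event just before \eqn{t_j}.  The conditional competing-event-free
#' survival is estimated either by stratified Kaplan-Meier curves or by a
#' cause-specific Cox model on the competing cause (with optional
#' interaction terms).  Weights are evaluated at the left limit so a
#' subject's own competing event at \eqn{t_j} does not alter its weight
#' there.
#'
#' @param x a [crsample].
#' @param weight_model `"cox"` (default) or `"km"` (stratified; base
#'   covariates only, no interaction terms).
#' @param terms model terms for the competing-cause model, e.g.
#'   `c("X1", "X2")` or `c("X1", "X2", "X1:X2")`.
#' @param cause the cause of interest (whose event-time grid the weights are
#'   evaluated on); the weight model is fitted to the *other* cause.
#' @param truncate optional cap applied to the weights (default: none); the
#'   number of capped entries is reported via a message.
#' @return An object of class `ipc_weights`: list with the event-time grid
#'   `times`, the n-by-length(times) weight matrix `W`, the model
#'   description, and `n_truncated`.
#' @export
ipcw_weights <- function(x, weight_model = c("cox", "km"), terms,
                         cause = CAUSE_AE, truncate = NULL) {
  x <- as_crsample(x)
  weight_model <- match.arg(weight_model)
  competing <- if (cause == CAUSE_AE) CAUSE_COMPETING else CAUSE_AE
  grid <- sort(unique(x$time[x$status == 1L & x$cause == cause]))
  n <- nrow(x)
  W <- matrix(1, nrow = n, ncol = length(grid))
  n_trunc <- 0L
  model <- list(type = "unit")
  if (any(x$status == 1L & x$cause == competing, na.rm = TRUE) && length(grid)) {
    if (weight_model == "cox") {
      m <- fit_cox(x, cause = competing, terms = terms)
      lp <- if (length(terms))
        as.numeric(term_values(terms, as.data.frame(x)) %*% m$coefficients)
      else rep(0, n)
      h0_left <- step_left_limit(m$baseline, grid)
      # S_RL(t- | X_i) = exp(-H0(t-) exp(lp_i)); outer() gives the n x J grid
      W <- 1 / exp(-outer(exp(lp), h0_left))
      model <- list(type = "cox", fit = m)
    } else {
      if (any(grepl(":", terms, fixed = TRUE)))
        stop("interaction terms are not meaningful for the stratified KM weight model")
      curves <- stratified_km(x, cause = competing, strata = terms)
      keys <- apply(as.data.frame(x)[terms], 1, function(r)
        pattern_key(as.list(r), terms))
      s_left <- vapply(curves, step_left_limit, numeric(length(grid)), t = grid)
      s_left <- matrix(s_left, nrow = length(grid),
                       dimnames = list(NULL, names(curves)))
      W <- 1 / t(s_left[, keys, drop = FALSE])
      dimnames(W) <- NULL
      model <- list(type = "km", curves = curves)
    }
    at_risk <- outer(x$time, grid, `>=`)
    if (!is.null(truncate)) {
      over <- W > truncate & at_risk
      n_trunc <- sum(over)
      if (n_trunc) message(n_trunc, " weight value(s) truncated at ", truncate)
      W[W > truncate] <- truncate
    } else if (any(!is.finite(W[at_risk]))) {
      stop("estimated competing-event-free survival reached 0 for an at-risk ",
           "subject; set `truncate` to cap the weights")
    }
  }
  structure(list(times = grid, W = W, model = model, cause = cause,
                 n_truncated = n_trunc),
            class = "ipc_weights")
}

#' IPCW product-limit incidence
#'
#' The weighted Kaplan-Meier estimate of the potential incidence of the
#' cause of interest: at each of its event times the unit contributions to
#' the event count and to the risk set are both replaced by the IPCW weights
#' of [ipcw_weights()], creating a pseudo-population resembling the one
#' observable in the absence of the competing event.  The incidence is one
#' minus the weighted product-limit survival.
#'
#' @param x the same [crsample] the weights were built from.
#' @param weights an `ipc_weights` object.
#' @param cause the cause of interest (must match the weights).
#' @return A non-decreasing [step_function()] starting at 0.
#' @export
ipcw_km_incidence <- function(x, weights, cause = CAUSE_AE) {
  x <- as_crsample(x)
  stopifnot(inherits(weights, "ipc_weights"))
  if (cause != weights$cause)
    stop("weights were built for cause ", weights$cause)
  grid <- weights$times
  if (length(grid) == 0L) return(step_function(numeric(0), numeric(0), 0))
  if (nrow(weights$W) != nrow(x))
    stop("weights and sample have different numbers of subjects")
  haz <- vapply(seq_along(grid), function(j) {
    at_risk <- x$time >= grid[j]
    ev <- x$status == 1L & !is.na(x$cause) & x$cause == cause & x$time == grid[j]
    den <- sum(weights$W[at_risk, j])
    if (den <= 0) stop("weighted risk set is empty at time ", grid[j])
    sum(weights$W[ev, j]) / den
  }, numeric(1))
  step_function(grid, 1 - cumprod(1 - haz), 0)
}
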