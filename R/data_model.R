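#' Cause codes
#'
#' Integer codes for the two competing failure causes: `CAUSE_AE = 1` for the
#' adverse event and `CAUSE_COMPETING = 2` for the competing efficacy-endpoint
#' event (relapse/death).
#'
#' @name cause-codes
#' @aliases CAUSE_AE CAUSE_COMPETING
#' @export
CAUSE_AE <- 1L

#' @rdname cause-codes
#' @export
CAUSE_COMPETING <- 2L

#' Construct a competing-risks sample
#'
#' A `crsample` holds subject-level right-censored competing-risks data: one
#' row per subject with the observed follow-up time, the failure indicator
#' and, for failures, the cause of failure (1 = adverse event, 2 = competing
#' event), plus any baseline covariates.  Only the minimum of the two latent
#' event times is observable, so `cause` is defined exactly when `status == 1`.
#'
#' @param time non-negative observed follow-up times (one unit throughout,
#'   e.g. years).
#' @param status failure indicator, 0 = censored, 1 = failed.
#' @param cause failure cause, `CAUSE_AE` or `CAUSE_COMPETING` where
#'   `status == 1`, `NA` where censored.
#' @param covariates optional data frame of baseline covariates (one row per
#'   subject).
#' @param id optional subject identifiers; defaults to `1:n`.
#' @return A data frame of class `crsample` with columns `id`, `time`,
#'   `status`, `cause` and one column per covariate; the covariate names are
#'   kept in `attr(x, "covariates")`.
#' @examples
#' crsample(time = c(1, 2, 3), status = c(1, 1, 0), cause = c(1, 2, NA))
#' @export
crsample <- function(time, status, cause = NULL, covariates = NULL, id = NULL) {
  n <- length(time)
  if (n == 0L) stop("a competing-risks sample must contain at least one subject")
  time <- as.numeric(time)
  status <- as.integer(status)
  if (is.null(cause)) cause <- rep(NA_integer_, n)
  cause <- suppressWarnings(as.integer(cause))
  if (is.null(id)) id <- seq_len(n)
  if (length(status) != n || length(cause) != n || length(id) != n)
    stop("time, status, cause and id must have equal length")
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad))
    stop("negative or non-finite time for subject(s): ", paste(id[bad], collapse = ", "))
  if (!all(status %in% c(0L, 1L)))
    stop("status must be 0 (censored) or 1 (failed)")
  bad <- which(status == 1L & (is.na(cause) | !(cause %in% c(CAUSE_AE, CAUSE_COMPETING))))
  if (length(bad))
    stop("failed subject(s) without a valid cause (1 or 2): ", paste(id[bad], collapse = ", "))
  bad <- which(status == 0L & !is.na(cause))
  if (length(bad))
    stop("censored subject(s) must not carry a cause: ", paste(id[bad], collapse = ", "))
  out <- data.frame(id = id, time = time, status = status, cause = cause)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per subject")
    cov_names <- names(covariates)
    if (any(cov_names %in% names(out)))
      stop("covariate names clash with reserved columns id/time/status/cause")
    out <- cbind(out, covariates)
  }
  structure(out, covariates = cov_names,
            class = c("crsample", "data.frame"))
}

#' Coerce a data frame to a competing-risks sample
#'
#' @param x a data frame with columns `time`, `status`, `cause` (optionally
#'   `id`) and covariate columns.
#' @param covariates names of the covariate columns; by default every column
#'   other than `id`, `time`, `status`, `cause`.
#' @return A `crsample`.
#' @export
as_crsample <- function(x, covariates = NULL) {
  if (inherits(x, "crsample") && is.null(covariates)) return(x)
  x <- as.data.frame(x)
  need <- c("time", "status")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(x), c("id", "time", "status", "cause"))
  miss <- setdiff(covariates, names(x))
  if (length(miss)) stop("unknown covariate column(s): ", paste(miss, collapse = ", "))
  crsample(time = x$time, status = x$status,
           cause = if ("cause" %in% names(x)) x$cause else NULL,
           covariates = if (length(covariates)) x[covariates] else NULL,
           id = if ("id" %in% names(x)) x$id else NULL)
}

#' @export
print.crsample <- function(x, ...) {
  cat(sprintf("Competing-risks sample: %d subjects, %d AE, %d competing, %d censored\n",
              nrow(x), sum(x$status == 1L & x$cause == CAUSE_AE, na.rm = TRUE),
              sum(x$status == 1L & x$cause == CAUSE_COMPETING, na.rm = TRUE),
              sum(x$status == 0L)))
  cv <- attr(x, "covariates")
  if (length(cv)) cat("Covariates:", paste(cv, collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

#' Read a competing-risks sample from delimited text
#'
#' Expects a header row and columns `id,time,status,cause,<covariate...>`
#' (comma separated by default).  `status` is 0/1 and `cause` is 1 (AE) or
#' 2 (competing), empty for censored rows.  Malformed rows are rejected with
#' a message naming the offending row.
#'
#' @param path file path.
#' @param covariates covariate column names; default: all remaining columns.
#' @param sep field separator.
#' @return A [crsample].
#' @export
read_sample <- function(path, covariates = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  for (col in intersect(c("time", "status", "cause"), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(v))
    if (length(bad))
      stop(sprintf("unparseable value in column '%s' at data row(s) %s of %s",
                   col, paste(bad, collapse = ", "), path))
    raw[[col]] <- v
  }
  tryCatch(as_crsample(raw, covariates = covariates),
           error = function(e) stop("invalid sample in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a competing-risks sample to delimited text
#'
#' @param x a [crsample].
#' @param path file path.
#' @export
write_sample <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Build the life table of a competing-risks sample
#'
#' Tabulates, at every distinct failure time \eqn{t_j}, the number at risk
#' \eqn{n_j}, the AE and competing-event counts \eqn{d_{jAE}}, \eqn{d_{jRL}},
#' and the number censored in \eqn{[t_j, t_{j+1})}.  Censoring times tied
#' with a failure time are removed from the risk set after the failures
#' (events-before-censoring convention); both causes at a common time share
#' the same risk set.
#'
#' @param x a [crsample].
#' @return A data frame of class `life_table` with columns `time`, `n_risk`,
#'   `d_ae`, `d_rl`, `n_cens`; attributes `n_total` (sample size) and
#'   `n_cens_before` (subjects censored before the first failure time).
#' @examples
#' lt <- build_life_table(table_one_sample())
#' head(lt)
#' @export
build_life_table <- function(x) {
  x <- as_crsample(x)
  ft <- sort(unique(x$time[x$status == 1L]))
  if (length(ft) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      d_ae = integer(0), d_rl = integer(0),
                      n_cens = integer(0))
    attr(out, "n_total") <- nrow(x)
    attr(out, "n_cens_before") <- sum(x$status == 0L)
    class(out) <- c("life_table", "data.frame")
    return(out)
  }
  # a subject censored exactly at t_j is still at risk at t_j
  n_risk <- vapply(ft, function(t) sum(x$time >= t), integer(1))
  d_ae <- vapply(ft, function(t)
    sum(x$status == 1L & x$time == t & x$cause == CAUSE_AE), integer(1))
  d_rl <- vapply(ft, function(t)
    sum(x$status == 1L & x$time == t & x$cause == CAUSE_COMPETING), integer(1))
  upper <- c(ft[-1], Inf)
  n_cens <- vapply(seq_along(ft), function(j)
    sum(x$status == 0L & x$time >= ft[j] & x$time < upper[j]), integer(1))
  out <- data.frame(time = ft, n_risk = n_risk, d_ae = d_ae, d_rl = d_rl,
                    n_cens = n_cens)
  attr(out, "n_total") <- nrow(x)
  attr(out, "n_cens_before") <- sum(x$status == 0L & x$time < ft[1])
  class(out) <- c("life_table", "data.frame")
  out
}

as_life_table <- function(x) {
  if (inherits(x, "life_table")) x else build_life_table(x)
}

# Distinct failure times, risk sets and per-cause event counts of the
# 300-subject worked example; all estimator columns are reproducible from
# these counts alone (no subject is censored).
.table_one_counts <- data.frame(
  time = c(0.0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0, 1.1, 1.2, 1.3, 2.1),
  n_risk = c(300, 196, 115, 65, 49, 36, 25, 18, 15, 11, 7, 5, 3, 1),
  d_ae = c(29, 21, 11, 4, 6, 1, 3, 0, 2, 1, 0, 0, 1, 1),
  d_rl = c(75, 60, 39, 12, 7, 10, 4, 3, 2, 3, 2, 2, 1, 0)
)

#' The 300-subject worked-example sample
#'
#' Reconstructs the simulated example dataset of 300 subjects from its
#' published life-table counts: at each of the 14 distinct failure times the
#' recorded numbers of AE and competing (relapse) events are expanded into
#' individual records.  No subject is censored and no covariates are carried
#' (the printed table does not report them), so every estimator computed on
#' the published counts is reproducible from this sample.  80 subjects fail
#' of the AE and 220 of the competing event; total follow-up is 56.4
#' person-years.
#'
#' @return A [crsample] with 300 records.
#' @examples
#' s <- table_one_sample()
#' crude_proportion(s)       # 80/300
#' @export
table_one_sample <- function() {
  tc <- .table_one_counts
  time <- rep(tc$time, times = tc$d_ae + tc$d_rl)
  cause <- unlist(lapply(seq_len(nrow(tc)), function(j)
    rep(c(CAUSE_AE, CAUSE_COMPETING), times = c(tc$d_ae[j], tc$d_rl[j]))))
  crsample(time = time, status = rep(1L, length(time)), cause = cause)
}

#' Right-continuous step functions
#'
#' The output form of every time-dependent estimator in the package: a
#' right-continuous piecewise-constant curve given by strictly increasing
#' jump times, the value attained at each jump, and the value on
#' \eqn{[0, t_1)}.  Evaluation beyond the last jump carries the last value
#' forward.
#'
#' @param times strictly increasing non-negative jump times (may be empty).
#' @param values value attained at (and after) each jump time.
#' @param initial value on `[0, first jump)`.
#' @return An object of class `crstep`.
#' @seealso [step_eval()], [step_left_limit()]
#' @export
step_function <- function(times, values, initial) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) && (any(times < 0) || any(diff(times) <= 0)))
    stop("jump times must be non-negative and strictly increasing")
  structure(list(times = times, values = values, initial = as.numeric(initial)),
            class = "crstep")
}

#' Evaluate a step function
#'
#' `step_eval(f, t)` returns the right-continuous value at `t` (the value
#' attached to the largest jump time `<= t`, or the initial value before the
#' first jump).  `step_left_limit(f, t)` returns the left limit
#' \eqn{f(t-)}, i.e. the value attached to the largest jump time strictly
#' below `t`.
#'
#' @param f a [step_function()].
#' @param t non-negative evaluation times (vectorised).
#' @return Numeric vector of the same length as `t`.
#' @export
step_eval <- function(f, t) {
  stopifnot(inherits(f, "crstep"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("evaluation times must be non-negative")
  idx <- findInterval(t, f$times)
  ifelse(idx == 0L, f$initial, f$values[pmax(idx, 1L)])
}

#' @rdname step_eval
#' @export
step_left_limit <- function(f, t) {
  stopifnot(inherits(f, "crstep"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("evaluation times must be non-negative")
  idx <- findInterval(t, f$times, left.open = TRUE)
  ifelse(idx == 0L, f$initial, f$values[pmax(idx, 1L)])
}

#' @export
print.crstep <- function(x, ...) {
  cat(sprintf("Step function: initial value %g, %d jump(s)\n",
              x$initial, length(x$times)))
  if (length(x$times))
    print(utils::head(data.frame(time = x$times, value = x$values), 10))
  invisible(x)
}

#' @export
as.data.frame.crstep <- function(x, ...) {
  data.frame(time = c(0, x$times), value = c(x$initial, x$values))
}

#' Serialize a step function as two-column text
#'
#' Writes `time,value` rows with an initial row `0,<initial_value>`;
#' `read_step_function()` reads the same format back.
#'
#' @param f a [step_function()].
#' @param path file path.
#' @export
write_step_function <- function(f, path) {
  utils::write.csv(as.data.frame(f), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_step_function
#' @export
read_step_function <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(d)))
    stop("step-function file must have columns time,value")
  if (nrow(d) == 0L || d$time[1] != 0)
    stop("step-function file must start with the row 0,<initial_value>")
  step_function(d$time[-1], d$value[-1], d$value[1])
}

# Pointwise combination of step functions on the union of their jump grids.
# fun receives a matrix (grid rows x curves) and must return one value per row.
step_combine <- function(curves, fun) {
  stopifnot(length(curves) > 0)
  grid <- sort(unique(unlist(lapply(curves, `[[`, "times"))))
  inits <- vapply(curves, `[[`, numeric(1), "initial")
  if (length(grid) == 0L)
    return(step_function(numeric(0), numeric(0), fun(matrix(inits, nrow = 1))))
  vals <- vapply(curves, step_eval, numeric(length(grid)), t = grid)
  vals <- matrix(vals, nrow = length(grid))
  step_function(grid, fun(vals), fun(matrix(inits, nrow = 1)))
}
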