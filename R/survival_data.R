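#' Discrete survival data
#'
#' Bundle a discrete observed time, an event indicator and a covariate
#' matrix into a validated container for forward continuation ratio (FCR)
#' modelling. Follow-up time is divided into `K + 1` intervals
#' `[a0, a1), ..., [aK, Inf)`; the observed time `T_i = min(Y_i, C_i)`
#' records the interval (1-based) in which subject `i` experienced the
#' event (`status = 1`) or was censored (`status = 0`).
#'
#' @param time Integer vector of observed intervals, values in `1..K+1`.
#' @param status Integer (or logical) event indicator, 1 = event, 0 =
#'   censored.
#' @param x Numeric covariate matrix, one row per subject, features in
#'   columns. Column names are used as feature identifiers; unnamed
#'   columns are labelled `V1..VP`.
#' @param n_intervals Total number of time intervals `K + 1`. Defaults to
#'   `max(time)`, so the last observed interval is taken to be the final
#'   open-ended one.
#'
#' @return An object of class `discrete_survival_data`: a list with
#'   elements `time`, `status`, `x`, `k` (number of modelled thresholds,
#'   `n_intervals - 1`), `n` and `p`.
#'
#' @examples
#' x <- matrix(rnorm(20), nrow = 10)
#' d <- discrete_survival_data(time = rep(1:5, 2), status = rep(0:1, 5), x = x)
#' d$k
#' @export
discrete_survival_data <- function(time, status, x, n_intervals = NULL) {
  if (is.logical(status)) status <- as.integer(status)
  if (!is.numeric(time) || !is.numeric(status)) {
    stop("`time` and `status` must be numeric vectors.", call. = FALSE)
  }
  if (any(time != as.integer(time))) {
    stop("`time` must contain integer interval indices.", call. = FALSE)
  }
  time <- as.integer(time)
  status <- as.integer(status)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (subjects in rows).", call. = FALSE)
  }
  n <- length(time)
  if (length(status) != n || nrow(x) != n) {
    stop("`time`, `status` and `x` must describe the same subjects: got lengths ",
         n, ", ", length(status), " and ", nrow(x), " rows.", call. = FALSE)
  }
  if (!all(status %in% c(0L, 1L))) {
    stop("`status` must be 0/1.", call. = FALSE)
  }
  if (is.null(n_intervals)) n_intervals <- max(time)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 2L) {
    stop("Need at least 2 time intervals (one modelled threshold).", call. = FALSE)
  }
  bad <- which(time < 1L | time > n_intervals)
  if (length(bad)) {
    stop("Observed interval outside 1..", n_intervals, " for subject(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ".", call. = FALSE)
  }
  if (!any(status == 1L)) {
    stop("No events observed (`status` all zero); the model is not identifiable.",
         call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  structure(
    list(time = time, status = status, x = x,
         k = n_intervals - 1L, n = n, p = ncol(x)),
    class = "discrete_survival_data"
  )
}

#' Coerce a data frame to discrete survival data
#'
#' Data-frame-first constructor: the outcome columns are named and every
#' remaining numeric column becomes a model feature.
#'
#' @param data A data frame with one row per subject.
#' @param time,status Columns holding the observed interval and the event
#'   indicator (tidy evaluation; bare names or strings).
#' @param n_intervals Total number of intervals `K + 1`; default `max(time)`.
#'
#' @return A [discrete_survival_data] object.
#' @examples
#' df <- data.frame(t = c(1, 2, 3), d = c(1, 0, 1), g1 = rnorm(3), g2 = rnorm(3))
#' as_discrete_survival_data(df, time = t, status = d)
#' @export
as_discrete_survival_data <- function(data, time, status, n_intervals = NULL) {
  stopifnot(is.data.frame(data))
  time_v <- rlang::eval_tidy(rlang::enquo(time), data)
  status_v <- rlang::eval_tidy(rlang::enquo(status), data)
  time_nm <- rlang::as_name(rlang::enquo(time))
  status_nm <- rlang::as_name(rlang::enquo(status))
  feat <- setdiff(names(data), c(time_nm, status_nm))
  feat <- feat[vapply(data[feat], is.numeric, logical(1))]
  if (!length(feat)) stop("No numeric feature columns found.", call. = FALSE)
  discrete_survival_data(time_v, status_v, as.matrix(data[feat]),
                         n_intervals = n_intervals)
}

#' @export
print.discrete_survival_data <- function(x, ...) {
  cat("Discrete survival data: ", x$n, " subjects, ", x$p, " features, ",
      x$k + 1L, " time intervals\n", sep = "")
  cat("Events: ", sum(x$status), " (",
      round(100 * mean(x$status), 1), "% uncensored)\n", sep = "")
  invisible(x)
}

#' Event matrix
#'
#' Binary `N x (K+1)` matrix with `y[i, k] = 1` exactly when subject `i`
#' experienced the event in interval `k`. Rows of censored subjects are
#' all zero, so row sums equal the event indicator.
#'
#' @param data A [discrete_survival_data] object.
#' @return Integer matrix with `K + 1` columns.
#' @export
event_matrix <- function(data) {
  stopifnot(inherits(data, "discrete_survival_data"))
  y <- matrix(0L, data$n, data$k + 1L)
  ev <- data$status == 1L
  y[cbind(which(ev), data$time[ev])] <- 1L
  colnames(y) <- paste0("interval", seq_len(ncol(y)))
  y
}

#' Response matrix and cumulative at-risk matrix
#'
#' Encodes event-or-censoring timing as a binary `N x (K+1)` matrix
#' `t_mat`, together with its reverse cumulative row sums `t_cum`
#' (`t_cum[i, k] = sum_{j >= k} t_mat[i, j]`), which indicate whether
#' subject `i` was still at risk entering interval `k`.
#'
#' Two censoring conventions are supported. Under `"start"` (the
#' default) a subject censored in interval `c` is assumed censored at the
#' start of that interval, hence known only to have survived intervals
#' `1..c-1`: `t_mat[i, k] = 1` iff the event occurred at `k` or `c = k + 1`.
#' A subject censored in interval 1 then carries no information and has
#' an all-zero row. Under `"end"` the subject is assumed censored at the
#' end of interval `c`, i.e. survived it: `t_mat[i, k] = 1` iff the
#' observed time equals `k`.
#'
#' @param data A [discrete_survival_data] object.
#' @param convention `"start"` or `"end"`.
#' @return A list with integer matrices `t_mat` and `t_cum`.
#' @export
response_matrix <- function(data, convention = c("start", "end")) {
  stopifnot(inherits(data, "discrete_survival_data"))
  convention <- match.arg(convention)
  kp1 <- data$k + 1L
  t_mat <- matrix(0L, data$n, kp1)
  ev <- data$status == 1L
  t_mat[cbind(which(ev), data$time[ev])] <- 1L
  cens <- which(!ev)
  if (convention == "start") {
    # censored in interval c: survived 1..c-1, so the marker sits at c-1
    keep <- cens[data$time[cens] >= 2L]
    t_mat[cbind(keep, data$time[keep] - 1L)] <- 1L
  } else {
    t_mat[cbind(cens, data$time[cens])] <- 1L
  }
  t_cum <- t(apply(t_mat, 1L, function(r) rev(cumsum(rev(r)))))
  storage.mode(t_cum) <- "integer"
  colnames(t_mat) <- colnames(t_cum) <- paste0("interval", seq_len(kp1))
  list(t_mat = t_mat, t_cum = t_cum)
}

#' Long-format Bernoulli records
#'
#' Expand discrete survival data into the independent Bernoulli records
#' that underpin the FCR likelihood: one record per (subject, interval)
#' pair at risk, keeping intervals `k <= K` (the final open interval has
#' discrete hazard 1 by construction and contributes only constants).
#' Records are stacked column-by-column (all subjects at interval 1,
#' then interval 2, ...), matching the wide-to-long restructuring of the
#' event matrix.
#'
#' @param data A [discrete_survival_data] object.
#' @param convention Censoring convention passed to [response_matrix()].
#' @return A tibble with columns `subject`, `interval`, `y` (0/1).
#' @export
bernoulli_long <- function(data, convention = c("start", "end")) {
  stopifnot(inherits(data, "discrete_survival_data"))
  convention <- match.arg(convention)
  y_mat <- event_matrix(data)
  t_cum <- response_matrix(data, convention)$t_cum
  if (convention == "start") {
    dropped <- sum(data$status == 0L & data$time == 1L)
    if (dropped > 0L) {
      warning(dropped, " subject(s) censored in interval 1 contribute no ",
              "Bernoulli records under the censor-at-start convention.",
              call. = FALSE)
    }
  }
  k_max <- data$k
  at_risk <- t_cum[, seq_len(k_max), drop = FALSE] == 1L
  idx <- which(at_risk, arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  tibble::tibble(
    subject = as.integer(idx[, 1L]),
    interval = as.integer(idx[, 2L]),
    y = as.integer(y_mat[idx])
  )
}

#' Reconstruct (time, status) from the event and response matrices
#'
#' Inverse of the matrix constructions, used for integrity checks. Under
#' the censor-at-start convention a subject censored in interval 1 has an
#' all-zero response row and is reported with `time = 1`, `status = 0`.
#'
#' @param y_mat Event matrix as from [event_matrix()].
#' @param t_mat Response matrix component `t_mat` from [response_matrix()].
#' @param convention Censoring convention used to build `t_mat`.
#' @return A tibble with columns `time` and `status`.
#' @export
from_matrices <- function(y_mat, t_mat, convention = c("start", "end")) {
  convention <- match.arg(convention)
  stopifnot(all(dim(y_mat) == dim(t_mat)))
  status <- as.integer(rowSums(y_mat) > 0L)
  tpos <- apply(t_mat, 1L, function(r) if (any(r == 1L)) which.max(r) else 0L)
  time <- integer(nrow(y_mat))
  ev <- status == 1L
  time[ev] <- tpos[ev]
  if (convention == "start") {
    time[!ev] <- ifelse(tpos[!ev] == 0L, 1L, tpos[!ev] + 1L)
  } else {
    time[!ev] <- tpos[!ev]
  }
  tibble::tibble(time = as.integer(time), status = status)
}
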