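#' @importFrom rlang %||% .data
NULL

# append a step to the filter trace carried on the matrix attribute
add_trace <- function(x_new, x_old, step, params) {
  old <- attr(x_old, "filter_trace")
  row <- tibble::tibble(step = step,
                        features_in = ncol(x_old), features_out = ncol(x_new),
                        parameters = params)
  attr(x_new, "filter_trace") <- dplyr::bind_rows(old, row)
  ko <- attr(x_old, "kept_index") %||% seq_len(ncol(x_old))
  keep <- match(colnames(x_new), colnames(x_old))
  attr(x_new, "kept_index") <- ko[keep]
  x_new
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("Expected a numeric matrix or data frame of features (columns).",
         call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

#' Filter trace of a preprocessed matrix
#'
#' Each filtering step records the step name, feature counts before and
#' after, and its parameters; the `kept_index` attribute maps surviving
#' columns back to the original matrix.
#'
#' @param x A matrix returned by the `filter_*` / [standardize_features()]
#'   functions.
#' @return A tibble with columns `step`, `features_in`, `features_out`,
#'   `parameters`, or `NULL` if no step has run.
#' @export
filter_trace <- function(x) attr(x, "filter_trace")

#' Drop features with missing values
#'
#' Removes every feature column containing at least one `NA`/`NaN`.
#'
#' @param x Numeric feature matrix (samples in rows) or data frame.
#' @return The filtered matrix, with an updated [filter_trace()].
#' @export
filter_missing <- function(x) {
  x <- as_feature_matrix(x)
  keep <- colSums(is.na(x)) == 0L
  add_trace(x[, keep, drop = FALSE], x, "missing", "drop any NA")
}

#' Drop features with few unique values
#'
#' Keeps features whose fraction of distinct values is at least
#' `min_unique_frac` (default 20%), removing near-constant features.
#'
#' @param x Numeric feature matrix or data frame.
#' @param min_unique_frac Minimum fraction of distinct values in (0, 1].
#' @return The filtered matrix, with an updated [filter_trace()].
#' @export
filter_low_unique <- function(x, min_unique_frac = 0.20) {
  stopifnot(min_unique_frac > 0, min_unique_frac <= 1)
  x <- as_feature_matrix(x)
  frac <- apply(x, 2L, function(v) length(unique(v))) / nrow(x)
  keep <- frac >= min_unique_frac
  add_trace(x[, keep, drop = FALSE], x, "low_unique",
            paste0("min_unique_frac=", min_unique_frac))
}

#' Drop highly correlated features
#'
#' Greedy removal: while any pair of features has `|Pearson r|` above
#' `rho_max`, the member of the worst offending pair with the larger
#' mean absolute correlation to all remaining features is dropped.
#' Deterministic given column order (ties keep the earlier column).
#'
#' @param x Numeric feature matrix or data frame, no zero-variance
#'   columns (run [filter_low_unique()] / a variance filter first).
#' @param rho_max Absolute correlation cutoff in (0, 1).
#' @return The filtered matrix, with an updated [filter_trace()].
#' @export
filter_correlated <- function(x, rho_max = 0.75) {
  stopifnot(rho_max > 0, rho_max < 1)
  x <- as_feature_matrix(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("Zero-variance feature(s) present; remove them (e.g. with ",
         "`filter_low_unique()`) before the correlation filter.",
         call. = FALSE)
  }
  cm <- abs(stats::cor(x))
  diag(cm) <- 0
  alive <- rep(TRUE, ncol(x))
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    mx <- max(sub)
    if (mx <= rho_max) break
    idx_alive <- which(alive)
    pos <- which(sub == mx, arr.ind = TRUE)[1L, ]
    pair <- idx_alive[pos]
    mean_abs <- rowMeans(sub[pos, , drop = FALSE])
    drop_local <- if (mean_abs[2L] > mean_abs[1L]) 2L else 1L
    alive[pair[drop_local]] <- FALSE
  }
  add_trace(x[, alive, drop = FALSE], x, "correlated",
            paste0("rho_max=", rho_max))
}

#' Keep the most variable features
#'
#' Retains the `top_k` features with the largest sample variance; ties
#' are broken by original column order. If fewer than `top_k` features
#' are available, all are kept with a warning.
#'
#' @param x Numeric feature matrix or data frame.
#' @param top_k Number of features to keep.
#' @return The filtered matrix (original column order preserved), with
#'   an updated [filter_trace()].
#' @export
filter_top_variance <- function(x, top_k = 1000) {
  stopifnot(top_k >= 1)
  x <- as_feature_matrix(x)
  if (top_k >= ncol(x)) {
    if (top_k > ncol(x)) {
      warning("`top_k` (", top_k, ") exceeds available features (", ncol(x),
              "); keeping all.", call. = FALSE)
    }
    return(add_trace(x, x, "top_variance", paste0("top_k=", top_k)))
  }
  v <- apply(x, 2L, stats::var)
  keep <- sort(order(-v)[seq_len(top_k)]) # stable: order() breaks ties by index
  add_trace(x[, keep, drop = FALSE], x, "top_variance",
            paste0("top_k=", top_k))
}

#' Center and scale features
#'
#' Standardizes each column to mean 0 and standard deviation 1 (n-1
#' denominator).
#'
#' @param x Numeric feature matrix or data frame without zero-variance
#'   columns.
#' @return The standardized matrix, with an updated [filter_trace()].
#' @export
standardize_features <- function(x) {
  x <- as_feature_matrix(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("Cannot standardize zero-variance feature(s).", call. = FALSE)
  }
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out <- add_trace(out, x, "standardize", "center, sd=1 (n-1)")
  out
}

#' Full preprocessing pipeline
#'
#' Applies, in order: missing-value removal, the low-unique-value
#' filter, the pairwise-correlation filter, the top-variance filter and
#' standardization — the usual preparation of a gene-expression matrix
#' for high-dimensional survival modelling.
#'
#' @param x Numeric feature matrix or data frame.
#' @param min_unique_frac Passed to [filter_low_unique()].
#' @param rho_max Passed to [filter_correlated()].
#' @param top_k Passed to [filter_top_variance()].
#' @return The processed matrix with the complete [filter_trace()].
#' @export
preprocess_features <- function(x, min_unique_frac = 0.20, rho_max = 0.75,
                                top_k = 1000) {
  x |>
    filter_missing() |>
    filter_low_unique(min_unique_frac) |>
    filter_correlated(rho_max) |>
    filter_top_variance(top_k) |>
    standardize_features()
}
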