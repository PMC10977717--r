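#' Potential scale reduction factor (classic Gelman-Rubin)
#'
#' Computes the classic (non-rank-normalized) PSRF for one parameter
#' from a `chains x draws` matrix: with within-chain variance `W` and
#' between-chain variance `B = n * var(chain means)`,
#' `PSRF = sqrt(((n - 1)/n * W + B/n) / W)`.
#'
#' Degenerate cases: if every chain is constant at the same value the
#' parameter is perfectly agreed and the PSRF is 1; if chains are
#' constant at different values the PSRF is `Inf`.
#'
#' @param x Numeric matrix, one row per chain, one column per draw.
#' @return Scalar PSRF estimate.
#' @export
psrf <- function(x) {
  stopifnot(is.matrix(x))
  m <- nrow(x)
  n <- ncol(x)
  if (m < 2L) stop("PSRF needs at least 2 chains; re-run with multiple chains.",
                   call. = FALSE)
  if (n < 10L) stop("PSRF needs at least 10 draws per chain.", call. = FALSE)
  w <- mean(apply(x, 1L, stats::var))
  b <- n * stats::var(rowMeans(x))
  if (w == 0) return(if (b == 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Convergence report for an FCR fit
#'
#' Classic Gelman-Rubin PSRF for every monitored parameter: thresholds
#' `alpha`, coefficients `beta`, indicators `gamma`, the effective
#' coefficients `beta * gamma`, and the penalty `lambda` (`K + 3P + 1`
#' monitored quantities). Values above the threshold (default 1.1)
#' indicate lack of convergence.
#'
#' @param fit An [fcr_blasso] fit with at least two chains.
#' @param threshold PSRF cutoff flagging non-convergence.
#' @return An object of class `fcr_convergence`: list with `psrf`
#'   (tibble `term`, `type`, `psrf`), `n_above`, `threshold`, and
#'   `converged`.
#' @export
convergence_report <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "fcr_blasso"))
  blocks <- c("alpha", "beta", "gamma", "betagamma", "lambda")
  res <- purrr::map_dfr(blocks, function(bl) {
    arr <- switch(bl,
      lambda = array(fit$lambda, c(nrow(fit$lambda), ncol(fit$lambda), 1L),
                     dimnames = list(NULL, NULL, "lambda")),
      betagamma = {
        a <- fit$beta * fit$gamma
        dimnames(a) <- dimnames(fit$beta)
        a
      },
      fit[[bl]])
    nm <- dimnames(arr)[[3]]
    tibble::tibble(
      term = if (bl %in% c("betagamma")) paste0(nm, "*gamma") else nm,
      type = bl,
      psrf = vapply(seq_len(dim(arr)[3]), function(j) psrf(arr[, , j]),
                    numeric(1))
    )
  })
  n_above <- sum(res$psrf > threshold, na.rm = TRUE)
  structure(
    list(psrf = res, n_above = n_above, threshold = threshold,
         converged = n_above == 0L),
    class = "fcr_convergence"
  )
}

#' @export
print.fcr_convergence <- function(x, ...) {
  cat("Convergence report:", nrow(x$psrf), "monitored parameters\n")
  cat("  PSRF >", x$threshold, ":", x$n_above, "parameter(s)\n")
  cat("  converged:", x$converged, "\n")
  if (x$n_above > 0) {
    worst <- dplyr::slice_max(x$psrf, .data$psrf, n = 5L, with_ties = FALSE)
    cat("  worst:", paste0(worst$term, " (", round(worst$psrf, 3), ")",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.fcr_convergence <- function(x, ...) x$psrf
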