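#' Prior odds for the inclusion indicator
#'
#' Under `gamma_m ~ Bernoulli(s)` the prior odds of `H_A: gamma = 1`
#' against `H_0: gamma = 0` are `s / (1 - s)`.
#'
#' @param s Prior inclusion probability, strictly inside (0, 1).
#' @return Prior odds (scalar).
#' @export
prior_odds_gamma <- function(s) {
  if (!is.numeric(s) || s <= 0 || s >= 1) {
    stop("`s` must lie strictly between 0 and 1.", call. = FALSE)
  }
  s / (1 - s)
}

#' Prior odds for the coefficient interval hypothesis
#'
#' For the marginal prior of `beta` obtained by integrating the Laplace
#' prior over `lambda ~ Gamma(a, b)` (density proportional to
#' `(b + |beta|)^(-(a+1))`), the tail probability is
#' `Pr(|beta| > eps) = (b/(b+eps))^a`, so the prior odds of
#' `H_A: |beta| > eps` against `H_0: |beta| <= eps` are
#' `b^a / ((b + eps)^a - b^a)`. This is also the `s -> 1` limit of
#' [prior_odds_betagamma()]. At `eps = 0` the null has prior probability
#' zero and the odds are `Inf`.
#'
#' @param a,b Shape and rate of the Gamma prior on `lambda`.
#' @param eps Half-width of the interval null, `eps >= 0`.
#' @return Prior odds (scalar).
#' @export
prior_odds_beta <- function(a, b, eps) {
  stopifnot(a > 0, b > 0, eps >= 0)
  if (eps == 0) return(Inf)
  b^a / ((b + eps)^a - b^a)
}

#' Prior odds for the effective-coefficient interval hypothesis
#'
#' For the product `gamma * beta` with independent `gamma ~ Bernoulli(s)`
#' and marginal `beta` as in [prior_odds_beta()], the prior odds of
#' `H_A: |gamma * beta| > eps` against `H_0: |gamma * beta| <= eps` are
#'
#' `s * b^a / ( s * ((b+eps)^a - b^a) + (1-s) * (b+eps)^a )`
#'
#' (the `Gamma(a+1)/ (a Gamma(a))` factors of the underlying integrals
#' cancel). `H_0` absorbs the point mass `Pr(gamma = 0)`.
#'
#' @inheritParams prior_odds_beta
#' @param s Prior inclusion probability in (0, 1).
#' @return Prior odds (scalar).
#' @export
prior_odds_betagamma <- function(a, b, eps, s) {
  stopifnot(a > 0, b > 0, eps > 0, s > 0, s < 1)
  num <- s * b^a
  den <- s * ((b + eps)^a - b^a) + (1 - s) * (b + eps)^a
  num / den
}

#' Bayes factor from an empirical posterior event frequency
#'
#' `BF = posterior odds / prior odds`, where the posterior odds are
#' `f / (1 - f)` for the fraction `f` of pooled posterior draws
#' satisfying the alternative. Boundary draws are not smoothed: `f = 1`
#' returns `Inf` (selected at any finite threshold) and `f = 0` returns
#' 0; callers can apply their own continuity correction from the raw
#' draw counts.
#'
#' @param f Posterior event frequency in \[0, 1\]; vectorized.
#' @param prior_odds Positive prior odds of the same hypothesis.
#' @return Bayes factor(s).
#' @export
bayes_factor <- function(f, prior_odds) {
  if (any(prior_odds <= 0)) stop("`prior_odds` must be positive.", call. = FALSE)
  stopifnot(all(f >= 0 & f <= 1))
  ifelse(f == 1, Inf, (f / (1 - f)) / prior_odds)
}

#' Feature selection from a Bayesian LASSO FCR fit
#'
#' Applies one or more of the selection rules to pooled posterior draws:
#' \describe{
#'   \item{CI / HPDI}{select features whose `level` equal-tailed credible
#'     (or highest posterior density) interval for the effective
#'     coefficient `beta * gamma` excludes zero (set
#'     `use_betagamma = FALSE` for intervals on `beta` alone).}
#'   \item{PrGamma}{select features whose posterior inclusion
#'     probability `Pr(gamma_m | Data)` exceeds `threshold` (default 0.5).}
#'   \item{BF_beta / BF_betagamma / BF_gamma}{Bayes factors for
#'     `|beta| > eps`, `|gamma beta| > eps` and `gamma = 1` with the
#'     matching closed-form prior odds; select when BF exceeds
#'     `threshold` (default 5).}
#' }
#'
#' @param fit An [fcr_blasso] fit.
#' @param method Character vector of rules among `"CI"`, `"HPDI"`,
#'   `"PrGamma"`, `"BF_beta"`, `"BF_betagamma"`, `"BF_gamma"`.
#' @param threshold Selection threshold; default 5 for Bayes-factor
#'   rules and 0.5 for `PrGamma` (ignored by CI/HPDI).
#' @param level Interval coverage for CI/HPDI (default 0.95).
#' @param epsilon Interval-null half-width for the `beta`/`betagamma`
#'   Bayes factors; defaults to the fitted spec's `epsilon`.
#' @param use_betagamma Use the effective coefficient for CI/HPDI
#'   (default `TRUE`).
#' @return A tibble with one row per feature and method: `term`,
#'   `method`, `evidence` (Bayes factor, inclusion probability, or the
#'   interval's signed margin from zero), `lower`/`upper` interval
#'   bounds where applicable, `n_sat`/`n_draws` raw counts behind
#'   empirical frequencies, `selected`, `threshold`, `epsilon`, `s`.
#' @export
select_features <- function(fit, method = c("BF_gamma", "CI", "HPDI",
                                            "PrGamma", "BF_beta",
                                            "BF_betagamma"),
                            threshold = NULL, level = 0.95, epsilon = NULL,
                            use_betagamma = TRUE) {
  stopifnot(inherits(fit, "fcr_blasso"))
  method <- match.arg(method, several.ok = TRUE)
  if (is.null(epsilon)) epsilon <- fit$spec$epsilon
  s <- fit$spec$s
  a <- fit$spec$a
  b <- fit$spec$b
  beta <- pooled_draws(fit, "beta")
  gam <- pooled_draws(fit, "gamma")
  bg <- beta * gam
  n_draws <- nrow(beta)
  terms <- fit$feature_names

  one <- function(meth) {
    if (meth %in% c("CI", "HPDI")) {
      dr <- if (use_betagamma) bg else beta
      ints <- if (meth == "CI") {
        qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
        t(apply(dr, 2L, stats::quantile, probs = qs, names = FALSE))
      } else {
        t(apply(dr, 2L, hpd_interval, level = level))
      }
      lower <- unname(ints[, 1L]); upper <- unname(ints[, 2L])
      sel <- lower > 0 | upper < 0
      tibble::tibble(
        term = terms, method = meth,
        evidence = ifelse(lower > 0, lower, ifelse(upper < 0, upper, 0)),
        lower = lower, upper = upper,
        n_sat = NA_integer_, n_draws = n_draws,
        selected = sel, threshold = level, epsilon = NA_real_, s = s)
    } else if (meth == "PrGamma") {
      thr <- if (is.null(threshold)) 0.5 else threshold
      pg <- unname(colMeans(gam))
      tibble::tibble(
        term = terms, method = meth, evidence = pg,
        lower = NA_real_, upper = NA_real_,
        n_sat = as.integer(colSums(gam)), n_draws = n_draws,
        selected = pg > thr, threshold = thr, epsilon = NA_real_, s = s)
    } else {
      thr <- if (is.null(threshold)) 5 else threshold
      sat <- switch(meth,
        BF_beta = abs(beta) > epsilon,
        BF_betagamma = abs(bg) > epsilon,
        BF_gamma = gam == 1)
      po <- switch(meth,
        BF_beta = prior_odds_beta(a, b, epsilon),
        BF_betagamma = prior_odds_betagamma(a, b, epsilon, s),
        BF_gamma = prior_odds_gamma(s))
      n_sat <- unname(colSums(sat))
      bf <- bayes_factor(n_sat / n_draws, po)
      tibble::tibble(
        term = terms, method = meth, evidence = bf,
        lower = NA_real_, upper = NA_real_,
        n_sat = as.integer(n_sat), n_draws = n_draws,
        selected = bf > thr, threshold = thr,
        epsilon = if (meth == "BF_gamma") NA_real_ else epsilon, s = s)
    }
  }
  dplyr::bind_rows(lapply(method, one))
}

#' Write a selection table to delimited text
#'
#' @param selection Tibble from [select_features()].
#' @param path Output path (`.csv` comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  write_delim_auto(as.data.frame(selection), path)
  invisible(path)
}
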