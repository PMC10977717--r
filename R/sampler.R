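#' Model specification for the Bayesian LASSO FCR model
#'
#' Hyperparameters of the hierarchical model: `alpha_k ~ Normal(0, sigma2)`,
#' `beta_m | lambda ~ Laplace(0, 1/lambda)` (density `(lambda/2) exp(-lambda
#' |beta|)`), `lambda ~ Gamma(a, b)` with rate `b`, and `gamma_m ~
#' Bernoulli(s)` variable-inclusion indicators.
#'
#' @param a,b Shape and rate of the Gamma prior on the penalty `lambda`.
#' @param s Prior inclusion probability of each feature, in (0, 1).
#' @param sigma2 Variance of the Normal prior on each threshold `alpha_k`.
#' @param epsilon Half-width of the interval null `|beta| <= epsilon` used
#'   by the Bayes-factor selection rules; a small positive value.
#' @param convention Censoring convention, `"start"` (censoring at the
#'   beginning of the recorded interval, the default) or `"end"`.
#' @param fixed_lambda Optional positive value at which to freeze the
#'   penalty instead of sampling it (plain LASSO-style fit).
#' @param fix_gamma If `TRUE`, all inclusion indicators are held at 1,
#'   reducing the model to a plain Bayesian LASSO FCR.
#' @return An object of class `fcr_model_spec`.
#' @export
fcr_model_spec <- function(a = 1, b = 1, s = 0.1, sigma2 = 100,
                           epsilon = 0.05, convention = c("start", "end"),
                           fixed_lambda = NULL, fix_gamma = FALSE) {
  convention <- match.arg(convention)
  stopifnot(a > 0, b > 0, s > 0, s < 1, sigma2 > 0, epsilon > 0)
  if (!is.null(fixed_lambda)) stopifnot(fixed_lambda > 0)
  structure(
    list(a = a, b = b, s = s, sigma2 = sigma2, epsilon = epsilon,
         convention = convention, fixed_lambda = fixed_lambda,
         fix_gamma = isTRUE(fix_gamma)),
    class = "fcr_model_spec"
  )
}

#' MCMC schedule
#'
#' Defaults follow the reference protocol: 500 adaptation sweeps (during
#' which random-walk proposal scales tune towards 44% acceptance and are
#' then frozen), 500 burn-in sweeps, 3 chains thinned every third sweep,
#' and 9,999 retained draws in total across chains.
#'
#' @param n_adapt,n_burnin Adaptation and burn-in sweeps per chain.
#' @param n_chains Number of independent chains.
#' @param thin Thinning stride.
#' @param n_saved_total Total retained draws across all chains; must be
#'   divisible by `n_chains`.
#' @return An object of class `mcmc_schedule`.
#' @export
mcmc_schedule <- function(n_adapt = 500, n_burnin = 500, n_chains = 3,
                          thin = 3, n_saved_total = 9999) {
  stopifnot(n_adapt >= 0, n_burnin >= 0, n_chains >= 1, thin >= 1,
            n_saved_total >= n_chains)
  if (n_saved_total %% n_chains != 0) {
    stop("`n_saved_total` must be divisible by `n_chains`.", call. = FALSE)
  }
  structure(
    list(n_adapt = as.integer(n_adapt), n_burnin = as.integer(n_burnin),
         n_chains = as.integer(n_chains), thin = as.integer(thin),
         n_saved_total = as.integer(n_saved_total)),
    class = "mcmc_schedule"
  )
}

#' Fit the Bayesian LASSO FCR model by Metropolis-within-Gibbs
#'
#' Expands the data into long-format Bernoulli records under the chosen
#' censoring convention and samples the posterior of the hierarchical
#' clog-log FCR model. Per sweep: each threshold `alpha_k` and each
#' active coefficient `beta_m` moves by adaptive random-walk Metropolis;
#' an inactive `beta_m` (its indicator off) is refreshed from its
#' Laplace prior, which is its exact full conditional; each `gamma_m` is
#' drawn from its exact Bernoulli full conditional; and `lambda` from
#' its conjugate `Gamma(a + P, b + sum|beta|)` full conditional.
#'
#' @param data A [discrete_survival_data] object, or a data frame (then
#'   `time` and `status` name the outcome columns and all other numeric
#'   columns are features).
#' @param spec An [fcr_model_spec()].
#' @param schedule An [mcmc_schedule()].
#' @param seed Master RNG seed; per-chain streams are derived from it, so
#'   identical `seed` + schedule reproduce the draws exactly.
#' @param time,status Outcome columns when `data` is a data frame.
#' @param prior_only If `TRUE`, the likelihood is dropped and the sampler
#'   explores the joint prior (for validation studies).
#' @return An object of class `fcr_blasso`: posterior arrays
#'   (`chain x draw x parameter`) for `alpha`, `beta`, `gamma`, `lambda`,
#'   per-chain acceptance rates, and the spec/schedule/seed metadata.
#' @examples
#' sim <- simulate_dataset(simulation_design(n = 60, p = 4, n_true_pos = 1,
#'                                           n_true_neg = 1), seed = 7)
#' fit <- fcr_blasso(sim$data, fcr_model_spec(s = 0.5),
#'                   mcmc_schedule(50, 50, 2, 1, 100), seed = 1)
#' glance(fit)
#' @export
fcr_blasso <- function(data, spec = fcr_model_spec(),
                       schedule = mcmc_schedule(), seed = 1L,
                       time = "time", status = "status",
                       prior_only = FALSE) {
  if (is.data.frame(data)) {
    data <- as_discrete_survival_data(data, time = !!rlang::sym(time),
                                      status = !!rlang::sym(status))
  }
  stopifnot(inherits(data, "discrete_survival_data"),
            inherits(spec, "fcr_model_spec"),
            inherits(schedule, "mcmc_schedule"))

  long <- suppressWarnings(bernoulli_long(data, spec$convention))
  if (nrow(long) == 0L && !prior_only) {
    stop("No at-risk Bernoulli records (all subjects censored in interval 1 ",
         "under the censor-at-start convention); nothing to fit.", call. = FALSE)
  }

  n_save <- schedule$n_saved_total %/% schedule$n_chains
  k <- data$k
  p <- data$p

  # crude threshold start: clog-log of the pooled per-record event rate
  rate <- if (nrow(long)) max(min(mean(long$y), 0.95), 0.05) else 0.2
  alpha0 <- rep(log(-log(1 - rate)), k)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, schedule$n_chains)

  chains <- vector("list", schedule$n_chains)
  for (c in seq_len(schedule$n_chains)) {
    set.seed(chain_seeds[c])
    gamma0 <- if (spec$fix_gamma) rep(1L, p) else stats::rbinom(p, 1L, spec$s)
    chains[[c]] <- fcr_blasso_chain(
      rec_i = long$subject - 1L, rec_k = long$interval - 1L, rec_y = long$y,
      X = data$x, K = k,
      a = spec$a, b = spec$b, s = spec$s, sigma2 = spec$sigma2,
      fix_gamma = spec$fix_gamma,
      fixed_lambda = if (is.null(spec$fixed_lambda)) NA_real_ else spec$fixed_lambda,
      prior_only = prior_only,
      n_adapt = schedule$n_adapt, n_burnin = schedule$n_burnin,
      n_save = n_save, thin = schedule$thin,
      alpha0 = alpha0, beta0 = rep(0, p), gamma0 = gamma0,
      lambda0 = spec$a / spec$b)
  }

  bind3 <- function(field, nm) {
    arr <- array(NA_real_, c(schedule$n_chains, n_save, length(nm)),
                 dimnames = list(NULL, NULL, nm))
    for (c in seq_along(chains)) arr[c, , ] <- as.matrix(chains[[c]][[field]])
    arr
  }
  feat <- colnames(data$x)
  fit <- structure(
    list(
      alpha = bind3("alpha", paste0("alpha", seq_len(k))),
      beta = bind3("beta", feat),
      gamma = bind3("gamma", feat),
      lambda = t(vapply(chains, function(ch) as.numeric(ch$lambda),
                        numeric(n_save))),
      loglik = t(vapply(chains, function(ch) as.numeric(ch$loglik),
                        numeric(n_save))),
      accept = list(
        alpha = t(vapply(chains, function(ch) as.numeric(ch$accept_alpha),
                         numeric(k))),
        beta = t(vapply(chains, function(ch) as.numeric(ch$accept_beta),
                        numeric(p)))),
      spec = spec, schedule = schedule, seed = seed,
      chain_seeds = chain_seeds, feature_names = feat,
      dims = list(n = data$n, p = p, k = k),
      n_records = nrow(long), prior_only = prior_only),
    class = "fcr_blasso"
  )
  if (schedule$n_chains == 1L) {
    fit$lambda <- matrix(fit$lambda, nrow = 1L)
    fit$loglik <- matrix(fit$loglik, nrow = 1L)
  }
  fit
}

#' @export
print.fcr_blasso <- function(x, ...) {
  cat("Bayesian LASSO FCR fit\n")
  cat("  data: N =", x$dims$n, ", P =", x$dims$p, ", K =", x$dims$k,
      "(", x$n_records, "Bernoulli records )\n")
  cat("  prior inclusion s =", x$spec$s, "; censoring convention:",
      x$spec$convention, "\n")
  cat("  chains:", x$schedule$n_chains, "x", dim(x$beta)[2], "retained draws",
      "(thin", x$schedule$thin, ")\n")
  cat("  posterior mean lambda:", round(mean(x$lambda), 3), "\n")
  invisible(x)
}

# pooled draws (all chains stacked) for one parameter block
pooled_draws <- function(fit, block = c("beta", "gamma", "alpha", "lambda",
                                        "betagamma")) {
  block <- match.arg(block)
  if (block == "lambda") {
    return(matrix(as.numeric(t(fit$lambda)), ncol = 1L,
                  dimnames = list(NULL, "lambda")))
  }
  arr <- if (block == "betagamma") fit$beta * fit$gamma else fit[[block]]
  nc <- dim(arr)[1]; nd <- dim(arr)[2]; np <- dim(arr)[3]
  out <- matrix(NA_real_, nc * nd, np)
  for (c in seq_len(nc)) out[seq_len(nd) + (c - 1L) * nd, ] <- arr[c, , ]
  colnames(out) <- if (block == "betagamma") {
    dimnames(fit$beta)[[3]]
  } else dimnames(arr)[[3]]
  out
}

#' Highest posterior density interval of a sample
#'
#' Shortest interval containing a `level` fraction of the draws
#' (empirical HPD for a unimodal posterior).
#'
#' @param x Numeric draws.
#' @param level Coverage level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(m + 1L):n] - x[seq_len(n - m)]
  j <- which.min(widths)
  c(lower = x[j], upper = x[j + m])
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, median, equal-tailed credible interval
#' and HPD interval, pooled across chains. Includes the thresholds,
#' coefficients, effective coefficients (`beta * gamma`), inclusion
#' indicators and the penalty.
#'
#' @param fit An [fcr_blasso] fit.
#' @param level Interval coverage (default 0.95).
#' @return A tibble with columns `term`, `type`, `mean`, `median`,
#'   `lower`, `upper`, `hpd_lower`, `hpd_upper`.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fcr_blasso"), level > 0, level < 1)
  one_block <- function(block) {
    d <- pooled_draws(fit, block)
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    purrr::map_dfr(seq_len(ncol(d)), function(j) {
      v <- d[, j]
      ci <- stats::quantile(v, qs, names = FALSE)
      hpd <- hpd_interval(v, level)
      tibble::tibble(term = colnames(d)[j], type = block,
                     mean = mean(v), median = stats::median(v),
                     lower = ci[1], upper = ci[2],
                     hpd_lower = hpd[[1]], hpd_upper = hpd[[2]])
    })
  }
  dplyr::bind_rows(lapply(c("alpha", "beta", "betagamma", "gamma", "lambda"),
                          one_block))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Bayesian LASSO FCR fit
#'
#' @param x An [fcr_blasso] fit.
#' @param level Interval coverage for `conf.low`/`conf.high`.
#' @param type Parameter block(s) to return.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `type`,
#'   `estimate` (posterior mean), `median`, `conf.low`, `conf.high`
#'   (equal-tailed), `hpd_lower`, `hpd_upper`.
#' @export
tidy.fcr_blasso <- function(x, level = 0.95,
                            type = c("beta", "betagamma", "gamma", "alpha",
                                     "lambda"), ...) {
  type <- match.arg(type, several.ok = TRUE)
  out <- posterior_summary(x, level)
  out <- dplyr::filter(out, .data$type %in% !!type)
  dplyr::rename(out, estimate = "mean", conf.low = "lower",
                conf.high = "upper")
}

#' Glance at a Bayesian LASSO FCR fit
#'
#' @param x An [fcr_blasso] fit.
#' @param ... Unused.
#' @return A one-row tibble with data dimensions, schedule, posterior
#'   mean penalty and convergence summary.
#' @export
glance.fcr_blasso <- function(x, ...) {
  conv <- convergence_report(x)
  tibble::tibble(
    n = x$dims$n, p = x$dims$p, k = x$dims$k,
    n_records = x$n_records,
    n_chains = x$schedule$n_chains, n_draws = dim(x$beta)[2],
    s = x$spec$s, epsilon = x$spec$epsilon,
    mean_lambda = mean(x$lambda),
    max_psrf = max(conv$psrf$psrf, na.rm = TRUE),
    n_psrf_above = conv$n_above,
    converged = conv$converged
  )
}

#' Posterior interval plot
#'
#' Caterpillar plot of the effective coefficients `beta * gamma` with
#' equal-tailed credible intervals, most extreme posterior means first.
#'
#' @param object An [fcr_blasso] fit.
#' @param level Interval coverage.
#' @param n_terms Number of features shown (by absolute posterior mean).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fcr_blasso <- function(object, level = 0.95, n_terms = 30, ...) {
  tt <- tidy(object, level = level, type = "betagamma")
  tt <- dplyr::slice_max(tt, abs(.data$estimate), n = n_terms,
                         with_ties = FALSE)
  tt <- dplyr::mutate(tt, term = stats::reorder(.data$term, .data$estimate))
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "effective coefficient (beta * gamma)", y = NULL,
                  title = "Posterior effective coefficients")
}
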