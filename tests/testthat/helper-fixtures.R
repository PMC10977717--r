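# Shared fixtures and oracles, all generated in code.

# random discrete survival data with given dimensions
random_dsd <- function(n = 30, p = 3, n_intervals = 5, seed = 1,
                       censor_prob = 0.3) {
  set.seed(seed)
  time <- sample.int(n_intervals, n, replace = TRUE)
  status <- stats::rbinom(n, 1, 1 - censor_prob)
  if (!any(status == 1)) status[1] <- 1L
  x <- matrix(stats::rnorm(n * p), n, p)
  discrete_survival_data(time, status, x, n_intervals = n_intervals)
}

# brute-force event matrix by double loop
brute_event_matrix <- function(time, status, n_intervals) {
  y <- matrix(0L, length(time), n_intervals)
  for (i in seq_along(time)) {
    for (k in seq_len(n_intervals)) {
      if (status[i] == 1L && time[i] == k) y[i, k] <- 1L
    }
  }
  y
}

# brute-force long-format records: (i, k, y) whenever t_cum[i,k]=1, k <= K
brute_long <- function(y_mat, t_cum, k_max) {
  out <- NULL
  for (k in seq_len(k_max)) {
    for (i in seq_len(nrow(y_mat))) {
      if (t_cum[i, k] == 1L) out <- rbind(out, c(i, k, y_mat[i, k]))
    }
  }
  tibble::tibble(subject = as.integer(out[, 1]), interval = as.integer(out[, 2]),
                 y = as.integer(out[, 3]))
}

# direct product-form likelihood, censor at interval start: for delta=1,
# pi_{k_i} * prod_{j<k_i}(1-pi_j); for delta=0 censored at c, survived
# intervals 1..c-1: prod_{j<=c-1}(1-pi_j). Hazard of final interval is 1.
brute_lik_start <- function(data, alpha, beta) {
  eta <- drop(data$x %*% beta)
  hz <- function(i, k) {
    if (k > data$k) 1 else cloglog_hazard(alpha[k], eta[i])
  }
  ll <- 0
  for (i in seq_len(data$n)) {
    ti <- data$time[i]
    if (data$status[i] == 1L) {
      term <- log(hz(i, ti))
      if (ti > 1) for (j in seq_len(ti - 1)) term <- term + log(1 - hz(i, j))
    } else {
      term <- 0
      if (ti > 1) for (j in seq_len(ti - 1)) term <- term + log(1 - hz(i, j))
    }
    ll <- ll + term
  }
  ll
}

# direct evaluation of the censor-at-end product form
brute_lik_end <- function(data, alpha, beta) {
  eta <- drop(data$x %*% beta)
  hz <- function(i, k) {
    if (k > data$k) 1 else cloglog_hazard(alpha[k], eta[i])
  }
  ll <- 0
  for (i in seq_len(data$n)) {
    ti <- data$time[i]
    if (data$status[i] == 1L) {
      term <- log(hz(i, ti))
      if (ti > 1) for (j in seq_len(ti - 1)) term <- term + log(1 - hz(i, j))
    } else {
      term <- 0
      for (j in seq_len(ti)) if (j <= data$k) term <- term + log(1 - hz(i, j))
    }
    ll <- ll + term
  }
  ll
}

# minimal hand-built fit object for selection-rule oracles
fake_fit <- function(beta_arr, gamma_arr, spec = fcr_model_spec(s = 0.1),
                     lambda = NULL) {
  nc <- dim(beta_arr)[1]; nd <- dim(beta_arr)[2]; np <- dim(beta_arr)[3]
  nm <- dimnames(beta_arr)[[3]] %||% paste0("V", seq_len(np))
  dimnames(beta_arr) <- dimnames(gamma_arr) <- list(NULL, NULL, nm)
  k <- 2L
  structure(
    list(alpha = array(0, c(nc, nd, k), dimnames = list(NULL, NULL, c("alpha1", "alpha2"))),
         beta = beta_arr, gamma = gamma_arr,
         lambda = if (is.null(lambda)) matrix(1, nc, nd) else lambda,
         loglik = matrix(0, nc, nd),
         accept = list(), spec = spec,
         schedule = mcmc_schedule(1, 1, nc, 1, nc * nd),
         seed = 1L, feature_names = nm,
         dims = list(n = 10L, p = np, k = k), n_records = 10L,
         prior_only = FALSE),
    class = "fcr_blasso")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pooled chains x draws -> matrix, via the package's internal pooling
pooled_draws_for_test <- function(fit, block) {
  bayesfcr:::pooled_draws(fit, block)
}
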