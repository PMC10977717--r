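test_that("identical seed and schedule reproduce draws exactly", {
  sim <- simulate_dataset(simulation_design(n = 60, p = 5, n_true_pos = 1,
                                            n_true_neg = 1), seed = 3)
  sch <- mcmc_schedule(50, 50, 2, 2, 100)
  f1 <- fcr_blasso(sim$data, fcr_model_spec(s = 0.2), sch, seed = 11)
  f2 <- fcr_blasso(sim$data, fcr_model_spec(s = 0.2), sch, seed = 11)
  f3 <- fcr_blasso(sim$data, fcr_model_spec(s = 0.2), sch, seed = 12)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$gamma, f2$gamma)
  expect_false(identical(f1$beta, f3$beta))
})

test_that("sampler refuses data with no at-risk records", {
  d <- discrete_survival_data(c(1, 1), c(1, 0), matrix(rnorm(4), 2, 2),
                              n_intervals = 3)
  d$status <- c(0L, 0L) # force the degenerate all-censored-at-1 case
  d$time <- c(1L, 1L)
  expect_error(fcr_blasso(d, fcr_model_spec(), mcmc_schedule(10, 10, 2, 1, 10)),
               "at-risk")
  expect_error(discrete_survival_data(c(2, 3), c(0, 0), matrix(0, 2, 1)),
               "No events")
})

test_that("prior-only sampling recovers the marginal priors of lambda and beta", {
  d <- discrete_survival_data(rep(1:2, 5), rep(1, 10), matrix(rnorm(50), 10, 5),
                              n_intervals = 3)
  a <- 2; b <- 1.5
  fit <- fcr_blasso(d, fcr_model_spec(a = a, b = b, s = 0.1),
                    mcmc_schedule(100, 100, 2, 10, 5000), seed = 42,
                    prior_only = TRUE)
  lam <- as.numeric(fit$lambda)
  ks_lam <- suppressWarnings(ks.test(lam, pgamma, shape = a, rate = b))
  expect_gt(ks_lam$p.value, 0.01)

  # marginal prior of beta integrates the Laplace over Gamma(a, b):
  # F(v) = 0.5 (b/(b-v))^a for v < 0, 1 - 0.5 (b/(b+v))^a for v >= 0
  pmarg <- function(v) ifelse(v < 0, 0.5 * (b / (b - v))^a,
                              1 - 0.5 * (b / (b + v))^a)
  bet <- pooled_draws_for_test(fit, "beta")
  for (j in c(1, 3)) {
    ks_b <- suppressWarnings(ks.test(bet[, j], pmarg))
    expect_gt(ks_b$p.value, 0.01)
  }

  # gamma draws are exact 0/1 with mean near s
  g <- pooled_draws_for_test(fit, "gamma")
  expect_true(all(g %in% c(0, 1)))
  expect_lt(abs(mean(g) - 0.1), 0.02)
})

test_that("lambda is drawn from its conjugate Gamma(a + P, b + sum|beta|) conditional", {
  sim <- simulate_dataset(simulation_design(n = 80, p = 6, n_true_pos = 1,
                                            n_true_neg = 1), seed = 5)
  a <- 1; b <- 1
  fit <- fcr_blasso(sim$data, fcr_model_spec(a = a, b = b, s = 0.3),
                    mcmc_schedule(200, 200, 2, 3, 2000), seed = 9)
  lam <- as.numeric(t(fit$lambda))
  bet <- pooled_draws_for_test(fit, "beta")
  # within a saved sweep, lambda was drawn after beta: the PIT against the
  # conjugate conditional must be uniform
  u <- pgamma(lam, shape = a + ncol(bet), rate = b + rowSums(abs(bet)))
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("tiny-instance posterior means match dense grid integration", {
  set.seed(2)
  n <- 20
  x <- matrix(rnorm(n * 2), n, 2)
  x <- scale(x)
  time <- sample.int(3, n, replace = TRUE)
  status <- rbinom(n, 1, 0.8)
  status[1] <- 1L
  d <- discrete_survival_data(time, status, x, n_intervals = 3)

  lam <- 1
  fit <- fcr_blasso(d, fcr_model_spec(fixed_lambda = lam, fix_gamma = TRUE,
                                      sigma2 = 100),
                    mcmc_schedule(500, 500, 3, 3, 6000), seed = 21)

  # dense-grid posterior: flat-ish Normal(0, 100) prior on alpha, Laplace
  # prior on beta; the likelihood factorizes over intervals given beta
  long <- suppressWarnings(bernoulli_long(d))
  ga <- seq(-4, 2, length.out = 41)
  gb <- seq(-2.5, 2.5, length.out = 41)
  nb <- length(gb)
  post_sum <- matrix(0, 4, 1) # running means for alpha1, alpha2, beta1, beta2
  tot <- 0
  wts_a <- dnorm(ga, 0, 10)
  for (i1 in seq_len(nb)) for (i2 in seq_len(nb)) {
    beta <- c(gb[i1], gb[i2])
    eta <- drop(x %*% beta)
    ll_k <- sapply(1:2, function(k) {
      rows <- long$interval == k
      sapply(ga, function(av) {
        lp <- av + eta[long$subject[rows]]
        pi <- -expm1(-exp(pmin(pmax(lp, -30), 30)))
        sum(ifelse(long$y[rows] == 1, log(pi), log(1 - pi)))
      })
    })
    w1 <- exp(ll_k[, 1]) * wts_a
    w2 <- exp(ll_k[, 2]) * wts_a
    wprior_b <- exp(-lam * sum(abs(beta)))
    mass <- sum(w1) * sum(w2) * wprior_b
    tot <- tot + mass
    post_sum[1] <- post_sum[1] + sum(w1 * ga) * sum(w2) * wprior_b
    post_sum[2] <- post_sum[2] + sum(w1) * sum(w2 * ga) * wprior_b
    post_sum[3] <- post_sum[3] + mass * beta[1]
    post_sum[4] <- post_sum[4] + mass * beta[2]
  }
  grid_means <- post_sum / tot

  draws <- cbind(pooled_draws_for_test(fit, "alpha"),
                 pooled_draws_for_test(fit, "beta"))
  mc_mean <- colMeans(draws)
  mc_se <- apply(draws, 2, function(v) {
    neff <- min(coda::effectiveSize(v), length(v))
    sd(v) / sqrt(max(neff, 50))
  })
  for (j in 1:4) {
    expect_lt(abs(mc_mean[j] - grid_means[j]), 3 * mc_se[j] + 0.03)
  }
})

test_that("the sampler recovers strong planted effects", {
  design <- simulation_design(n = 300, p = 20, n_true_pos = 2, n_true_neg = 1,
                              block_size = 5, rho = 0.5)
  hits <- 0
  reps <- 6
  for (r in seq_len(reps)) {
    sim <- simulate_dataset(design, seed = 100 + r)
    fit <- fcr_blasso(sim$data, fcr_model_spec(s = 0.1),
                      mcmc_schedule(300, 300, 2, 2, 600), seed = 200 + r)
    bg <- colMeans(pooled_draws_for_test(fit, "beta") *
                   pooled_draws_for_test(fit, "gamma"))
    pg <- colMeans(pooled_draws_for_test(fit, "gamma"))
    truth <- sim$truth$idx
    signs_ok <- all(sign(bg[truth]) == sign(sim$truth$beta[truth]))
    top_ok <- setequal(order(-pg)[seq_along(truth)], truth)
    if (signs_ok && top_ok) hits <- hits + 1
  }
  expect_gte(hits, reps - 1)
})

test_that("posterior summaries behave on known draws", {
  # constant draws collapse to a point
  fit <- fake_fit(array(2, c(2, 50, 1)), array(1, c(2, 50, 1)))
  ps <- posterior_summary(fit)
  row <- ps[ps$type == "beta", ]
  expect_equal(row$mean, 2)
  expect_equal(c(row$lower, row$upper, row$hpd_lower, row$hpd_upper),
               rep(2, 4))

  # large normal sample: equal-tailed interval near +/- 1.96
  set.seed(7)
  z <- array(rnorm(10000), c(2, 5000, 1))
  fitz <- fake_fit(z, array(1, c(2, 5000, 1)))
  rz <- posterior_summary(fitz, 0.95)
  rz <- rz[rz$type == "beta", ]
  expect_equal(rz$lower, -1.96, tolerance = 0.05)
  expect_equal(rz$upper, 1.96, tolerance = 0.05)

  # HPD of a skewed sample is no wider than the equal-tailed interval
  set.seed(8)
  sk <- rexp(5000)
  hpd <- hpd_interval(sk, 0.95)
  et <- quantile(sk, c(0.025, 0.975), names = FALSE)
  expect_lte(hpd[2] - hpd[1], et[2] - et[1] + 1e-9)
})

test_that("tidy and glance expose the fit in broom form", {
  sim <- simulate_dataset(simulation_design(n = 60, p = 4, n_true_pos = 1,
                                            n_true_neg = 1), seed = 1)
  fit <- fcr_blasso(sim$data, fcr_model_spec(s = 0.3),
                    mcmc_schedule(50, 50, 2, 1, 200), seed = 2)
  td <- tidy(fit, type = "beta")
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4L)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$p, 4L)
  p <- ggplot2::autoplot(fit, n_terms = 4)
  expect_s3_class(p, "ggplot")
})
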