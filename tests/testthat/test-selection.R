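test_that("prior odds for gamma follow s/(1-s)", {
  expect_equal(prior_odds_gamma(0.5), 1)
  expect_equal(prior_odds_gamma(0.1), 1 / 9, tolerance = 1e-12)
  expect_equal(prior_odds_gamma(0.01), 1 / 99, tolerance = 1e-12)
  expect_error(prior_odds_gamma(0), "between")
  expect_error(prior_odds_gamma(1), "between")
})

test_that("beta prior odds match quadrature of the marginal prior", {
  # marginal prior after integrating Laplace over Gamma(a, b):
  # f(v) = (a b^a / 2) (b + |v|)^(-(a+1))
  for (par in list(c(1, 1, 0.1), c(2, 0.5, 0.05), c(0.7, 2, 0.3))) {
    a <- par[1]; b <- par[2]; eps <- par[3]
    f <- function(v) (a * b^a / 2) * (b + abs(v))^(-(a + 1))
    p_in <- integrate(f, -eps, eps, rel.tol = 1e-12)$value
    p_out <- 1 - p_in
    expect_equal(prior_odds_beta(a, b, eps), p_out / p_in, tolerance = 1e-8)
  }
  # eps = 0: the interval null has prior probability zero
  expect_identical(prior_odds_beta(1, 1, 0), Inf)
  expect_equal(prior_odds_beta(1, 1, 0.1), 10, tolerance = 1e-8)
  expect_equal(prior_odds_beta(2, 0.5, 0.05), 0.25 / 0.0525, tolerance = 1e-8)
  # consistency: the s -> 1 limit of the effective-coefficient odds
  expect_equal(prior_odds_beta(1.3, 0.9, 0.2),
               prior_odds_betagamma(1.3, 0.9, 0.2, 1 - 1e-13),
               tolerance = 1e-6)
})

test_that("effective-coefficient prior odds match Monte Carlo and their limits", {
  a <- 1; b <- 1; eps <- 0.1; s <- 0.5
  set.seed(99)
  nmc <- 1e6
  lam <- rgamma(nmc, a, rate = b)
  bet <- ifelse(runif(nmc) < 0.5, -1, 1) * rexp(nmc, rate = lam)
  gam <- rbinom(nmc, 1, s)
  v <- gam * bet
  f_hat <- mean(abs(v) > eps)
  mc_odds <- f_hat / (1 - f_hat)
  se_f <- sqrt(f_hat * (1 - f_hat) / nmc)
  se_odds <- se_f / (1 - f_hat)^2 # delta method
  expect_lt(abs(prior_odds_betagamma(a, b, eps, s) - mc_odds), 3 * se_odds)

  # s -> 1 limit: point mass at gamma = 0 vanishes
  expect_equal(prior_odds_betagamma(a, b, eps, 1 - 1e-12),
               b^a / ((b + eps)^a - b^a), tolerance = 1e-6)
  # eps -> Inf: the alternative has vanishing probability
  expect_lt(prior_odds_betagamma(a, b, 1e8, s), 1e-6)
})

test_that("Bayes factors follow the posterior-to-prior odds ratio", {
  expect_equal(bayes_factor(0.9, 1 / 9), 81, tolerance = 1e-12)
  # posterior frequency equal to the prior event probability: no evidence
  s <- 0.2
  expect_equal(bayes_factor(s, prior_odds_gamma(s)), 1, tolerance = 1e-12)
  expect_identical(bayes_factor(1, 0.5), Inf)
  expect_identical(bayes_factor(0, 0.5), 0)
  expect_error(bayes_factor(0.5, 0), "positive")
})

test_that("all selection rules match a brute-force recomputation on fixed draws", {
  set.seed(12)
  nc <- 2; nd <- 400; np <- 5
  beta_arr <- array(rnorm(nc * nd * np, 0, 0.5), c(nc, nd, np))
  beta_arr[, , 2] <- beta_arr[, , 2] + 1.5 # clear positive effect
  gamma_arr <- array(rbinom(nc * nd * np, 1, 0.4), c(nc, nd, np))
  gamma_arr[, , 2] <- 1
  gamma_arr[, , 5] <- 0 # never included
  spec <- fcr_model_spec(a = 1.2, b = 0.8, s = 0.15, epsilon = 0.07)
  fit <- fake_fit(beta_arr, gamma_arr, spec)

  sel <- select_features(fit, method = c("CI", "HPDI", "PrGamma", "BF_beta",
                                         "BF_betagamma", "BF_gamma"))

  # flatten pooled draws exactly as documented: chains stacked
  flat <- function(arr) apply(arr, 3, function(m) as.vector(t(m)))
  bet <- flat(beta_arr); gam <- flat(gamma_arr); bg <- bet * gam

  for (j in seq_len(np)) {
    ci <- quantile(bg[, j], c(0.025, 0.975), names = FALSE)
    row <- sel[sel$method == "CI" & sel$term == paste0("V", j), ]
    expect_equal(c(row$lower, row$upper), ci, tolerance = 1e-12)
    expect_equal(row$selected, ci[1] > 0 | ci[2] < 0)

    pg <- mean(gam[, j])
    rowp <- sel[sel$method == "PrGamma" & sel$term == paste0("V", j), ]
    expect_equal(rowp$evidence, pg, tolerance = 1e-12)
    expect_equal(rowp$selected, pg > 0.5)

    for (meth in c("BF_beta", "BF_betagamma", "BF_gamma")) {
      fsat <- switch(meth,
        BF_beta = mean(abs(bet[, j]) > spec$epsilon),
        BF_betagamma = mean(abs(bg[, j]) > spec$epsilon),
        BF_gamma = mean(gam[, j]))
      po <- switch(meth,
        BF_beta = prior_odds_beta(spec$a, spec$b, spec$epsilon),
        BF_betagamma = prior_odds_betagamma(spec$a, spec$b, spec$epsilon,
                                            spec$s),
        BF_gamma = prior_odds_gamma(spec$s))
      bf <- if (fsat == 1) Inf else (fsat / (1 - fsat)) / po
      rowb <- sel[sel$method == meth & sel$term == paste0("V", j), ]
      expect_equal(rowb$evidence, bf, tolerance = 1e-10)
      expect_equal(rowb$selected, bf > 5)
    }
  }

  # feature 5: indicator always off
  expect_equal(sel$evidence[sel$method == "PrGamma" & sel$term == "V5"], 0)
  expect_equal(sel$evidence[sel$method == "BF_gamma" & sel$term == "V5"], 0)
  expect_false(any(sel$selected[sel$term == "V5" &
                                sel$method %in% c("PrGamma", "BF_gamma")]))
  # feature 2: always included, effect bounded away from zero
  expect_true(all(sel$selected[sel$term == "V2"]))
})

test_that("BF_gamma is monotone in the posterior inclusion and in 1/s", {
  f <- seq(0.05, 0.95, by = 0.1)
  bf <- bayes_factor(f, prior_odds_gamma(0.2))
  expect_true(all(diff(bf) > 0))
  # weaker prior inclusion raises the BF at fixed posterior frequency
  expect_true(all(bayes_factor(0.4, prior_odds_gamma(0.05)) >
                  bayes_factor(0.4, prior_odds_gamma(0.2))))
})

test_that("selection is invariant to chain permutation", {
  set.seed(31)
  nc <- 3; nd <- 100; np <- 3
  beta_arr <- array(rnorm(nc * nd * np), c(nc, nd, np))
  gamma_arr <- array(rbinom(nc * nd * np, 1, 0.5), c(nc, nd, np))
  f1 <- fake_fit(beta_arr, gamma_arr)
  f2 <- fake_fit(beta_arr[c(3, 1, 2), , , drop = FALSE],
                 gamma_arr[c(3, 1, 2), , , drop = FALSE])
  s1 <- select_features(f1, c("CI", "HPDI", "BF_gamma"))
  s2 <- select_features(f2, c("CI", "HPDI", "BF_gamma"))
  expect_equal(s1$evidence, s2$evidence, tolerance = 1e-12)
  expect_equal(s1$selected, s2$selected)
})

test_that("selection tables write to delimited text", {
  fit <- fake_fit(array(rnorm(200), c(2, 50, 2)),
                  array(rbinom(200, 1, 0.5), c(2, 50, 2)))
  sel <- select_features(fit, "BF_gamma")
  f <- tempfile(fileext = ".tsv")
  write_selection(sel, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 2L)
  expect_true(all(c("term", "method", "evidence", "selected") %in% names(back)))
  unlink(f)
})
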