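#' Write posterior draws as a flat delimited table
#'
#' One row per (chain, draw, parameter) with the parameter labelled
#' `alpha<k>`, `beta:<feature>`, `gamma:<feature>` or `lambda`, so draws
#' can be archived and reloaded with [read_draws()].
#'
#' @param fit An [fcr_blasso] fit.
#' @param path Output path (`.csv` comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "fcr_blasso"))
  nc <- dim(fit$beta)[1]
  nd <- dim(fit$beta)[2]
  blocks <- list(
    alpha = fit$alpha,
    beta = fit$beta,
    gamma = fit$gamma
  )
  rows <- purrr::map_dfr(names(blocks), function(bl) {
    arr <- blocks[[bl]]
    nm <- dimnames(arr)[[3]]
    lab <- if (bl == "alpha") nm else paste0(bl, ":", nm)
    purrr::map_dfr(seq_len(dim(arr)[3]), function(j) {
      tibble::tibble(
        chain = rep(seq_len(nc), each = nd),
        draw = rep(seq_len(nd), nc),
        parameter = lab[j],
        value = as.vector(t(arr[, , j])))
    })
  })
  lam <- tibble::tibble(
    chain = rep(seq_len(nc), each = nd),
    draw = rep(seq_len(nd), nc),
    parameter = "lambda",
    value = as.vector(t(fit$lambda)))
  write_delim_auto(as.data.frame(dplyr::bind_rows(rows, lam)), path)
  invisible(path)
}

#' Read posterior draws from a flat delimited table
#'
#' Reconstructs an [fcr_blasso]-class object (draw arrays plus the
#' supplied spec) from a table written by [write_draws()], sufficient
#' for [select_features()], [posterior_summary()] and
#' [convergence_report()].
#'
#' @param path Path written by [write_draws()].
#' @param spec The [fcr_model_spec()] the fit used (hyperparameters are
#'   needed to recompute prior odds).
#' @return An object of class `fcr_blasso`.
#' @export
read_draws <- function(path, spec = fcr_model_spec()) {
  df <- read_delim_auto(path)
  stopifnot(all(c("chain", "draw", "parameter", "value") %in% names(df)))
  nc <- max(df$chain)
  nd <- max(df$draw)
  get_block <- function(prefix) {
    rows <- grepl(paste0("^", prefix), df$parameter)
    sub <- df[rows, ]
    nm <- unique(sub$parameter)
    arr <- array(NA_real_, c(nc, nd, length(nm)),
                 dimnames = list(NULL, NULL, sub("^[a-z]+:", "", nm)))
    for (j in seq_along(nm)) {
      pj <- sub[sub$parameter == nm[j], ]
      arr[cbind(pj$chain, pj$draw, j)] <- pj$value
    }
    arr
  }
  alpha <- get_block("alpha")
  beta <- get_block("beta:")
  gamma <- get_block("gamma:")
  lam_df <- df[df$parameter == "lambda", ]
  lambda <- matrix(NA_real_, nc, nd)
  lambda[cbind(lam_df$chain, lam_df$draw)] <- lam_df$value
  p <- dim(beta)[3]
  k <- dim(alpha)[3]
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
         loglik = matrix(NA_real_, nc, nd), accept = list(), spec = spec,
         schedule = mcmc_schedule(0, 0, nc, 1, nc * nd), seed = NA_integer_,
         chain_seeds = rep(NA_integer_, nc),
         feature_names = dimnames(beta)[[3]],
         dims = list(n = NA_integer_, p = p, k = k),
         n_records = NA_integer_, prior_only = FALSE),
    class = "fcr_blasso")
}
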