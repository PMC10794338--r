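#' The ex-Gaussian distribution
#'
#' Density and random generation for the exponentially modified Gaussian
#' distribution, the convolution of a Normal(`mu`, `sigma`) and an
#' Exponential with mean `beta`. It is the standard positively skewed model
#' for reaction times; its mean is `mu + beta` and its variance
#' `sigma^2 + beta^2`.
#'
#' @param x Vector of quantiles (ms).
#' @param n Number of draws.
#' @param mu Gaussian mean (ms).
#' @param sigma Gaussian SD (ms), > 0.
#' @param beta Mean of the exponential component (ms), > 0.
#' @param log If `TRUE`, return log density.
#' @return `dexgauss` a density vector, `rexgauss` a vector of draws.
#' @export
dexgauss <- function(x, mu, sigma, beta, log = FALSE) {
  stopifnot(all(sigma > 0), all(beta > 0))
  lg <- -base::log(beta) + (mu - x) / beta + sigma^2 / (2 * beta^2) +
    stats::pnorm((x - mu) / sigma - sigma / beta, log.p = TRUE)
  if (log) lg else exp(lg)
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, beta) {
  stopifnot(all(sigma > 0), all(beta > 0))
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / beta)
}

# Moment-based starting values (mean, sd, skewness).
exgauss_moments_start <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  g1 <- mean((x - m)^3) / s^3
  g1 <- min(max(g1, 0.05), 1.9) # keep the start inside the feasible region
  beta <- s * (g1 / 2)^(1 / 3)
  sigma2 <- s^2 - beta^2
  sigma <- sqrt(max(sigma2, (0.1 * s)^2))
  c(mu = m - beta, sigma = sigma, beta = beta)
}

#' Maximum-likelihood ex-Gaussian fit for one sample
#'
#' Fits (`mu`, `sigma`, `beta`) by direct likelihood maximisation with log
#' links on `sigma` and `beta`, starting from moment estimates. Standard
#' errors come from the numerically evaluated Hessian.
#'
#' @param rt Vector of positive reaction times (ms); needs at least 4
#'   observations with nonzero spread.
#' @return A list of class `exgauss_fit`: `estimates` tibble (term,
#'   estimate, std_error), `loglik`, `n`, `converged`, `conditional_mean`
#'   (`mu + beta`), `data` (the RTs, for plotting).
#' @examples
#' set.seed(1)
#' fit <- exgauss_mle(rexgauss(500, 500, 50, 100))
#' tidy(fit)
#' @export
exgauss_mle <- function(rt) {
  rt <- as.numeric(rt)
  if (any(is.na(rt)) || any(rt <= 0)) {
    abort("reaction times must be positive and non-missing.")
  }
  bad <- structure(
    list(estimates = tibble(term = c("mu", "sigma", "beta"),
                            estimate = NA_real_, std_error = NA_real_),
         loglik = NA_real_, n = length(rt), converged = FALSE,
         conditional_mean = NA_real_, data = rt),
    class = "exgauss_fit"
  )
  if (length(rt) < 4 || stats::sd(rt) == 0) return(bad)
  start <- exgauss_moments_start(rt)
  par0 <- c(start["mu"], log(start["sigma"]), log(start["beta"]))
  nll <- function(p) {
    s <- exp(p[2]); b <- exp(p[3])
    if (!all(is.finite(c(p[1], s, b))) || s <= 0 || b <= 0) return(1e10)
    v <- -sum(dexgauss(rt, p[1], s, b, log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- tryCatch(
    stats::optim(par0, nll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) return(bad)
  est <- unname(c(opt$par[1], exp(opt$par[2]), exp(opt$par[3])))
  # delta method from the log-link parameterisation
  se <- tryCatch({
    vc <- solve(opt$hessian)
    grad_scale <- c(1, est[2], est[3])
    sqrt(pmax(0, diag(vc)) ) * grad_scale
  }, error = function(e) rep(NA_real_, 3))
  structure(
    list(
      estimates = tibble(term = c("mu", "sigma", "beta"),
                         estimate = est, std_error = se),
      loglik = -opt$value, n = length(rt),
      converged = opt$convergence == 0 && all(is.finite(est)),
      conditional_mean = est[1] + est[3],
      data = rt
    ),
    class = "exgauss_fit"
  )
}

#' Ex-Gaussian reaction-time model over design cells
#'
#' Likelihood-based analogue of the hierarchical Bayesian ex-Gaussian
#' regression used for trial-level RT analyses: the distributional model is
#' `rt ~ item type * partial` on `mu` with `item type + partial` on
#' `log(sigma)` and `log(beta)`.
#'
#' Two variants are supported. The **per-cell** variant (default) fits an
#' independent ex-Gaussian in every `item_type` x `partial` cell; it is
#' robust, always available, and is the variant whose estimates carry
#' standard errors. The **hierarchical** variant adds Gaussian random
#' intercepts on `mu` (e.g. participant and information category) and
#' maximises the penalised likelihood, with the random-effect SDs updated by
#' an EM-style recursion; it is a maximum-likelihood approximation to the
#' full Bayesian model, not an MCMC replication.
#'
#' @param data A data frame of trial-level RTs.
#' @param rt_col,cell_cols Column names: the RT (ms) and the cell-defining
#'   factors (default `item_type` and `is_partial_error`).
#' @param hierarchical If `TRUE`, fit the penalised random-intercept model.
#' @param random Columns holding random-intercept grouping factors (used
#'   only when `hierarchical = TRUE`; missing columns are skipped).
#' @param min_cell Minimum RTs per cell for the per-cell variant.
#' @param max_em_iter Outer iterations for the random-effect SD recursion.
#' @return An object of class `exgauss_cells_fit` (list of per-cell
#'   [exgauss_mle()] fits plus a `cells` tibble with conditional means
#'   `mu + beta`), or class `exgauss_hier_fit` for the hierarchical variant
#'   (fixed-effect estimates per distributional parameter, random-intercept
#'   SDs, log-likelihood, convergence flag).
#' @export
fit_exgaussian <- function(data, rt_col = "rt_ms",
                           cell_cols = c("item_type", "is_partial_error"),
                           hierarchical = FALSE,
                           random = c("participant_id", "category"),
                           min_cell = 50,
                           max_em_iter = 6) {
  assert_columns(data, c(rt_col, cell_cols), "`data`")
  rt <- data[[rt_col]]
  if (any(is.na(rt)) || any(rt <= 0)) {
    abort("reaction times must be positive; drop excluded trials first.")
  }
  if (!hierarchical) {
    cells <- data |>
      group_by(dplyr::across(dplyr::all_of(cell_cols))) |>
      group_modify(function(g, key) {
        if (nrow(g) < min_cell) {
          abort(sprintf("cell with %d RTs is below the minimum of %d.",
                        nrow(g), min_cell))
        }
        fit <- exgauss_mle(g[[rt_col]])
        est <- fit$estimates
        tibble(n = fit$n, converged = fit$converged,
               mu = est$estimate[1], sigma = est$estimate[2],
               beta = est$estimate[3],
               se_mu = est$std_error[1], se_sigma = est$std_error[2],
               se_beta = est$std_error[3],
               conditional_mean = fit$conditional_mean,
               loglik = fit$loglik,
               fit = list(fit))
      }) |>
      ungroup()
    return(structure(list(cells = cells, cell_cols = cell_cols),
                     class = "exgauss_cells_fit"))
  }
  fit_exgaussian_hier(data, rt_col, cell_cols, random, max_em_iter)
}

fit_exgaussian_hier <- function(data, rt_col, cell_cols, random,
                                max_em_iter) {
  rt <- data[[rt_col]]
  f1 <- factor(data[[cell_cols[1]]])
  f2 <- factor(as.logical(data[[cell_cols[2]]]), levels = c(FALSE, TRUE))
  X_mu <- stats::model.matrix(~ f1 * f2)
  X_sc <- stats::model.matrix(~ f1 + f2)
  random <- intersect(random, names(data))
  groups <- lapply(random, function(r) factor(data[[r]]))
  names(groups) <- random
  n_u <- vapply(groups, nlevels, integer(1))
  p_mu <- ncol(X_mu); p_sc <- ncol(X_sc)

  start <- exgauss_moments_start(rt)
  par <- c(start["mu"], rep(0, p_mu - 1),
           log(start["sigma"]), rep(0, p_sc - 1),
           log(start["beta"]), rep(0, p_sc - 1),
           rep(0, sum(n_u)))
  idx_mu <- seq_len(p_mu)
  idx_ls <- p_mu + seq_len(p_sc)
  idx_lb <- p_mu + p_sc + seq_len(p_sc)
  idx_u <- split(p_mu + 2 * p_sc + seq_len(sum(n_u)),
                 rep(seq_along(n_u), n_u))
  tau <- rep(25, length(n_u)) # ms; starting random-intercept SD

  nll <- function(p, tau) {
    mu <- drop(X_mu %*% p[idx_mu])
    for (k in seq_along(groups)) {
      mu <- mu + p[idx_u[[k]]][as.integer(groups[[k]])]
    }
    sigma <- exp(drop(X_sc %*% p[idx_ls]))
    beta <- exp(drop(X_sc %*% p[idx_lb]))
    if (!all(is.finite(mu)) || !all(is.finite(sigma)) ||
        !all(is.finite(beta)) || any(sigma <= 0) || any(beta <= 0)) {
      return(1e10)
    }
    pen <- 0
    for (k in seq_along(groups)) {
      pen <- pen - sum(stats::dnorm(p[idx_u[[k]]], 0, tau[k], log = TRUE))
    }
    v <- -sum(dexgauss(rt, mu, sigma, beta, log = TRUE)) + pen
    if (!is.finite(v)) 1e10 else v
  }
  converged <- FALSE
  for (it in seq_len(max_em_iter)) {
    opt <- stats::optim(par, nll, tau = tau, method = "BFGS",
                        control = list(maxit = 300))
    par <- opt$par
    new_tau <- vapply(seq_along(groups), function(k) {
      sqrt(mean(par[idx_u[[k]]]^2) + 1e-6)
    }, numeric(1))
    done <- all(abs(new_tau - tau) < 0.5)
    tau <- new_tau
    if (done && opt$convergence == 0) { converged <- TRUE; break }
  }
  fixef <- list(
    mu = stats::setNames(par[idx_mu], colnames(X_mu)),
    log_sigma = stats::setNames(par[idx_ls], colnames(X_sc)),
    log_beta = stats::setNames(par[idx_lb], colnames(X_sc))
  )
  structure(
    list(fixef = fixef,
         ranef_sd = stats::setNames(tau, random),
         ranef = lapply(seq_along(groups), function(k) {
           stats::setNames(par[idx_u[[k]]], levels(groups[[k]]))
         }),
         loglik = -nll(par, tau), n = length(rt), converged = converged),
    class = "exgauss_hier_fit"
  )
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf("<ex-Gaussian MLE, n = %d, %s>\n", x$n,
              if (x$converged) "converged" else "NOT converged"))
  print(x$estimates)
  invisible(x)
}

#' @export
print.exgauss_cells_fit <- function(x, ...) {
  cat("<ex-Gaussian per-cell fits>\n")
  print(x$cells |> select(-"fit"))
  invisible(x)
}
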