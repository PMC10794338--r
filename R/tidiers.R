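#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Bayes-factor result
#'
#' @param x A `bf_result` from [jzs_ttest_bf()], [jzs_mixed_anova_bf()] or
#'   [signed_rank_bf()].
#' @param ... Unused.
#' @return One row per model comparison: `model_a`, `model_b`, `log_bf`,
#'   `bf`, `error`.
#' @method tidy bf_result
#' @export
tidy.bf_result <- function(x, ...) {
  x$comparisons |> mutate(bf = exp(.data$log_bf), .after = "log_bf")
}

#' @rdname tidy.bf_result
#' @method glance bf_result
#' @export
glance.bf_result <- function(x, ...) {
  tibble(
    method = x$method,
    prior_scale = x$prior_scale[[1]],
    n_comparisons = nrow(x$comparisons),
    seed = x$seed
  )
}

#' Tidy an ex-Gaussian fit
#'
#' @param x An `exgauss_fit` from [exgauss_mle()] or an `exgauss_cells_fit`
#'   / `exgauss_hier_fit` from [fit_exgaussian()].
#' @param ... Unused.
#' @return Parameter estimates, one row per term (and per cell for the
#'   per-cell variant).
#' @method tidy exgauss_fit
#' @export
tidy.exgauss_fit <- function(x, ...) x$estimates

#' @rdname tidy.exgauss_fit
#' @method glance exgauss_fit
#' @export
glance.exgauss_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n = x$n, converged = x$converged,
         conditional_mean = x$conditional_mean)
}

#' @rdname tidy.exgauss_fit
#' @method tidy exgauss_cells_fit
#' @export
tidy.exgauss_cells_fit <- function(x, ...) {
  x$cells |>
    select(-"fit") |>
    tidyr::pivot_longer(c("mu", "sigma", "beta"),
                        names_to = "term", values_to = "estimate") |>
    mutate(std_error = dplyr::case_when(
      .data$term == "mu" ~ .data$se_mu,
      .data$term == "sigma" ~ .data$se_sigma,
      TRUE ~ .data$se_beta
    )) |>
    select(dplyr::all_of(c(x$cell_cols, "term", "estimate", "std_error",
                           "n", "converged")))
}

#' @rdname tidy.exgauss_fit
#' @method glance exgauss_cells_fit
#' @export
glance.exgauss_cells_fit <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    n = sum(x$cells$n),
    logLik = sum(x$cells$loglik),
    converged = all(x$cells$converged)
  )
}

#' @rdname tidy.exgauss_fit
#' @method tidy exgauss_hier_fit
#' @export
tidy.exgauss_hier_fit <- function(x, ...) {
  bind_rows(
    tibble(parameter = "mu", term = names(x$fixef$mu),
           estimate = unname(x$fixef$mu)),
    tibble(parameter = "log_sigma", term = names(x$fixef$log_sigma),
           estimate = unname(x$fixef$log_sigma)),
    tibble(parameter = "log_beta", term = names(x$fixef$log_beta),
           estimate = unname(x$fixef$log_beta))
  )
}

#' @rdname tidy.exgauss_fit
#' @method glance exgauss_hier_fit
#' @export
glance.exgauss_hier_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n = x$n, converged = x$converged)
}
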