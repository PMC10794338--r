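new_bf_result <- function(comparisons, method, prior_scale, seed = NA,
                          details = list()) {
  structure(
    list(comparisons = comparisons, method = method,
         prior_scale = prior_scale, seed = seed, details = details),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<Bayes factor: %s (prior scale %s)>\n", x$method,
              paste(signif(x$prior_scale, 3), collapse = "/")))
  df <- x$comparisons |>
    mutate(bf = exp(.data$log_bf))
  print(df)
  invisible(x)
}

#' JZS Bayes-factor t test
#'
#' Default Bayes factor for a one-sample (or paired-difference) design under
#' the Jeffreys-Zellner-Siow prior: a Cauchy prior with scale `prior_scale`
#' on the standardised effect size. `BF10` is computed by adaptive
#' quadrature of the noncentral-t marginal likelihood over the Cauchy prior;
#' one-sided variants use the truncated, renormalised half-Cauchy.
#'
#' @param differences Numeric vector (paired differences or a one-sample
#'   variable); needs `n >= 2` and nonzero variance.
#' @param prior_scale Cauchy scale on the standardised effect (default
#'   0.707, the conventional "medium" width).
#' @param direction `"two_sided"`, `"greater"` (effect > 0) or `"less"`.
#' @return A [`bf_result`][jzs_mixed_anova_bf] with one comparison
#'   (`H1` vs `H0`), its `log_bf` and the quadrature error.
#' @examples
#' jzs_ttest_bf(c(0.5, 1.2, 0.3, 0.9, 1.1, 0.2, 0.8, 0.4))
#' @export
jzs_ttest_bf <- function(differences,
                         prior_scale = 0.707,
                         direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  d <- as.numeric(differences)
  if (length(d) < 2 || any(!is.finite(d))) {
    abort("`differences` must hold at least two finite values.")
  }
  if (stats::sd(d) == 0) {
    abort("`differences` has zero variance; the t statistic is undefined.")
  }
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  nu <- n - 1
  lik <- function(delta) {
    suppressWarnings(stats::dt(tstat, df = nu, ncp = delta * sqrt(n)))
  }
  r <- prior_scale
  integrand <- function(delta) lik(delta) * stats::dcauchy(delta, 0, r)
  bounds <- switch(direction,
    two_sided = c(-Inf, Inf),
    greater = c(0, Inf),
    less = c(-Inf, 0)
  )
  quad <- stats::integrate(integrand, bounds[1], bounds[2],
                           rel.tol = 1e-10, abs.tol = 0)
  prior_mass <- if (direction == "two_sided") 1 else 0.5
  m1 <- quad$value / prior_mass
  m0 <- stats::dt(tstat, df = nu)
  log_bf <- log(m1) - log(m0)
  err <- quad$abs.error / prior_mass / m1 # relative, approx error on log BF
  comparisons <- tibble(
    model_a = paste0("H1_", direction), model_b = "H0",
    log_bf = log_bf, error = err
  )
  new_bf_result(comparisons, method = "JZS t test", prior_scale = r,
                details = list(t = tstat, n = n, df = nu,
                               direction = direction))
}

# Orthonormal contrast matrix for an a-level factor: columns span the
# centered (sum-to-zero) subspace, making level effects exchangeable.
level_contrasts <- function(a) {
  S <- diag(a) - 1 / a
  eg <- eigen(S, symmetric = TRUE)
  eg$vectors[, seq_len(a - 1), drop = FALSE]
}

# Sufficient statistics of one model: centered design (by batch), cross
# products. `batches` is a named list of design-matrix blocks, `scales` the
# matching Cauchy scale per block.
anova_model_stats <- function(y, batches, scales) {
  X <- do.call(cbind, batches)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yt <- y - mean(y)
  list(
    S = crossprod(Xc),
    Xty = drop(crossprod(Xc, yt)),
    yty = sum(yt^2),
    n = length(y),
    col_scale = rep(scales, vapply(batches, ncol, integer(1))),
    col_batch = rep(seq_along(batches), vapply(batches, ncol, integer(1)))
  )
}

# Monte-Carlo log marginal likelihood (up to model-independent constants)
# under the default g-prior structure: one g per batch, g ~ InvGamma(1/2,
# r^2/2). Returns the log marginal and its MC standard error.
anova_log_marginal <- function(stats, n_samples, batch_scales) {
  n <- stats$n
  p <- length(stats$Xty)
  nb <- length(batch_scales)
  const_y <- stats$yty < 1e-12 # degenerate constant dv: drop common factor
  ll <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    g <- 1 / stats::rgamma(nb, shape = 0.5, rate = batch_scales^2 / 2)
    sg <- sqrt(g)[stats$col_batch]
    M <- diag(p) + (sg %o% sg) * stats$S
    L <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(L)) { ll[s] <- NA_real_; next }
    v <- sg * stats$Xty
    u <- backsolve(L, v, transpose = TRUE)
    q <- stats$yty - sum(u^2)
    ll[s] <- -sum(log(diag(L))) -
      if (const_y) 0 else (n - 1) / 2 * log(max(q, 1e-300))
  }
  ll <- ll[is.finite(ll)]
  m <- max(ll)
  w <- exp(ll - m)
  log_marg <- m + log(mean(w))
  se <- stats::sd(w) / (mean(w) * sqrt(length(w)))
  list(log_marginal = log_marg, se = se)
}

#' JZS mixed-model Bayes-factor ANOVA
#'
#' Default Bayes factors for the two-factor mixed design used for
#' participant-level analyses: one within-subject factor (item type), one
#' between-subject factor (condition), and participant as a random
#' intercept. Model marginal likelihoods follow the default g-prior
#' construction: effects receive zero-centered Gaussian priors whose scale
#' parameter `g` carries an inverse-gamma prior equivalent to a Cauchy
#' (scale `prior_scale`, default 0.5) on standardised effects; the
#' participant batch uses scale 1. Each marginal is integrated over the `g`
#' parameters by seeded Monte Carlo and reported with its MC error.
#'
#' Four models are compared: `Null` (participant only), `Fam` (+ between
#' factor), `Main` (+ within factor), `Full` (+ interaction). The standard
#' report is `Main` vs `Fam` (the test of the within-factor effect) and
#' `Full` vs `Main` (the test of the interaction).
#'
#' @param summaries Long participant-summary tibble (one row per participant
#'   x within level), e.g. from [summarize_participants()].
#' @param dv Dependent variable: `"mean_rt"` (uses `mean_rt_ms`) or
#'   `"prop_partial"`, or any column name present in `summaries`.
#' @param within Column holding the within-subject factor, and
#'   `within_levels` the pair or triple of levels to analyse (defaults to
#'   all levels present).
#' @param between Column holding the between-subject factor.
#' @param prior_scale Cauchy scale for fixed-effect batches (default 0.5).
#' @param prior_scale_random Cauchy scale for the participant batch
#'   (default 1).
#' @param samples Monte-Carlo draws per model.
#' @param seed Integer seed (the integration is seeded and reproducible).
#' @param transform `"none"` or `"arcsine"` (arcsine-square-root, for
#'   proportions).
#' @param within_levels Levels of `within` to include.
#' @return A `bf_result` with comparisons `Fam` vs `Null`, `Main` vs `Fam`,
#'   `Full` vs `Main`, each with `log_bf` and MC `error`; model log
#'   marginals are kept in `details`.
#' @export
jzs_mixed_anova_bf <- function(summaries,
                               dv = c("mean_rt", "prop_partial"),
                               within = "item_type",
                               within_levels = NULL,
                               between = "condition",
                               prior_scale = 0.5,
                               prior_scale_random = 1,
                               samples = 10000,
                               seed = 1,
                               transform = c("none", "arcsine")) {
  transform <- match.arg(transform)
  if (is.character(dv) && length(dv) > 1) dv <- dv[1]
  dv_col <- switch(dv, mean_rt = "mean_rt_ms", prop_partial = "prop_partial",
                   dv)
  assert_columns(summaries, c("participant_id", within, between, dv_col),
                 "`summaries`")
  d <- summaries
  if (is.null(within_levels)) {
    within_levels <- sort(unique(as.character(d[[within]])))
  }
  d <- d[d[[within]] %in% within_levels, ]
  d <- d[!duplicated(d[, c("participant_id", within)]), ]

  # balance validation: every participant must have every level, one
  # condition, and no missing dv
  tab <- table(d$participant_id, d[[within]])
  if (any(tab != 1)) {
    abort("unbalanced design: every participant needs exactly one row per within level.")
  }
  cond_per <- tapply(as.character(d[[between]]), d$participant_id,
                     function(x) length(unique(x)))
  if (any(cond_per != 1)) {
    abort("each participant must belong to exactly one between-subjects condition.")
  }
  y <- d[[dv_col]]
  if (any(is.na(y))) abort("missing dv values in the summary table.")
  if (transform == "arcsine") y <- arcsine_transform(y)

  part <- factor(d$participant_id)
  fw <- factor(as.character(d[[within]]), levels = within_levels)
  fb <- factor(as.character(d[[between]]))
  if (nlevels(fb) < 2) abort("the between-subjects factor needs 2 levels.")

  Zp <- stats::model.matrix(~ part - 1)
  Qw <- level_contrasts(nlevels(fw))
  Qb <- level_contrasts(nlevels(fb))
  Xw <- Qw[as.integer(fw), , drop = FALSE]
  Xb <- Qb[as.integer(fb), , drop = FALSE]
  # row-wise Kronecker product for the interaction batch
  Xi <- do.call(cbind, lapply(seq_len(ncol(Xb)), function(j) Xw * Xb[, j]))

  models <- list(
    Null = list(batches = list(participant = Zp),
                scales = prior_scale_random),
    Fam = list(batches = list(participant = Zp, between = Xb),
               scales = c(prior_scale_random, prior_scale)),
    Main = list(batches = list(participant = Zp, between = Xb, within = Xw),
                scales = c(prior_scale_random, prior_scale, prior_scale)),
    Full = list(batches = list(participant = Zp, between = Xb, within = Xw,
                               interaction = Xi),
                scales = c(prior_scale_random, rep(prior_scale, 3)))
  )
  marg <- with_seed(seed, {
    lapply(models, function(m) {
      st <- anova_model_stats(y, m$batches, m$scales)
      anova_log_marginal(st, samples, m$scales)
    })
  })
  lm_of <- function(nm) marg[[nm]]$log_marginal
  se_of <- function(nm) marg[[nm]]$se
  pairs <- list(c("Fam", "Null"), c("Main", "Fam"), c("Full", "Main"))
  comparisons <- purrr::map_dfr(pairs, function(p) {
    tibble(model_a = p[1], model_b = p[2],
           log_bf = lm_of(p[1]) - lm_of(p[2]),
           error = sqrt(se_of(p[1])^2 + se_of(p[2])^2))
  })
  new_bf_result(
    comparisons, method = "JZS mixed ANOVA",
    prior_scale = c(fixed = prior_scale, random = prior_scale_random),
    seed = seed,
    details = list(
      log_marginals = vapply(marg, `[[`, numeric(1), "log_marginal"),
      mc_se = vapply(marg, `[[`, numeric(1), "se"),
      dv = dv_col, within_levels = within_levels, transform = transform,
      n_participants = nlevels(part), samples = samples
    )
  )
}

#' Rank-based Bayes factor for paired differences
#'
#' Approximate Bayesian analogue of the Wilcoxon signed-rank test via
#' latent-normal data augmentation: latent Gaussian values constrained to
#' reproduce the observed signed ranks are Gibbs-sampled together with the
#' standardised effect `delta` (Cauchy prior, scale `prior_scale`), and the
#' Bayes factor follows from the Savage-Dickey ratio at `delta = 0` using
#' Rao-Blackwellised conditional densities. The construction is sampler
#' based and *approximate*: ties in the absolute differences are broken
#' deterministically, and accuracy is limited by Monte-Carlo error (two
#' independent chains are run and their half-difference reported).
#'
#' @param differences Paired differences; zeros are dropped (with a
#'   warning); at least 3 nonzero values are required.
#' @param direction `"two_sided"`, `"greater"` or `"less"`.
#' @param prior_scale Cauchy prior scale on `delta`.
#' @param iterations Gibbs iterations per chain (first 10% discarded).
#' @param seed Integer seed.
#' @return A `bf_result` with the directional `log_bf` and an MC error
#'   estimate.
#' @export
signed_rank_bf <- function(differences,
                           direction = c("two_sided", "greater", "less"),
                           prior_scale = 0.707,
                           iterations = 2000,
                           seed = 1) {
  direction <- match.arg(direction)
  d <- as.numeric(differences)
  d <- d[is.finite(d)]
  if (any(d == 0)) {
    warn("dropping zero differences for the signed-rank analysis.")
    d <- d[d != 0]
  }
  if (length(d) < 3) abort("need at least 3 nonzero differences.")
  n <- length(d)
  ord <- order(abs(d)) # latent |z| must increase along this order
  s <- sign(d)
  r <- prior_scale

  run_chain <- function(chain_seed) {
    with_seed(chain_seed, {
      z <- s * (rank(abs(d), ties.method = "first") / (n + 1))
      delta <- 0
      burn <- max(1L, floor(iterations * 0.1))
      dens0 <- numeric(iterations)
      pgt <- numeric(iterations)
      post_prec <- n + 0 # z likelihood N(delta, 1): posterior given z below
      for (it in seq_len(iterations)) {
        for (jj in seq_len(n)) {
          i <- ord[jj]
          lo_abs <- if (jj == 1) 0 else abs(z[ord[jj - 1]])
          hi_abs <- if (jj == n) Inf else abs(z[ord[jj + 1]])
          if (s[i] > 0) { a <- lo_abs; b <- hi_abs } else { a <- -hi_abs; b <- -lo_abs }
          pa <- stats::pnorm(a, delta, 1)
          pb <- stats::pnorm(b, delta, 1)
          if (pb - pa < 1e-12) {
            z[i] <- max(min(delta, b - 1e-8), a + 1e-8)
          } else {
            z[i] <- stats::qnorm(stats::runif(1, pa, pb), delta, 1)
          }
        }
        # delta | z: N(zbar, 1/n) likelihood x Cauchy prior, griddy draw
        zbar <- mean(z)
        grid <- seq(zbar - 6 / sqrt(n), zbar + 6 / sqrt(n), length.out = 400)
        grid <- sort(unique(c(grid, 0)))
        lp <- stats::dnorm(grid, zbar, 1 / sqrt(n), log = TRUE) +
          stats::dcauchy(grid, 0, r, log = TRUE)
        w <- exp(lp - max(lp))
        cw <- cumsum(w); cw <- cw / cw[length(cw)]
        delta <- grid[findInterval(stats::runif(1), cw) + 1]
        # Rao-Blackwellised conditional density at 0 and P(delta > 0 | z)
        norm_c <- stats::integrate(function(x) {
          stats::dnorm(x, zbar, 1 / sqrt(n)) * stats::dcauchy(x, 0, r)
        }, -Inf, Inf, rel.tol = 1e-8)$value
        dens0[it] <- stats::dnorm(0, zbar, 1 / sqrt(n)) *
          stats::dcauchy(0, 0, r) / norm_c
        pgt[it] <- stats::integrate(function(x) {
          stats::dnorm(x, zbar, 1 / sqrt(n)) * stats::dcauchy(x, 0, r)
        }, 0, Inf, rel.tol = 1e-8)$value / norm_c
      }
      keep <- seq.int(burn + 1L, iterations)
      list(dens0 = mean(dens0[keep]), pgt = mean(pgt[keep]))
    })
  }
  ch <- lapply(c(derive_seed(seed, 1), derive_seed(seed, 2)), run_chain)
  log_bf_chain <- vapply(ch, function(c1) {
    log_bf10 <- stats::dcauchy(0, 0, r, log = TRUE) - log(c1$dens0)
    switch(direction,
      two_sided = log_bf10,
      greater = log_bf10 + log(c1$pgt / 0.5),
      less = log_bf10 + log((1 - c1$pgt) / 0.5)
    )
  }, numeric(1))
  comparisons <- tibble(
    model_a = paste0("H1_", direction), model_b = "H0",
    log_bf = mean(log_bf_chain),
    error = abs(diff(log_bf_chain)) / 2
  )
  new_bf_result(comparisons, method = "latent-normal signed-rank (approximate)",
                prior_scale = r, seed = seed,
                details = list(n = n, direction = direction,
                               chains = log_bf_chain))
}
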