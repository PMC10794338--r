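# Independent oracles. Each deliberately re-derives its quantity along a
# different computational route than the package implementation.

# Step-function reconstruction by explicit segment filling (no
# findInterval): value vector at 1 ms resolution over 0..floor(dur).
brute_force_densify <- function(times, values, dur) {
  n_grid <- floor(dur) + 1
  v <- numeric(n_grid)
  if (length(times) > 0) {
    start <- ceiling(times) + 1 # first grid index at/after the event time
    for (k in seq_along(times)) {
      if (start[k] <= n_grid) v[start[k]:n_grid] <- values[k]
    }
  }
  v
}

# Trial outcome by linear scan of the densified 1 kHz grids.
brute_force_outcome <- function(ev_e_t, ev_e_v, ev_i_t, ev_i_v,
                                deadline, correct_key,
                                thr = 0.95, guard = 5) {
  ve <- brute_force_densify(ev_e_t, ev_e_v, deadline)
  vi <- brute_force_densify(ev_i_t, ev_i_v, deadline)
  tgrid <- seq_along(ve) - 1
  cross_e <- which(ve > thr)[1]
  cross_i <- which(vi > thr)[1]
  ce <- if (is.na(cross_e)) Inf else tgrid[cross_e]
  ci <- if (is.na(cross_i)) Inf else tgrid[cross_i]
  rt <- min(ce, ci)
  starts <- any(ve[tgrid <= guard] > 0) || any(vi[tgrid <= guard] > 0)
  if (!is.finite(rt)) {
    return(list(rt = NA_real_, key = NA_character_, partial = NA,
                starts_pressed = starts))
  }
  key <- if (ce < ci) "e" else if (ci < ce) "i" else {
    if (ve[rt + 1] > vi[rt + 1]) "e" else if (vi[rt + 1] > ve[rt + 1]) "i" else "tie"
  }
  before <- tgrid < rt
  partial <- any(ve[before] > 0) && any(vi[before] > 0)
  list(rt = rt, key = key, partial = partial, starts_pressed = starts)
}

# Dense-grid trapezoid quadrature of the JZS t-test marginal in the
# effect-size parameterisation.
ttest_bf_oracle <- function(d, r = 0.707, direction = "two_sided") {
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  nu <- n - 1
  f <- function(delta) {
    suppressWarnings(dt(tstat, df = nu, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, r)
  }
  grid <- switch(direction,
    two_sided = seq(-15, 15, length.out = 60001),
    greater = seq(0, 15, length.out = 30001),
    less = seq(-15, 0, length.out = 30001)
  )
  h <- diff(grid[1:2])
  y <- f(grid)
  m1 <- (sum(y) - (y[1] + y[length(y)]) / 2) * h
  prior_mass <- if (direction == "two_sided") 1 else 0.5
  (m1 / prior_mass) / dt(tstat, df = nu)
}

# High-effort ANOVA marginal: same model definition, different integration
# route -- dense n x n covariance per draw (determinant() + solve(), no
# Woodbury reduction), independent RNG stream.
oracle_anova_log_bf <- function(y, participant, within, between,
                                prior_fixed = 0.5, prior_random = 1,
                                nsamp = 60000, seed = 99) {
  part <- factor(participant)
  fw <- factor(within)
  fb <- factor(between)
  lc <- function(a) {
    S <- diag(a) - 1 / a
    eigen(S, symmetric = TRUE)$vectors[, seq_len(a - 1), drop = FALSE]
  }
  Zp <- model.matrix(~ part - 1)
  Xw <- lc(nlevels(fw))[as.integer(fw), , drop = FALSE]
  Xb <- lc(nlevels(fb))[as.integer(fb), , drop = FALSE]
  Xi <- do.call(cbind, lapply(seq_len(ncol(Xb)), function(j) Xw * Xb[, j]))
  models <- list(
    Null = list(X = list(Zp), r = prior_random),
    Fam = list(X = list(Zp, Xb), r = c(prior_random, prior_fixed)),
    Main = list(X = list(Zp, Xb, Xw), r = c(prior_random, rep(prior_fixed, 2))),
    Full = list(X = list(Zp, Xb, Xw, Xi), r = c(prior_random, rep(prior_fixed, 3)))
  )
  n <- length(y)
  yt <- y - mean(y)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  logm <- vapply(models, function(m) {
    Xc <- lapply(m$X, function(x) scale(x, center = TRUE, scale = FALSE))
    pcols <- vapply(Xc, ncol, integer(1))
    Xall <- do.call(cbind, Xc)
    ll <- numeric(nsamp)
    for (s in seq_len(nsamp)) {
      g <- 1 / rgamma(length(m$r), shape = 0.5, rate = m$r^2 / 2)
      gvec <- rep(g, pcols)
      V <- diag(n) + Xall %*% (gvec * t(Xall))
      q <- drop(crossprod(yt, solve(V, yt)))
      ll[s] <- -0.5 * as.numeric(determinant(V, logarithm = TRUE)$modulus) -
        (n - 1) / 2 * log(q)
    }
    mx <- max(ll)
    mx + log(mean(exp(ll - mx)))
  }, numeric(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  c(Fam_Null = logm[["Fam"]] - logm[["Null"]],
    Main_Fam = logm[["Main"]] - logm[["Fam"]],
    Full_Main = logm[["Full"]] - logm[["Main"]])
}

# Balanced 2 x 2 participant-summary table with configurable effects, for
# ANOVA tests.
make_summary_table <- function(n_participants, probe_shift = 0,
                               cond_shift = 0, interaction = 0,
                               part_sd = 50, noise_sd = 25,
                               base = 470, seed = 1,
                               dv_name = "mean_rt_ms",
                               levels = c("irrelevant", "probe")) {
  withr::with_seed(seed, {
    pid <- sprintf("p%03d", seq_len(n_participants))
    cond <- rep(c("low", "high"), length.out = n_participants)
    g <- tidyr::expand_grid(participant_id = pid,
                            item_type = levels)
    g$condition <- rep(cond, each = length(levels))
    u <- rnorm(n_participants, 0, part_sd)
    is_second <- g$item_type == levels[2]
    g[[dv_name]] <- base +
      ifelse(is_second, probe_shift, 0) +
      ifelse(g$condition == "high", cond_shift, 0) +
      ifelse(is_second & g$condition == "high", interaction, 0) +
      u[match(g$participant_id, pid)] +
      rnorm(nrow(g), 0, noise_sd)
    g
  })
}
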