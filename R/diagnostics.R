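# Convergence and fit assessment.

#' Posterior draws of every cell mean
#'
#' Reassembles `mu_it = exp(alpha + X_it beta + phi_i + xi_t + delta_it)`
#' for every retained draw (chains pooled).
#'
#' @param fit An `stcar_fit`.
#' @param panel The [area_panel] the model was fitted to.
#' @return S x (N*T) matrix of Poisson means, cells in area-fastest order.
#' @export
mu_draws <- function(fit, panel) {
  N <- length(fit$area_ids); T <- length(fit$years)
  alpha <- fit_draws(fit, "alpha")
  beta <- fit_draws(fit, "beta")
  phi <- fit_draws(fit, "phi")
  xi <- fit_draws(fit, "xi")
  X <- panel_X(panel)
  ci <- rep(seq_len(N), times = T)
  ct <- rep(seq_len(T), each = N)
  eta <- matrix(alpha, length(alpha), N * T)
  if (ncol(beta) > 0) eta <- eta + beta %*% t(X)
  eta <- eta + phi[, ci, drop = FALSE] + xi[, ct, drop = FALSE]
  if (fit$config$include_interaction) eta <- eta + fit_draws(fit, "delta")
  exp(eta)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain PSRF: each chain is halved (when long enough) and the
#' statistic `sqrt((n-1)/n + (m+1)/m * B/(n W))` is computed over the
#' resulting m sequences of length n, with `B` n times the variance of the
#' sequence means and `W` the mean within-sequence variance.  Values near 1
#' indicate the chains have mixed.
#'
#' @param chains List of numeric vectors (equal lengths), one per chain,
#'   holding draws of a single scalar parameter.
#' @param split Halve each chain first? (Disabled automatically for chains
#'   shorter than 4.)
#' @return The PSRF, or `NA` with a warning when the within-chain variance
#'   is zero in every chain.
#' @export
gelman_rubin <- function(chains, split = TRUE) {
  stopifnot(length(chains) >= 2)
  n0 <- unique(lengths(chains))
  stopifnot(length(n0) == 1)
  if (split && n0 >= 4) {
    h <- floor(n0 / 2)
    chains <- unlist(lapply(chains, function(x)
      list(x[seq_len(h)], x[(h + 1):(2 * h)])), recursive = FALSE)
  }
  m <- length(chains); n <- length(chains[[1]])
  W <- mean(vapply(chains, var, numeric(1)))
  if (W == 0) {
    warning("zero within-chain variance; PSRF undefined")
    return(NA_real_)
  }
  B <- n * var(vapply(chains, mean, numeric(1)))
  sqrt((n - 1) / n + (m + 1) / m * B / (n * W))
}

#' PSRF table for the headline parameters of a fit
#'
#' @param fit An `stcar_fit` with at least two chains.
#' @return Named vector of split-chain PSRFs for `alpha`, each `beta`, and
#'   the sampled variance components.
#' @export
rhat_table <- function(fit) {
  stopifnot(length(fit$chains) >= 2)
  per_chain <- function(param, col = NULL) {
    lapply(fit$chains, function(ch) {
      x <- ch[[param]]
      if (!is.null(col)) x[, col] else x
    })
  }
  out <- c(alpha = gelman_rubin(per_chain("alpha")))
  for (p in seq_along(fit$covariate_names))
    out[paste0("beta_", fit$covariate_names[p])] <-
      gelman_rubin(per_chain("beta", p))
  cfg <- fit$config
  if (cfg$include_spatial && !is.finite(cfg$fixed_variances["phi"]))
    out["var_phi"] <- gelman_rubin(per_chain("var_phi"))
  if (cfg$include_temporal && !is.finite(cfg$fixed_variances["xi"]))
    out["var_xi"] <- gelman_rubin(per_chain("var_xi"))
  if (cfg$include_interaction && !is.finite(cfg$fixed_variances["delta"]))
    out["var_delta"] <- gelman_rubin(per_chain("var_delta"))
  out
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - p_WAIC)`, with the log pointwise predictive density
#' computed by a stabilised log-sum-exp over draws and the effective number
#' of parameters `p_WAIC` the summed pointwise posterior variances of the
#' log-likelihood.
#'
#' @param fit An `stcar_fit`.
#' @param panel The fitted [area_panel].
#' @param mu Optional precomputed [mu_draws] matrix (avoids recomputation).
#' @return List with `waic`, `lppd`, `p_waic`, and a pointwise data frame
#'   (one row per cell, area-fastest order).
#' @export
waic <- function(fit, panel, mu = NULL) {
  if (is.null(mu)) mu <- mu_draws(fit, panel)
  y <- as.vector(panel$counts)
  S <- nrow(mu)
  ll <- dpois(rep(y, each = S), mu, log = TRUE)
  dim(ll) <- dim(mu)
  lmax <- apply(ll, 2, max)
  lppd_i <- lmax + log(colMeans(exp(sweep(ll, 2, lmax)))) # log-sum-exp
  p_i <- apply(ll, 2, var)
  pointwise <- data.frame(lppd = lppd_i, p_waic = p_i,
                          waic = -2 * (lppd_i - p_i))
  list(waic = sum(pointwise$waic), lppd = sum(lppd_i), p_waic = sum(p_i),
       pointwise = pointwise)
}

#' WAIC comparison table over fitted model variants
#'
#' @param fits Named list of `stcar_fit` objects (see
#'   [competing_model_family]).
#' @param panel The fitted [area_panel].
#' @return Data frame of WAIC, lppd and p_WAIC per variant, ordered best
#'   first.
#' @export
waic_table <- function(fits, panel) {
  rows <- lapply(fits, function(f) {
    w <- waic(f, panel)
    data.frame(waic = w$waic, lppd = w$lppd, p_waic = w$p_waic)
  })
  out <- do.call(rbind, rows)
  out$variant <- names(fits)
  out <- out[order(out$waic), c("variant", "waic", "lppd", "p_waic")]
  rownames(out) <- NULL
  out
}

#' Posterior predictive Bayesian p-values
#'
#' Per-cell mid-p tail probabilities
#' `p_it = P(y_rep > y_obs) + 0.5 P(y_rep = y_obs)`, averaged over the
#' posterior analytically via the Poisson tail function (no replicate
#' sampling noise), together with their cell average.  Under a
#' well-calibrated model the average is close to 0.5.  The alternative
#' `"chisq"` statistic is the classical omnibus discrepancy
#' `sum (y - mu)^2 / mu` compared between sampled replicates and the data.
#'
#' @param fit An `stcar_fit`.
#' @param panel The fitted [area_panel].
#' @param statistic `"midp"` (default, per-cell) or `"chisq"` (global
#'   discrepancy).
#' @param mu Optional precomputed [mu_draws] matrix (avoids recomputation).
#' @return For `"midp"`: list with `p` (N x T matrix) and `average`.  For
#'   `"chisq"`: list with the global `p` and the discrepancy draws.
#' @export
bayesian_pvalue <- function(fit, panel, statistic = c("midp", "chisq"),
                            mu = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(mu)) mu <- mu_draws(fit, panel)
  y <- as.vector(panel$counts)
  N <- length(panel$area_ids); T <- length(panel$years)
  S <- nrow(mu)
  if (statistic == "midp") {
    yrep <- rep(y, each = S)
    p_cell <- colMeans(matrix(
      ppois(yrep, mu, lower.tail = FALSE) + 0.5 * dpois(yrep, mu),
      S, N * T))
    p <- matrix(p_cell, N, T, dimnames = list(panel$area_ids, panel$years))
    list(p = p, average = mean(p_cell), statistic = "midp")
  } else {
    disc_obs <- rowSums(sweep(mu, 2, y, function(m, yy) (yy - m)^2 / m))
    yr <- matrix(rpois(length(mu), mu), S, N * T)
    disc_rep <- rowSums((yr - mu)^2 / mu)
    list(p = mean(disc_rep >= disc_obs),
         discrepancy = data.frame(observed = disc_obs,
                                  replicated = disc_rep),
         statistic = "chisq")
  }
}
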