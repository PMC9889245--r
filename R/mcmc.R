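# Fitting front end: prepares data structures, runs the compiled
# Metropolis-within-Gibbs core once per chain, wraps results.

# flatten panel covariates to the (N*T) x P matrix the core expects
# (cell order: area fastest, then year)
panel_X <- function(panel) {
  N <- length(panel$area_ids); T <- length(panel$years)
  P <- length(panel$covariate_names)
  X <- matrix(0, N * T, P)
  for (p in seq_len(P)) X[, p] <- as.vector(panel$covariates[, , p])
  colnames(X) <- panel$covariate_names
  X
}

# Cholesky factor of an (alpha, beta) proposal covariance, from the ML
# Poisson regression; diagonal fallback when the GLM is unusable.
proposal_chol <- function(panel, config) {
  P <- length(panel$covariate_names)
  if (config$prior_only || sum(panel$counts) == 0) {
    return(diag(c(1, rep(sqrt(config$beta_prior_variance), P)), P + 1))
  }
  X <- panel_X(panel)
  y <- as.vector(panel$counts)
  fit <- tryCatch(
    glm(y ~ X, family = poisson()),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || any(!is.finite(vcov(fit))))
    return(diag(0.1, P + 1))
  V <- vcov(fit)
  L <- tryCatch(t(chol(V)), error = function(e) diag(sqrt(diag(V))))
  unname(L)
}

#' Fit the space-time CAR Poisson model by MCMC
#'
#' Runs `config$n_chains` independent Metropolis-within-Gibbs chains from
#' over-dispersed starting points.  Each iteration updates the
#' (alpha, beta) block by multivariate-normal Metropolis (proposal shaped
#' by the Poisson-GLM covariance, scale adapted during burn-in), the
#' spatial field and national trend by single-site Metropolis, the
#' interaction rows by Metropolis proposals confined to the row-sum-zero
#' subspace, and the variance components by conjugate Gibbs.  Retained
#' draws satisfy the identifiability constraints: `sum(phi) = 0` (ICAR,
#' connected graphs), `sum(xi) = 0`, and `sum_t delta[i, t] = 0` for every
#' area.
#'
#' @param panel An [area_panel]; covariates should be centred (see
#'   [center_covariates]); uncentred covariates trigger a warning.
#' @param graph An `adjacency_graph` over the panel's areas (may be `NULL`
#'   when `include_spatial = FALSE`).
#' @param config A [model_config].
#' @return An `stcar_fit` object: per-chain draw matrices for `alpha`,
#'   `beta`, `phi`, `xi`, `delta` (cells area-fastest), the three
#'   variances, acceptance rates and adapted scales, plus the config and
#'   panel dimensions.
#' @export
run_mcmc <- function(panel, graph = NULL, config = model_config()) {
  N <- length(panel$area_ids); T <- length(panel$years)
  P <- length(panel$covariate_names)
  if (P > 0 && !panel$centered && !config$prior_only)
    warning("covariates are not centred; consider center_covariates()")
  if (config$include_spatial) {
    stopifnot(!is.null(graph))
    if (!identical(graph$area_ids, panel$area_ids))
      stop("graph and panel area ids differ")
    nb0 <- lapply(graph$nb, function(v) as.integer(v - 1L))
    n_iso <- sum(graph$n == 0)
    rank_phi <- N - graph$n_components + n_iso
  } else {
    nb0 <- rep(list(integer(0)), N)
    n_iso <- N; rank_phi <- 0L
  }
  if (config$include_temporal && T < 2)
    stop("temporal random walk needs T >= 2")
  X <- panel_X(panel)
  L <- proposal_chol(panel, config)
  fv <- config$fixed_variances
  n_keep <- ceiling(config$n_samples / config$n_chains)
  ybar <- mean(panel$counts)

  chains <- vector("list", config$n_chains)
  t0 <- proc.time()[["elapsed"]]
  for (k in seq_len(config$n_chains)) {
    set.seed(config$seed + k - 1)
    alpha0 <- log(ybar + 0.01) + rnorm(1, 0, 0.2)
    beta0 <- rnorm(P, 0, 0.1)
    phi0 <- if (config$include_spatial) rnorm(N, 0, 0.1) else numeric(N)
    if (config$include_spatial && config$spatial_structure == "icar")
      phi0 <- phi0 - mean(phi0)
    xi0 <- if (config$include_temporal) {
      z <- rnorm(T, 0, 0.1); z - mean(z)
    } else numeric(T)
    delta0 <- if (config$include_interaction) {
      z <- matrix(rnorm(N * T, 0, 0.05), N, T); z - rowMeans(z)
    } else matrix(0, N, T)
    v0 <- function(fix, def) if (is.finite(fix)) fix else def
    res <- stcar_mcmc_cpp(
      y = panel$counts, X = X, nb = nb0,
      n_isolated = n_iso, rank_phi = as.integer(rank_phi),
      n_burnin = config$n_burnin, n_keep = n_keep, thin = config$thin,
      inc_spatial = config$include_spatial,
      inc_temporal = config$include_temporal,
      inc_interaction = config$include_interaction,
      iid_spatial = config$spatial_structure == "iid",
      prior_only = config$prior_only,
      prior_shape = config$prior_precision_shape,
      prior_rate = config$prior_precision_rate,
      beta_var = config$beta_prior_variance,
      fix_var_phi = is.finite(fv["phi"]),
      fix_var_xi = is.finite(fv["xi"]),
      fix_var_delta = is.finite(fv["delta"]),
      var_phi0 = v0(fv["phi"], 0.1), var_xi0 = v0(fv["xi"], 0.01),
      var_delta0 = v0(fv["delta"], 0.01),
      alpha0 = alpha0, beta0 = beta0, phi0 = phi0, xi0 = xi0,
      delta0 = delta0, prop_chol = L,
      prop_scales = unname(config$proposal_scales),
      adapt = config$adapt,
      upd_ab = TRUE, upd_phi = TRUE, upd_xi = TRUE, upd_delta = TRUE,
      upd_vars = TRUE, eta_bound = config$eta_bound)
    colnames(res$beta) <- panel$covariate_names
    chains[[k]] <- res
  }
  structure(list(chains = chains, config = config,
                 area_ids = panel$area_ids, years = panel$years,
                 covariate_names = panel$covariate_names,
                 n_keep = n_keep,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "stcar_fit")
}

#' @export
print.stcar_fit <- function(x, ...) {
  cat("stcar_fit:", length(x$chains), "chain(s) x", x$n_keep,
      "retained draws,", length(x$area_ids), "areas x",
      length(x$years), "years\n")
  acc <- round(x$chains[[1]]$acceptance, 3)
  cat("  acceptance (chain 1):",
      paste(names(acc), acc, sep = "=", collapse = " "), "\n")
  cat("  elapsed:", round(x$elapsed, 1), "s\n")
  invisible(x)
}

#' Extract pooled posterior draws of one parameter block
#'
#' @param fit An `stcar_fit`.
#' @param param One of `"alpha"`, `"beta"`, `"phi"`, `"xi"`, `"delta"`,
#'   `"var_phi"`, `"var_xi"`, `"var_delta"`.
#' @return A vector (scalar parameters) or matrix (draws x components,
#'   chains stacked) of posterior draws.  `delta` columns are in
#'   area-fastest cell order, reshapeable to `(draws, N, T)`.
#' @export
fit_draws <- function(fit, param) {
  parts <- lapply(fit$chains, `[[`, param)
  if (is.matrix(parts[[1]])) do.call(rbind, parts) else unlist(parts)
}

#' One sweep of a single sampler block
#'
#' Runs exactly one iteration of the compiled sampler with only the named
#' block active, starting from `state`.  Intended for targeted validation
#' of individual updates rather than production fitting.
#'
#' @param block One of `"alpha_beta"`, `"phi"`, `"xi"`, `"delta"`,
#'   `"variances"`.
#' @param state List with entries `alpha`, `beta`, `phi`, `xi`, `delta`
#'   (N x T), `var_phi`, `var_xi`, `var_delta`.
#' @param panel An [area_panel].
#' @param graph An `adjacency_graph` (or `NULL` without a spatial term).
#' @param config A [model_config].
#' @return The updated `state`, with an `acceptance` attribute giving the
#'   per-block acceptance rates of the sweep.
#' @export
update_latent_block <- function(block, state, panel, graph = NULL,
                                config = model_config()) {
  block <- match.arg(block,
                     c("alpha_beta", "phi", "xi", "delta", "variances"))
  N <- length(panel$area_ids); T <- length(panel$years)
  P <- length(panel$covariate_names)
  if (config$include_spatial) {
    nb0 <- lapply(graph$nb, function(v) as.integer(v - 1L))
    n_iso <- sum(graph$n == 0)
    rank_phi <- N - graph$n_components + n_iso
  } else {
    nb0 <- rep(list(integer(0)), N); n_iso <- N; rank_phi <- 0L
  }
  fv <- config$fixed_variances
  res <- stcar_mcmc_cpp(
    y = panel$counts, X = panel_X(panel), nb = nb0,
    n_isolated = n_iso, rank_phi = as.integer(rank_phi),
    n_burnin = 0L, n_keep = 1L, thin = 1L,
    inc_spatial = config$include_spatial,
    inc_temporal = config$include_temporal,
    inc_interaction = config$include_interaction,
    iid_spatial = config$spatial_structure == "iid",
    prior_only = config$prior_only,
    prior_shape = config$prior_precision_shape,
    prior_rate = config$prior_precision_rate,
    beta_var = config$beta_prior_variance,
    fix_var_phi = is.finite(fv["phi"]), fix_var_xi = is.finite(fv["xi"]),
    fix_var_delta = is.finite(fv["delta"]),
    var_phi0 = state$var_phi, var_xi0 = state$var_xi,
    var_delta0 = state$var_delta,
    alpha0 = state$alpha, beta0 = state$beta, phi0 = state$phi,
    xi0 = state$xi, delta0 = state$delta,
    prop_chol = proposal_chol(panel, config),
    prop_scales = unname(config$proposal_scales), adapt = FALSE,
    upd_ab = block == "alpha_beta", upd_phi = block == "phi",
    upd_xi = block == "xi", upd_delta = block == "delta",
    upd_vars = block == "variances", eta_bound = config$eta_bound)
  out <- res$final_state
  attr(out, "acceptance") <- res$acceptance
  out
}

#' Fit the competing model family for WAIC comparison
#'
#' Named structural variants of the full space-time model: dropping the
#' interaction, exchanging the ICAR spatial prior for an iid one, dropping
#' the spatial term, or dropping the national trend.
#'
#' @param panel An [area_panel].
#' @param graph An `adjacency_graph`.
#' @param config Base [model_config]; each variant modifies its structure
#'   flags.
#' @param variants Character vector from `"full"`, `"no_interaction"`,
#'   `"iid_spatial"`, `"no_spatial"`, `"no_temporal"`.
#' @return Named list of `stcar_fit` objects.
#' @export
competing_model_family <- function(panel, graph, config = model_config(),
                                   variants = c("full", "no_interaction",
                                                "iid_spatial", "no_spatial",
                                                "no_temporal")) {
  variants <- match.arg(variants, several.ok = TRUE)
  mods <- list(
    full = list(),
    no_interaction = list(include_interaction = FALSE),
    iid_spatial = list(spatial_structure = "iid"),
    no_spatial = list(include_spatial = FALSE),
    no_temporal = list(include_temporal = FALSE))
  fits <- lapply(variants, function(v) {
    cfg <- config
    for (nm in names(mods[[v]])) cfg[[nm]] <- mods[[v]][[nm]]
    run_mcmc(panel, graph, cfg)
  })
  setNames(fits, variants)
}

#' Monte-Carlo standard error of a chain mean (batch means)
#'
#' @param x Numeric vector of (possibly autocorrelated) draws.
#' @param n_batches Number of batches.
#' @return Estimated standard error of `mean(x)`.
#' @export
mcse_mean <- function(x, n_batches = 30) {
  n <- length(x)
  b <- max(2, floor(n / n_batches))
  m <- floor(n / b)
  bm <- vapply(seq_len(m), function(k) mean(x[((k - 1) * b + 1):(k * b)]),
               numeric(1))
  sd(bm) / sqrt(m)
}
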