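#' Model and sampler configuration
#'
#' Collects the prior specification, model-structure flags, and MCMC
#' settings.  Defaults match the reference analysis: Gamma(0.5, 0.005)
#' priors on the inverse variance components, a flat prior on the intercept,
#' Normal(0, 1000) priors on the regression coefficients, and 20,000 post
#' burn-in draws in total across 4 chains.
#'
#' @param prior_precision_shape,prior_precision_rate Shape and rate of the
#'   Gamma prior on each precision (inverse variance).
#' @param beta_prior_variance Prior variance of each regression coefficient.
#' @param n_chains Number of independent chains.
#' @param n_burnin Burn-in iterations per chain (adaptation happens here).
#' @param n_samples Total retained draws across all chains.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain k uses `seed + k - 1`.
#' @param include_spatial,include_temporal,include_interaction Structure
#'   flags defining the competing-model family.
#' @param spatial_structure `"icar"` (intrinsic CAR) or `"iid"`
#'   (exchangeable normal) spatial prior.
#' @param fixed_variances Named numeric vector; finite entries for
#'   `"phi"`, `"xi"`, `"delta"` hold that variance component fixed instead
#'   of sampling it (used by small-panel oracle checks).
#' @param proposal_scales Initial proposal scales for the
#'   (alpha,beta)/phi/xi/delta blocks; adapted during burn-in.
#' @param adapt Adapt proposal scales during burn-in?
#' @param prior_only Drop the likelihood and sample the prior (validation
#'   tool).
#' @param eta_bound Proposals pushing any log-mean beyond this bound are
#'   rejected (numerical overflow guard).
#' @return A `stcar_config` list.
#' @export
model_config <- function(prior_precision_shape = 0.5,
                         prior_precision_rate = 0.005,
                         beta_prior_variance = 1000,
                         n_chains = 4, n_burnin = 20000, n_samples = 20000,
                         thin = 1, seed = 1,
                         include_spatial = TRUE, include_temporal = TRUE,
                         include_interaction = TRUE,
                         spatial_structure = c("icar", "iid"),
                         fixed_variances = c(phi = NA, xi = NA, delta = NA),
                         proposal_scales = c(alpha_beta = 1, phi = 0.1,
                                             xi = 0.1, delta = 0.1),
                         adapt = TRUE, prior_only = FALSE, eta_bound = 30) {
  spatial_structure <- match.arg(spatial_structure)
  stopifnot(prior_precision_shape > 0, prior_precision_rate > 0,
            beta_prior_variance > 0, n_samples >= 1, n_chains >= 1,
            n_burnin >= 0, thin >= 1)
  fv <- c(phi = NA_real_, xi = NA_real_, delta = NA_real_)
  fv[names(fixed_variances)] <- as.numeric(fixed_variances)
  structure(list(prior_precision_shape = prior_precision_shape,
                 prior_precision_rate = prior_precision_rate,
                 beta_prior_variance = beta_prior_variance,
                 n_chains = n_chains, n_burnin = n_burnin,
                 n_samples = n_samples, thin = thin, seed = seed,
                 include_spatial = include_spatial,
                 include_temporal = include_temporal,
                 include_interaction = include_interaction,
                 spatial_structure = spatial_structure,
                 fixed_variances = fv,
                 proposal_scales = proposal_scales,
                 adapt = adapt, prior_only = prior_only,
                 eta_bound = eta_bound),
            class = "stcar_config")
}

#' Linear predictor of one panel cell
#'
#' `log(mu_it) = alpha + X_it beta + phi_i + xi_t + delta_it`.
#'
#' @param alpha Intercept (log scale).
#' @param beta Coefficient vector.
#' @param x Covariate values of the cell (same length as `beta`).
#' @param phi_i,xi_t,delta_it Spatial, temporal, and interaction effects of
#'   the cell.
#' @return The log mean, a finite scalar.
#' @export
log_mean <- function(alpha, beta, x, phi_i = 0, xi_t = 0, delta_it = 0) {
  vals <- c(alpha, beta, x, phi_i, xi_t, delta_it)
  if (any(!is.finite(vals))) stop("non-finite input to log_mean")
  alpha + sum(x * beta) + phi_i + xi_t + delta_it
}

#' Full-conditional prior parameters of one ICAR effect
#'
#' Under the intrinsic CAR prior, `phi_i | phi_{-i}` is Normal with mean the
#' average of the neighbours' values and variance `var_phi / n_i`.  Isolated
#' areas (no neighbours) get the exchangeable fallback Normal(0, var_phi).
#'
#' @param i Area index.
#' @param phi Current vector of spatial effects.
#' @param graph An `adjacency_graph`.
#' @param var_phi Conditional variance parameter.
#' @return A list with `mean` and `variance`.
#' @export
car_full_conditional_params <- function(i, phi, graph, var_phi) {
  nb <- graph$nb[[i]]
  if (length(nb) == 0) return(list(mean = 0, variance = var_phi))
  list(mean = mean(phi[nb]), variance = var_phi / length(nb))
}

#' Gibbs full-conditional parameters of the three precisions
#'
#' Conjugate Gamma full conditionals for the inverse variance components:
#' shape = prior shape + rank/2, rate = prior rate + quadratic form / 2,
#' where the quadratic forms are `phi' (D - W) phi` (plus `phi_i^2` for any
#' isolated area), the summed squared RW1 increments of `xi`, and the summed
#' squared increments of every row of `delta`; the ranks are
#' `N - #components (+ #isolated)`, `T - 1`, and `N (T - 1)`.
#'
#' @param state List with any of `phi` (length N), `xi` (length T),
#'   `delta` (N x T).
#' @param graph An `adjacency_graph` (needed when `phi` is present).
#' @param config A [model_config] (priors and spatial structure).
#' @return A list with one `c(shape, rate)` entry per supplied field.
#' @export
variance_full_conditionals <- function(state, graph = NULL,
                                       config = model_config()) {
  a <- config$prior_precision_shape; b <- config$prior_precision_rate
  out <- list()
  if (!is.null(state$phi)) {
    phi <- state$phi
    if (config$spatial_structure == "iid") {
      qf <- sum(phi^2); rk <- length(phi)
    } else {
      stopifnot(!is.null(graph))
      qf <- 0
      for (i in seq_along(phi))
        for (j in graph$nb[[i]])
          if (j > i) qf <- qf + (phi[i] - phi[j])^2
      iso <- which(graph$n == 0)
      qf <- qf + sum(phi[iso]^2)
      rk <- length(phi) - graph$n_components + length(iso)
    }
    out$phi <- c(shape = a + rk / 2, rate = b + qf / 2)
  }
  if (!is.null(state$xi)) {
    xi <- state$xi
    out$xi <- c(shape = a + (length(xi) - 1) / 2,
                rate = b + sum(diff(xi)^2) / 2)
  }
  if (!is.null(state$delta)) {
    d <- state$delta
    qf <- sum(t(apply(d, 1, diff))^2)
    out$delta <- c(shape = a + nrow(d) * (ncol(d) - 1) / 2,
                   rate = b + qf / 2)
  }
  out
}

#' One conjugate Gibbs draw of the variance components
#'
#' Draws each precision from its Gamma full conditional (see
#' [variance_full_conditionals]) and returns the implied variances, floored
#' at 1e-12 against numerical zeros.
#'
#' @inheritParams variance_full_conditionals
#' @return Named numeric vector of sampled variances (one per supplied
#'   field).
#' @export
update_variances <- function(state, graph = NULL, config = model_config()) {
  fc <- variance_full_conditionals(state, graph, config)
  out <- vapply(fc, function(p) {
    tau <- rgamma(1, shape = p["shape"], rate = p["rate"])
    if (tau < 1e-12) {
      warning("precision draw at numerical zero; flooring")
      tau <- 1e-12
    }
    1 / tau
  }, numeric(1))
  setNames(out, paste0("var_", names(fc)))
}
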