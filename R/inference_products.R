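# Posterior products: marginal effects, hotspots, expected counts,
# area-specific trends, deprivation gradients.

post_summary <- function(draws, probs = c(0.025, 0.975)) {
  q <- quantile(draws, probs, names = FALSE)
  c(mean = mean(draws), sd = sd(draws), lower = q[1], upper = q[2])
}

# exceedance with ties counted as 1/2 (exactly-zero draws arise in
# degenerate variants where a field is switched off)
exceed_prob <- function(draws) mean(draws > 0) + 0.5 * mean(draws == 0)

#' Covariate marginal effects
#'
#' The average change in expected count per unit change of covariate p:
#' for each retained draw, the fitted Poisson means are averaged over every
#' (area, year) cell and multiplied by that draw's coefficient,
#' `ME_p = mean(mu) * beta_p`; the draws of `ME_p` are then summarised.
#'
#' @param fit An `stcar_fit`.
#' @param panel The fitted [area_panel].
#' @param mu Optional precomputed [mu_draws] matrix.
#' @return Data frame with posterior mean, sd and 95% credible interval of
#'   the marginal effect of each covariate.
#' @export
marginal_effects <- function(fit, panel, mu = NULL) {
  if (is.null(mu)) mu <- mu_draws(fit, panel)
  beta <- fit_draws(fit, "beta")
  mubar <- rowMeans(mu)
  out <- t(vapply(seq_len(ncol(beta)),
                  function(p) post_summary(mubar * beta[, p]),
                  numeric(4)))
  data.frame(covariate = fit$covariate_names, out,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hotspot exceedance probabilities
#'
#' The posterior probability, per area, that the exponentiated spatial
#' residual exceeds one, `P(exp(phi_i) > 1)` (equivalently `phi_i > 0`).
#' Areas whose probability exceeds the threshold are flagged as having
#' excess event frequency after covariate adjustment.
#'
#' @param fit An `stcar_fit`.
#' @param threshold Flagging threshold (default 0.9).
#' @return Data frame with per-area `prob` and logical `hotspot` flag.
#' @export
hotspot_probability <- function(fit, threshold = 0.9) {
  phi <- fit_draws(fit, "phi")
  prob <- apply(phi, 2, exceed_prob)
  data.frame(area_id = fit$area_ids, prob = prob,
             hotspot = prob > threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Posterior expected counts and between-area gaps
#'
#' Summarises the fitted mean `mu_it` of every cell, and for each year the
#' gap between the areas with the highest and lowest expected counts.  The
#' gap is computed per draw (max over areas minus min over areas, which
#' areas may differ between draws) and then summarised, so its credible
#' interval is a genuine posterior interval of the gap.
#'
#' @param fit An `stcar_fit`.
#' @param panel The fitted [area_panel].
#' @param mu Optional precomputed [mu_draws] matrix.
#' @return List with `cells` (data frame of per-cell posterior summaries)
#'   and `yearly_gap` (per-year posterior summary of the extreme-area
#'   difference).
#' @export
expected_counts <- function(fit, panel, mu = NULL) {
  if (is.null(mu)) mu <- mu_draws(fit, panel)
  N <- length(fit$area_ids); T <- length(fit$years)
  cells <- t(apply(mu, 2, post_summary))
  cells <- data.frame(area_id = rep(fit$area_ids, times = T),
                      year = rep(fit$years, each = N),
                      cells, stringsAsFactors = FALSE, row.names = NULL)
  gap <- t(vapply(seq_len(T), function(t) {
    block <- mu[, (t - 1) * N + seq_len(N), drop = FALSE]
    g <- apply(block, 1, max) - apply(block, 1, min)
    post_summary(g)
  }, numeric(4)))
  yearly_gap <- data.frame(year = fit$years, gap,
                           stringsAsFactors = FALSE, row.names = NULL)
  list(cells = cells, yearly_gap = yearly_gap)
}

#' Area-specific time trends and exceedance of the national trend
#'
#' Each area's trend component is the sum of the national trend and its
#' space-time interaction, `xi_t + delta_it`.  The probability that an
#' area's incidence exceeds the national one in year t is taken from the
#' interaction alone, `P(delta_it > 0)` (ties counted 1/2), since under the
#' additive decomposition the interaction is exactly the area-minus-national
#' difference on the log scale.
#'
#' @param fit An `stcar_fit`.
#' @return List with `national` (per-year posterior median and 95% band of
#'   `xi_t`), `area_trend` (posterior mean of `xi_t + delta_it` per cell),
#'   and `exceed_prob` (N x T matrix of exceedance probabilities).
#' @export
area_trend <- function(fit) {
  N <- length(fit$area_ids); T <- length(fit$years)
  xi <- fit_draws(fit, "xi")
  national <- data.frame(
    year = fit$years,
    median = apply(xi, 2, median),
    lower = apply(xi, 2, quantile, 0.025),
    upper = apply(xi, 2, quantile, 0.975), row.names = NULL)
  if (fit$config$include_interaction) {
    delta <- fit_draws(fit, "delta")
    ex <- matrix(apply(delta, 2, exceed_prob), N, T,
                 dimnames = list(fit$area_ids, fit$years))
    trend <- delta + xi[, rep(seq_len(T), each = N), drop = FALSE]
    tr <- matrix(colMeans(trend), N, T,
                 dimnames = list(fit$area_ids, fit$years))
  } else {
    ex <- matrix(0.5, N, T, dimnames = list(fit$area_ids, fit$years))
    tr <- matrix(colMeans(xi)[rep(seq_len(T), each = N)], N, T,
                 dimnames = list(fit$area_ids, fit$years))
  }
  list(national = national, area_trend = tr, exceed_prob = ex)
}

#' Deprivation gradient of expected counts
#'
#' For two chosen years, the per-draw ordinary least-squares slope of
#' `log(mu_it)` on the (uncentred) deprivation covariate across areas,
#' summarised per year, together with the posterior of the between-year
#' slope difference -- a steepening slope indicates a widening
#' socio-economic gap.
#'
#' @param fit An `stcar_fit`.
#' @param panel The fitted [area_panel].
#' @param covariate Name of the deprivation covariate column.
#' @param years Length-2 vector of years to compare.
#' @param mu Optional precomputed [mu_draws] matrix.
#' @return List with `slopes` (per-year posterior summary) and
#'   `difference` (posterior summary of slope(year2) - slope(year1)).
#' @export
deprivation_gradient <- function(fit, panel, covariate,
                                 years = range(panel$years), mu = NULL) {
  p <- match(covariate, panel$covariate_names)
  if (is.na(p)) stop("covariate '", covariate, "' not in panel")
  stopifnot(length(years) == 2, all(years %in% panel$years))
  if (is.null(mu)) mu <- mu_draws(fit, panel)
  N <- length(fit$area_ids)
  slope_draws <- lapply(years, function(yr) {
    t <- match(yr, panel$years)
    x <- panel$covariates[, t, p]
    if (panel$centered && !is.null(panel$offsets))
      x <- x + panel$offsets[[covariate]]
    if (var(x) == 0) stop("covariate constant across areas in year ", yr)
    lmu <- log(mu[, (t - 1) * N + seq_len(N), drop = FALSE])
    xc <- x - mean(x)
    as.vector(lmu %*% xc) / sum(xc^2)  # per-draw OLS slope
  })
  slopes <- data.frame(year = years,
                       t(vapply(slope_draws, post_summary, numeric(4))),
                       row.names = NULL)
  list(slopes = slopes,
       difference = post_summary(slope_draws[[2]] - slope_draws[[1]]))
}
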