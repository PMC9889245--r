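# Shared fixtures: tiny graphs, panels, hand-built fit objects, and the
# independent grid-integration oracle used to validate the sampler.

# adjacency over explicit neighbour index lists (bypasses the readers so
# graph tests and model tests stay independent)
graph_from_nb <- function(nb, area_ids = sprintf("a%02d", seq_along(nb))) {
  n <- lengths(nb)
  comp <- integer(length(nb))
  cur <- 0L
  for (s in seq_along(nb)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, nb[[v]][comp[nb[[v]]] == 0])
    }
  }
  structure(list(area_ids = area_ids, nb = lapply(nb, as.integer),
                 n = stats::setNames(as.integer(n), area_ids),
                 components = comp, n_components = max(comp)),
            class = "adjacency_graph")
}

two_area_graph <- function() graph_from_nb(list(2L, 1L), c("A", "B"))

# minimal complete panel with arbitrary counts/covariates
toy_panel <- function(counts, covariates = NULL, centered = TRUE, ...) {
  N <- nrow(counts); T <- ncol(counts)
  area_panel(LETTERS[seq_len(N)], seq_len(T), counts,
             covariates = covariates, centered = centered, ...)
}

# hand-built stcar_fit carrying prescribed draws, for testing posterior
# products without running a sampler.  Arguments are draw matrices
# (S x dim); delta in area-fastest cell order.
fake_fit <- function(alpha, beta = NULL, phi = NULL, xi = NULL,
                     delta = NULL, area_ids = NULL, years = NULL,
                     include_interaction = !is.null(delta)) {
  S <- length(alpha)
  if (is.null(phi)) phi <- matrix(0, S, 1)
  if (is.null(xi)) xi <- matrix(0, S, 1)
  N <- ncol(phi); T <- ncol(xi)
  if (is.null(beta)) beta <- matrix(0, S, 0)
  if (is.null(delta)) delta <- matrix(0, S, N * T)
  if (is.null(area_ids)) area_ids <- LETTERS[seq_len(N)]
  if (is.null(years)) years <- seq_len(T)
  cfg <- model_config(include_interaction = include_interaction,
                      n_chains = 1, n_burnin = 0, n_samples = S)
  structure(list(chains = list(list(
    alpha = alpha, beta = beta, phi = phi, xi = xi, delta = delta,
    var_phi = rep(1, S), var_xi = rep(1, S), var_delta = rep(1, S))),
    config = cfg, area_ids = area_ids, years = years,
    covariate_names = colnames(beta) %||% paste0("x", seq_len(ncol(beta))),
    n_keep = S, elapsed = 0), class = "stcar_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: dense-grid numerical integration of the posterior of
# (alpha, beta, u, s) for a 2-area x 2-year, 1-covariate panel without
# interaction, phi = (u, -u), xi = (s, -s), fixed variances.  Returns the
# posterior means of alpha and beta.
grid_oracle_2x2 <- function(y, x, var_phi, var_xi, beta_var = 1000,
                            n_grid = 61) {
  A <- seq(log(mean(y)) - 2, log(mean(y)) + 2, length.out = n_grid)
  B <- seq(-2.5, 2.5, length.out = n_grid)
  U <- seq(-2.5, 2.5, length.out = n_grid)
  S <- seq(-1.5, 1.5, length.out = n_grid)
  lp <- array(0, rep(n_grid, 4))
  for (i in 1:2) for (t in 1:2) {
    su <- if (i == 1) 1 else -1
    st <- if (t == 1) 1 else -1
    eta <- outer(outer(outer(A, x[i, t] * B, `+`), su * U, `+`), st * S, `+`)
    lp <- lp + y[i, t] * eta - exp(eta)
  }
  lp <- lp - as.vector(outer(outer(outer(
    A * 0, B^2 / (2 * beta_var), `+`),
    (2 * U)^2 / (2 * var_phi), `+`), (2 * S)^2 / (2 * var_xi), `+`))
  w <- exp(lp - max(lp))
  list(alpha = sum(apply(w, 1, sum) * A) / sum(w),
       beta = sum(apply(w, 2, sum) * B) / sum(w))
}

# pooled MCSE of a pooled posterior mean across chains
pooled_mcse <- function(fit, param, col = NULL) {
  per <- vapply(fit$chains, function(ch) {
    x <- ch[[param]]
    if (!is.null(col)) x <- x[, col]
    mcse_mean(x)^2
  }, numeric(1))
  sqrt(mean(per) / length(per))
}

# write a GeoJSON FeatureCollection of axis-aligned unit squares given by
# their lower-left corners; returns the temp file path
write_squares_geojson <- function(corners, ids) {
  feats <- lapply(seq_along(ids), function(k) {
    x <- corners[k, 1]; y <- corners[k, 2]
    ring <- list(c(x, y), c(x + 1, y), c(x + 1, y + 1), c(x, y + 1),
                 c(x, y))
    list(type = "Feature",
         properties = list(area_id = ids[k]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  path
}
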