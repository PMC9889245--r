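# Reproducible pipeline: simulate -> fit -> diagnose -> summarise, driven
# by a single configuration document (R list or YAML file).

#' Run the modelling pipeline
#'
#' Executes the requested stages in order, writing plain-CSV artefacts plus
#' a JSON manifest (config snapshot, seeds, input digests, stage timings,
#' package version) sufficient to re-run the pipeline bit-identically.
#'
#' Configuration layout (all sections optional except `out_dir`):
#' \describe{
#'   \item{stages}{character vector from `"simulate"`, `"fit"`,
#'     `"diagnose"`, `"summarise"`; default all.}
#'   \item{simulate}{`rows`, `cols`, `years`, `seed`, plus any
#'     [simulate_panel] parameter (`alpha`, `beta`, `var_phi`, ...).}
#'   \item{data}{alternatively, paths: `panel`, `adjacency`, and reader
#'     options (`exclude_areas`, column names).}
#'   \item{model}{any [model_config] argument, e.g. `n_chains`,
#'     `n_burnin`, `n_samples`, `seed`, `include_interaction`.}
#'   \item{summarise}{`deprivation_covariate`, `gradient_years`,
#'     `hotspot_threshold`.}
#' }
#'
#' @param config A nested list as above, or the path of a YAML file
#'   holding one.
#' @param out_dir Output directory (created if absent); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list with the panel, fit, diagnostics and summary
#'   objects produced; artefacts are written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "fit", "diagnose", "summarise")
  bad <- setdiff(stages, c("simulate", "fit", "diagnose", "summarise"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  manifest <- list(package_version = as.character(utils::packageVersion("stcar")),
                   config = config, stages = stages, timings = list(),
                   inputs = list())
  result <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    v
  }

  if ("simulate" %in% stages) {
    sc <- config$simulate %||% list()
    rows <- sc$rows %||% 10; cols <- sc$cols %||% 10
    graph <- make_lattice_graph(rows, cols)
    args <- sc[setdiff(names(sc), c("rows", "cols", "years"))]
    args$graph <- graph
    if (!is.null(sc$years)) args$T <- sc$years
    sim <- timed("simulate", do.call(simulate_panel, args))
    panel <- sim$panel
    write_panel(panel, file.path(out_dir, "panel.csv"))
    edges <- do.call(rbind, lapply(seq_along(graph$nb), function(i) {
      js <- graph$nb[[i]][graph$nb[[i]] > i]
      if (length(js) == 0) return(NULL)
      data.frame(from = graph$area_ids[i], to = graph$area_ids[js])
    }))
    write.csv(edges, file.path(out_dir, "adjacency.csv"), row.names = FALSE)
    tr <- sim$truth
    jsonlite::write_json(
      tr[c("alpha", "beta", "var_phi", "var_xi", "var_delta", "seed")],
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    result$panel <- panel; result$graph <- graph; result$truth <- tr
  } else {
    dc <- config$data
    if (is.null(dc$panel)) stop("no simulate stage and no data$panel path")
    panel <- timed("read", read_panel(
      dc$panel, exclude_areas = dc$exclude_areas))
    graph <- read_adjacency(dc$adjacency, panel$area_ids)
    manifest$inputs <- as.list(tools::md5sum(c(dc$panel, dc$adjacency)))
    result$panel <- panel; result$graph <- graph
  }
  panel <- center_covariates(panel)
  result$panel <- panel

  fit <- NULL
  if ("fit" %in% stages) {
    cfg <- do.call(model_config, config$model %||% list())
    fit <- timed("fit", run_mcmc(panel, graph, cfg))
    result$fit <- fit
    acc <- fit$chains[[1]]$acceptance
    write.csv(data.frame(block = names(acc), acceptance = as.numeric(acc)),
              file.path(out_dir, "acceptance.csv"), row.names = FALSE)
  }

  if ("diagnose" %in% stages && !is.null(fit)) {
    diag <- timed("diagnose", {
      mu <- mu_draws(fit, panel)
      list(rhat = if (length(fit$chains) >= 2) rhat_table(fit),
           waic = waic(fit, panel, mu = mu),
           bayes_p = bayesian_pvalue(fit, panel, mu = mu))
    })
    result$diagnostics <- diag
    if (!is.null(diag$rhat))
      write.csv(data.frame(parameter = names(diag$rhat),
                           rhat = as.numeric(diag$rhat)),
                file.path(out_dir, "rhat.csv"), row.names = FALSE)
    write.csv(data.frame(waic = diag$waic$waic, lppd = diag$waic$lppd,
                         p_waic = diag$waic$p_waic,
                         avg_bayes_p = diag$bayes_p$average),
              file.path(out_dir, "fit_quality.csv"), row.names = FALSE)
  }

  if ("summarise" %in% stages && !is.null(fit)) {
    sm <- config$summarise %||% list()
    summ <- timed("summarise", {
      mu <- mu_draws(fit, panel)
      res <- list(marginal_effects = marginal_effects(fit, panel, mu = mu),
                  hotspots = hotspot_probability(
                    fit, threshold = sm$hotspot_threshold %||% 0.9),
                  trends = area_trend(fit),
                  expected = expected_counts(fit, panel, mu = mu))
      if (!is.null(sm$deprivation_covariate))
        res$gradient <- deprivation_gradient(
          fit, panel, sm$deprivation_covariate,
          years = sm$gradient_years %||% range(panel$years), mu = mu)
      res
    })
    result$summary <- summ
    write.csv(summ$marginal_effects,
              file.path(out_dir, "marginal_effects.csv"), row.names = FALSE)
    write.csv(summ$hotspots, file.path(out_dir, "hotspots.csv"),
              row.names = FALSE)
    tr <- summ$trends
    trends_df <- data.frame(
      area_id = rep(rownames(tr$exceed_prob), times = ncol(tr$exceed_prob)),
      year = rep(colnames(tr$exceed_prob), each = nrow(tr$exceed_prob)),
      trend = as.vector(tr$area_trend),
      exceed_prob = as.vector(tr$exceed_prob))
    write.csv(trends_df, file.path(out_dir, "trends.csv"), row.names = FALSE)
    write.csv(tr$national, file.path(out_dir, "national_trend.csv"),
              row.names = FALSE)
    write.csv(summ$expected$cells, file.path(out_dir, "expected_counts.csv"),
              row.names = FALSE)
    write.csv(summ$expected$yearly_gap, file.path(out_dir, "yearly_gap.csv"),
              row.names = FALSE)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
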