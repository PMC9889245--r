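#' Construct and validate an areal count panel
#'
#' An `area_panel` holds a complete area-by-year panel of non-negative
#' integer event counts together with area-level covariates.  Time-constant
#' covariates are stored per (area, year) cell, repeated across years.
#'
#' @param area_ids Character vector of unique area identifiers (length N).
#' @param years Integer vector of consecutive years (length T).
#' @param counts N x T integer matrix of event counts, `counts[i, t]` the
#'   count for area `area_ids[i]` in `years[t]`.
#' @param covariates N x T x P numeric array of covariate values (P may be 0).
#' @param covariate_names Character vector of P covariate labels.
#' @param centered Logical; have the covariates been mean-centred?
#' @param offsets Named numeric vector of centering offsets (grand means
#'   subtracted from each covariate column), or `NULL`.
#' @return An object of class `area_panel`.
#' @export
area_panel <- function(area_ids, years, counts, covariates = NULL,
                       covariate_names = NULL, centered = FALSE,
                       offsets = NULL) {
  area_ids <- as.character(area_ids)
  years <- as.integer(years)
  if (anyDuplicated(area_ids)) stop("area_ids must be unique")
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be consecutive")
  counts <- as.matrix(counts)
  N <- length(area_ids); T <- length(years)
  if (!all(dim(counts) == c(N, T)))
    stop("counts must be an N x T matrix (", N, " x ", T, ")")
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop("incomplete panel: missing count for area '", area_ids[bad[1]],
         "', year ", years[bad[2]])
  }
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(area_ids, years)
  if (is.null(covariates)) {
    covariates <- array(0, dim = c(N, T, 0))
    covariate_names <- character(0)
  } else {
    covariates <- as.array(covariates)
    if (length(dim(covariates)) != 3 || !all(dim(covariates)[1:2] == c(N, T)))
      stop("covariates must be an N x T x P array")
    if (any(!is.finite(covariates)))
      stop("covariates contain non-finite values")
    P <- dim(covariates)[3]
    if (is.null(covariate_names)) covariate_names <- paste0("x", seq_len(P))
    if (length(covariate_names) != P)
      stop("covariate_names must have length P = ", P)
    dimnames(covariates) <- list(area_ids, years, covariate_names)
  }
  structure(list(area_ids = area_ids, years = years, counts = counts,
                 covariates = covariates,
                 covariate_names = as.character(covariate_names),
                 centered = centered, offsets = offsets),
            class = "area_panel")
}

#' @export
print.area_panel <- function(x, ...) {
  cat("area_panel:", length(x$area_ids), "areas x", length(x$years),
      "years,", length(x$covariate_names), "covariates",
      if (x$centered) "(centred)" else "", "\n")
  cat("  years:", min(x$years), "-", max(x$years),
      " total count:", sum(x$counts), "\n")
  invisible(x)
}

#' Read an areal count panel from a delimited text file
#'
#' Expects one row per (area, year) combination.  The panel must be complete:
#' every area must have a row for every year.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param area_col,year_col,count_col Column names for the area identifier,
#'   year, and count.
#' @param covariate_cols Character vector of covariate column names; default
#'   `NULL` takes every remaining column.
#' @param exclude_areas Optional character vector of area ids to drop before
#'   validation (e.g. islands or areas with unusable covariate data).
#' @param sep Field separator (`","` or `"\t"`).
#' @return A validated [area_panel].
#' @export
read_panel <- function(path, area_col = "area_id", year_col = "year",
                       count_col = "count", covariate_cols = NULL,
                       exclude_areas = NULL, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  for (col in c(area_col, year_col, count_col))
    if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
  n_raw <- nrow(df)
  if (!is.null(exclude_areas)) df <- df[!df[[area_col]] %in% exclude_areas, ]
  message("read_panel: ", n_raw, " rows read, ", n_raw - nrow(df),
          " excluded")
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(df), c(area_col, year_col, count_col))
  area_ids <- sort(unique(as.character(df[[area_col]])))
  years <- sort(unique(as.integer(df[[year_col]])))
  N <- length(area_ids); T <- length(years); P <- length(covariate_cols)
  key <- paste(df[[area_col]], df[[year_col]])
  if (anyDuplicated(key))
    stop("duplicate (area, year) rows: ", key[duplicated(key)][1])
  want <- expand.grid(area = area_ids, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  miss <- !paste(want$area, want$year) %in% key
  if (any(miss)) {
    m <- want[which(miss)[1], ]
    stop("incomplete panel: missing cell for area '", m$area, "', year ",
         m$year)
  }
  idx <- match(paste(want$area, want$year), key)  # (area fastest, then year)
  cnt <- df[[count_col]][idx]
  if (any(is.na(cnt) | cnt < 0 | cnt != round(cnt)))
    stop("counts must be non-negative integers")
  counts <- matrix(as.integer(cnt), N, T)
  covs <- array(NA_real_, dim = c(N, T, P))
  for (p in seq_len(P))
    covs[, , p] <- as.numeric(df[[covariate_cols[p]]][idx])
  area_panel(area_ids, years, counts,
             covariates = if (P > 0) covs else NULL,
             covariate_names = covariate_cols)
}

#' Write an areal count panel to CSV
#'
#' Inverse of [read_panel]: emits one row per (area, year) with the count
#' and covariate columns, so `read_panel(write_panel(p, f))` recovers `p`.
#'
#' @param panel An [area_panel].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  N <- length(panel$area_ids); T <- length(panel$years)
  df <- data.frame(
    area_id = rep(panel$area_ids, times = T),
    year = rep(panel$years, each = N),
    count = as.vector(panel$counts),
    stringsAsFactors = FALSE)
  for (p in seq_along(panel$covariate_names))
    df[[panel$covariate_names[p]]] <- as.vector(panel$covariates[, , p])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# internal: build a validated adjacency_graph from an integer edge matrix
adjacency_from_edges <- function(edges, area_ids) {
  N <- length(area_ids)
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  nb <- lapply(seq_len(N), function(i)
    sort(as.integer(igraph::neighbors(g, i))))
  comp <- igraph::components(g)
  n_i <- vapply(nb, length, integer(1))
  iso <- which(n_i == 0)
  if (length(iso) > 0)
    message("adjacency: ", length(iso), " isolated area(s): ",
            paste(area_ids[iso], collapse = ", "))
  structure(list(area_ids = as.character(area_ids), nb = nb,
                 n = setNames(n_i, area_ids),
                 components = as.integer(comp$membership),
                 n_components = as.integer(comp$no)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("adjacency_graph:", length(x$area_ids), "areas,",
      sum(x$n) / 2, "edges,", x$n_components, "component(s)\n")
  invisible(x)
}

#' Read an areal adjacency structure from a neighbour-pair list
#'
#' Each data row names one unordered pair of adjacent areas.  The graph is
#' symmetric by construction; duplicate pairs (in either order) are dropped
#' with a warning, self-pairs are an error.
#'
#' @param path CSV file whose first two columns are area-id pairs.
#' @param area_ids Character vector of the panel's area identifiers; the
#'   graph is built over exactly these, and pairs naming unknown areas are
#'   an error.
#' @return An `adjacency_graph` with neighbour sets, neighbour counts `n`,
#'   and connected-component labels.
#' @export
read_adjacency <- function(path, area_ids) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("adjacency file needs two columns of area ids")
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  unknown <- setdiff(c(a, b), area_ids)
  if (length(unknown) > 0)
    stop("adjacency references unknown area id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  if (any(a == b)) stop("self-pair in adjacency: ", a[a == b][1])
  i <- match(a, area_ids); j <- match(b, area_ids)
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    warning("duplicate adjacency pair(s) deduplicated (",
            sum(duplicated(key)), ")")
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]
  }
  message("read_adjacency: ", length(i), " unique pairs over ",
          length(area_ids), " areas")
  adjacency_from_edges(cbind(i, j), area_ids)
}

#' Derive rook-style adjacency from polygon boundaries (GeoJSON)
#'
#' Two areas are neighbours when their boundaries share at least one whole
#' edge segment (rook contiguity): areas touching only at a single point are
#' not neighbours.  Coordinates are rounded to `digits` decimal places
#' before matching, so boundaries must be topologically consistent (shared
#' borders traced with the same vertices in both polygons), as is standard
#' for administrative boundary files.
#'
#' @param path Path to a GeoJSON FeatureCollection of Polygon/MultiPolygon
#'   features.
#' @param id_property Name of the feature property holding the area id.
#' @param digits Decimal places used when matching boundary vertices.
#' @return An `adjacency_graph` over the file's areas.
#' @export
adjacency_from_polygons <- function(path, id_property = "area_id",
                                    digits = 7) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  ids <- vapply(feats, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature missing property '", id_property, "'")
    as.character(id)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate area ids in polygon file")
  ring_edges <- function(ring) {
    pts <- vapply(ring, function(pt)
      paste(round(as.numeric(pt[[1]]), digits),
            round(as.numeric(pt[[2]]), digits)), character(1))
    n <- length(pts)
    if (n < 2) return(character(0))
    a <- pts[-n]; b <- pts[-1]
    paste(pmin(a, b), pmax(a, b), sep = "|")
  }
  edge_sets <- lapply(feats, function(f) {
    geom <- f$geometry
    if (is.null(geom) || !geom$type %in% c("Polygon", "MultiPolygon"))
      stop("unsupported or missing geometry (need Polygon/MultiPolygon)")
    rings <- if (geom$type == "Polygon") geom$coordinates
             else do.call(c, geom$coordinates)
    unique(unlist(lapply(rings, ring_edges)))
  })
  N <- length(ids)
  owner <- data.frame(edge = unlist(edge_sets),
                      area = rep.int(seq_len(N),
                                     vapply(edge_sets, length, integer(1))))
  shared <- split(owner$area, owner$edge)
  shared <- shared[vapply(shared, length, integer(1)) > 1]
  pairs <- unique(do.call(rbind, lapply(shared, function(s) {
    s <- sort(unique(s))
    if (length(s) < 2) return(NULL)
    t(combn(s, 2))
  })))
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  message("adjacency_from_polygons: ", N, " areas, ", nrow(pairs),
          " shared-border pairs")
  adjacency_from_edges(pairs, ids)
}

#' Centre the covariate columns of a panel
#'
#' Subtracts from each covariate its grand mean over all N x T cells, so
#' the fitted intercept is interpretable at covariate means and the MCMC
#' mixes better.  Offsets are retained on the returned panel.
#'
#' @param panel An [area_panel].
#' @return The panel with centred covariates and `offsets` recorded.
#' @export
center_covariates <- function(panel) {
  P <- length(panel$covariate_names)
  if (P == 0 || panel$centered) return(panel)
  offsets <- numeric(P)
  for (p in seq_len(P)) {
    col <- panel$covariates[, , p]
    offsets[p] <- mean(col)
    panel$covariates[, , p] <- col - offsets[p]
    if (stats::var(as.vector(col)) == 0)
      warning("covariate '", panel$covariate_names[p],
              "' is constant (zero variance after centering)")
  }
  panel$offsets <- setNames(offsets, panel$covariate_names)
  panel$centered <- TRUE
  panel
}

#' Descriptive statistics of per-area total counts
#'
#' Sums counts over years within each area and summarises the totals with
#' the mean, sample standard deviation (denominator N - 1), minimum and
#' maximum.
#'
#' @param panel An [area_panel].
#' @return A list with `totals` (named per-area sums), `mean`, `sd` (`NA`
#'   for a single area), `min`, `max`, `n_areas`, `n_years`.
#' @export
panel_descriptives <- function(panel) {
  totals <- rowSums(panel$counts)
  list(totals = totals,
       mean = mean(totals),
       sd = if (length(totals) > 1) sd(totals) else NA_real_,
       min = min(totals), max = max(totals),
       n_areas = length(panel$area_ids), n_years = length(panel$years))
}
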