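test_that("panel round-trips through write_panel/read_panel", {
  set.seed(31)
  covs <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  p <- area_panel(c("X", "Y", "Z"), 2011:2014,
                  matrix(rpois(12, 8), 3, 4),
                  covariates = covs, covariate_names = c("dep", "road"))
  f <- tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- suppressMessages(read_panel(f))
  expect_identical(p2$area_ids, p$area_ids)
  expect_identical(p2$years, p$years)
  expect_identical(unname(p2$counts), unname(p$counts))
  expect_equal(unname(p2$covariates), unname(p$covariates))
  expect_identical(p2$covariate_names, p$covariate_names)
})

test_that("panel validation rejects incomplete or malformed tables", {
  df <- data.frame(area_id = c("A", "A", "B"), year = c(1, 2, 1),
                   count = c(1, 2, 3))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(suppressMessages(read_panel(f)),
               "missing cell for area 'B', year 2")
  df$year <- c(1, 2, 3)  # still incomplete, different hole
  write.csv(df, f, row.names = FALSE)
  expect_error(suppressMessages(read_panel(f)), "incomplete panel")
  expect_error(area_panel("A", 1, matrix(-1)), "non-negative")
  expect_error(area_panel("A", 1, matrix(1.5)), "non-negative integers")
  expect_error(area_panel(c("A", "A"), 1, matrix(1:2)), "unique")
  expect_error(area_panel(c("A", "B"), c(1, 3), matrix(1:4, 2)),
               "consecutive")
  expect_error(
    area_panel("A", 1:2, matrix(1:2, 1),
               covariates = array(c(1, NaN), c(1, 2, 1))),
    "non-finite")
})

test_that("read_panel reads counts back in (area, year) order", {
  df <- expand.grid(area_id = c("B", "A"), year = 2:1)
  df$count <- c(4, 2, 3, 1)  # (B,2)=4 (A,2)=2 (B,1)=3 (A,1)=1
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  p <- suppressMessages(read_panel(f))
  expect_identical(unname(p$counts), matrix(c(1L, 3L, 2L, 4L), 2, 2))
  expect_identical(p$area_ids, c("A", "B"))
})

test_that("read_adjacency builds symmetric graphs and handles duplicates", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(from = c("A", "B"), to = c("B", "C")), f,
            row.names = FALSE)
  g <- suppressMessages(read_adjacency(f, c("A", "B", "C")))
  expect_identical(unname(g$n), c(1L, 2L, 1L))
  expect_identical(g$nb[[2]], c(1L, 3L))
  # duplicate pair in reversed order collapses to one undirected edge
  write.csv(data.frame(from = c("A", "B"), to = c("B", "A")), f,
            row.names = FALSE)
  expect_warning(g2 <- suppressMessages(read_adjacency(f, c("A", "B"))),
                 "deduplicated")
  expect_identical(unname(g2$n), c(1L, 1L))
  write.csv(data.frame(from = "A", to = "Q"), f, row.names = FALSE)
  expect_error(suppressMessages(read_adjacency(f, c("A", "B"))),
               "unknown area id")
  write.csv(data.frame(from = "A", to = "A"), f, row.names = FALSE)
  expect_error(suppressMessages(read_adjacency(f, c("A", "B"))),
               "self-pair")
})

test_that("2x2 rook grid from a pair list gives every area two neighbours", {
  f <- tempfile(fileext = ".csv")
  # cells 1 2 / 3 4: rook pairs enumerated by hand
  write.csv(data.frame(from = c("c1", "c1", "c2", "c3"),
                       to = c("c2", "c3", "c4", "c4")), f,
            row.names = FALSE)
  g <- suppressMessages(read_adjacency(f, paste0("c", 1:4)))
  expect_identical(unname(g$n), rep(2L, 4))
  expect_identical(g$n_components, 1L)
})

test_that("adjacency symmetry and neighbour counts hold for constructed graphs", {
  for (dims in list(c(2, 3), c(4, 4), c(1, 5))) {
    g <- make_lattice_graph(dims[1], dims[2])
    for (i in seq_along(g$nb)) {
      expect_equal(length(g$nb[[i]]), unname(g$n[i]))
      expect_false(i %in% g$nb[[i]])
      for (j in g$nb[[i]]) expect_true(i %in% g$nb[[j]])
    }
  }
})

test_that("polygon adjacency uses shared edges, not shared corners", {
  # two unit squares sharing a full edge
  f <- write_squares_geojson(rbind(c(0, 0), c(1, 0)), c("L", "R"))
  g <- suppressMessages(adjacency_from_polygons(f))
  expect_identical(unname(g$n), c(1L, 1L))
  # squares meeting only at a corner are not neighbours
  f2 <- write_squares_geojson(rbind(c(0, 0), c(1, 1)), c("SW", "NE"))
  g2 <- suppressMessages(adjacency_from_polygons(f2))
  expect_identical(unname(g2$n), c(0L, 0L))
})

test_that("3x3 grid of unit squares: corners get 2 neighbours, centre 4", {
  corners <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  ids <- sprintf("s%d%d", corners[, 1], corners[, 2])
  f <- write_squares_geojson(corners, ids)
  g <- suppressMessages(adjacency_from_polygons(f))
  deg <- unname(g$n)
  expect_identical(sort(deg), c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L))
  expect_identical(unname(g$n["s11"]), 4L)      # centre
  expect_identical(unname(g$n["s00"]), 2L)      # a corner
})

test_that("center_covariates removes grand means and keeps offsets", {
  covs <- array(c(1, 2, 3, 10, 10, 40), c(3, 1, 2))
  p <- area_panel(c("A", "B", "C"), 1, matrix(0L, 3, 1),
                  covariates = covs, covariate_names = c("u", "v"),
                  centered = FALSE)
  pc <- center_covariates(p)
  expect_equal(as.vector(pc$covariates[, , 1]), c(-1, 0, 1))
  expect_equal(unname(pc$offsets), c(2, 20))
  expect_equal(sum(pc$covariates[, , 2]), 0)
  # already-centred column: unchanged, offset 0
  p2 <- area_panel(c("A", "B", "C"), 1, matrix(0L, 3, 1),
                   covariates = array(c(-1, 0, 1), c(3, 1, 1)),
                   covariate_names = "w")
  pc2 <- center_covariates(p2)
  expect_equal(as.vector(pc2$covariates), c(-1, 0, 1))
  expect_equal(unname(pc2$offsets), 0)
  # constant column warns
  p3 <- area_panel(c("A", "B"), 1, matrix(0L, 2, 1),
                   covariates = array(5, c(2, 1, 1)))
  expect_warning(center_covariates(p3), "constant")
})

test_that("centering leaves every covariate with |mean| < 1e-10", {
  set.seed(99)
  for (rep in 1:3) {
    covs <- array(rnorm(5 * 3 * 4, mean = rnorm(1, 0, 50)), c(5, 3, 4))
    p <- area_panel(paste0("a", 1:5), 1:3, matrix(0L, 5, 3),
                    covariates = covs)
    pc <- center_covariates(p)
    for (k in 1:4) expect_lt(abs(mean(pc$covariates[, , k])), 1e-10)
  }
})

test_that("panel_descriptives summarises per-area totals", {
  p <- toy_panel(matrix(c(1L, 3L, 1L, 3L), 2, 2))
  d <- panel_descriptives(p)
  expect_equal(unname(d$totals), c(2, 6))
  expect_equal(d$mean, 4)
  expect_equal(d$sd, sd(c(2, 6)))  # sample sd, denominator N - 1
  expect_equal(c(d$min, d$max), c(2, 6))
  # single area: sd undefined
  d1 <- panel_descriptives(toy_panel(matrix(c(1L, 2L), 1, 2)))
  expect_true(is.na(d1$sd))
})
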