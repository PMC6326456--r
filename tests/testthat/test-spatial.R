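ev_tbl <- function(lon, lat, month, deaths) {
  tibble::tibble(lon = lon, lat = lat, month = month, deaths = deaths)
}

test_that("intensity mass is conserved within 1%", {
  spec <- grid_spec(0, 4, 0, 4, cell_deg = 0.1)
  # single event well inside the box
  g <- estimate_intensity(ev_tbl(2, 2, 99, 40), ref_month = 100,
                          window_months = 12, spec = spec)
  expect_lt(abs(sum(g$values) - 40) / 40, 0.01)
  # random event sets
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(1:12, 1)
    ev <- ev_tbl(runif(k, 0.5, 3.5), runif(k, 0.5, 3.5),
                 sample(88:99, k, replace = TRUE),
                 sample(1:100, k, replace = TRUE))
    g <- estimate_intensity(ev, 100, 12, spec)
    tot <- sum(ev$deaths)
    expect_lte(abs(sum(g$values) - tot) / max(1, tot), 0.01)
  }
})

test_that("intensity surface is symmetric for mirror-symmetric events", {
  spec <- grid_spec(0, 4, 0, 4, cell_deg = 0.2)
  g <- estimate_intensity(ev_tbl(c(1, 3), c(2, 2), c(99, 99), c(10, 10)),
                          100, 12, spec)
  flipped <- g$values[nrow(g$values):1, ]
  expect_equal(g$values, flipped, tolerance = 1e-9)
})

test_that("events outside the window are excluded; empty window is zero", {
  spec <- grid_spec(0, 1, 0, 1, cell_deg = 1)
  # 13 months before the reference month: outside [ref-12, ref-1]
  g <- estimate_intensity(ev_tbl(0.5, 0.5, 100 - 13, 30), 100, 12, spec)
  expect_equal(sum(g$values), 0)
  # 1 month before: inside; degenerate one-cell grid conserves the deaths
  g <- estimate_intensity(ev_tbl(0.5, 0.5, 99, 30), 100, 12, spec)
  expect_equal(lookup_intensity(g, 0.5, 0.5), 30, tolerance = 0.3)
})

test_that("adding an event never decreases any cell value", {
  spec <- grid_spec(0, 4, 0, 4, cell_deg = 0.25)
  set.seed(22)
  for (rep in 1:10) {
    k <- sample(1:6, 1)
    ev <- ev_tbl(runif(k, 0, 4), runif(k, 0, 4), 99, sample(1:50, k, TRUE))
    extra <- dplyr::bind_rows(ev, ev_tbl(runif(1, 0, 4), runif(1, 0, 4),
                                         99, sample(1:50, 1)))
    g1 <- estimate_intensity(ev, 100, 12, spec)
    g2 <- estimate_intensity(extra, 100, 12, spec)
    expect_true(all(g2$values - g1$values >= -1e-9))
  }
})

test_that("intensity is equivariant under joint translation", {
  set.seed(23)
  ev <- ev_tbl(runif(5, 1, 3), runif(5, 1, 3), 99, sample(1:40, 5))
  g1 <- estimate_intensity(ev, 100, 12, grid_spec(0, 4, 0, 4, 0.2),
                           proj_lat = 9)
  shifted <- ev
  shifted$lon <- shifted$lon + 1.4
  shifted$lat <- shifted$lat - 0.6
  g2 <- estimate_intensity(shifted, 100, 12,
                           grid_spec(1.4, 5.4, -0.6, 3.4, 0.2),
                           proj_lat = 9)
  expect_equal(g1$values, g2$values, tolerance = 1e-9)
})

test_that("cell lookup uses half-open cells and rejects outside points", {
  spec <- grid_spec(0, 1, 0, 1, cell_deg = 0.5)
  g <- estimate_intensity(ev_tbl(numeric(), numeric(), integer(),
                                 numeric()), 100, 12, spec)
  g$values[] <- matrix(1:4, 2, 2)
  expect_equal(lookup_intensity(g, 0.25, 0.25), 1)
  # interior boundary point belongs to the east/north cell
  expect_equal(lookup_intensity(g, 0.5, 0.25), 2)
  expect_equal(lookup_intensity(g, 0.25, 0.5), 3)
  expect_error(lookup_intensity(g, 1.2, 0.5), "outside")
})

test_that("per-child exposure follows the 12-completed-months window", {
  child <- tibble::tibble(interview_month = 100L, lon = 0.5, lat = 0.5)
  spec <- grid_spec(0, 1, 0, 1, cell_deg = 1)
  expect_equal(assign_child_intensity(child, ev_tbl(0.5, 0.5, 87, 30),
                                      12, spec), 0)
  got <- assign_child_intensity(child, ev_tbl(0.5, 0.5, 99, 30), 12, spec)
  expect_equal(got, 30, tolerance = 0.3)
})

test_that("window extremum honours mode and missing months", {
  s <- tibble::tibble(month = c(97, 98, 99), value = c(1, 5, 3))
  expect_equal(window_extremum(s, 100, 12, "max"), 5)
  expect_equal(window_extremum(s, 100, 12, "min"), 1)
  one <- tibble::tibble(month = 99, value = 4.2)
  expect_equal(window_extremum(one, 100, 12, "max"), 4.2)
  expect_equal(window_extremum(one, 100, 12, "min"), 4.2)
  s$value[2] <- NA
  expect_equal(window_extremum(s, 100, 12, "max"), 3)
  expect_error(window_extremum(s, 300, 12, "max"), "window")
})

cluster_tbl <- function(lon, lat, round) {
  tibble::tibble(cluster_id = sprintf("C%02d", seq_along(lon)),
                 survey_round = round, lon = lon, lat = lat)
}

test_that("two clusters, one per round, give a single area", {
  cl <- cluster_tbl(c(1, 2), c(1, 1), c(2008L, 2013L))
  p <- build_partition(cl, region = c(0, 3, 0, 2))
  expect_equal(nrow(p$areas), 1)
  expect_setequal(p$areas$cluster_ids[[1]], cl$cluster_id)
})

test_that("well-separated round pairs split into separate areas", {
  cl <- cluster_tbl(c(1, 1.2, 9, 9.2), c(1, 1.2, 9, 9.2),
                    c(2008L, 2013L, 2008L, 2013L))
  p <- build_partition(cl, region = c(0, 10, 0, 10))
  expect_equal(nrow(p$areas), 2)
  expect_true(all(p$areas$n_round1 >= 1 & p$areas$n_round2 >= 1))
})

test_that("single-round inputs are infeasible", {
  cl <- cluster_tbl(runif(5, 0, 1), runif(5, 0, 1), rep(2008L, 5))
  expect_error(build_partition(cl), "single survey round")
})

test_that("every area contains both rounds on random instances and the
           area count matches exhaustive search on small ones", {
  set.seed(24)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    rounds <- c(2008L, 2013L,
                sample(c(2008L, 2013L), n - 2, replace = TRUE))
    cl <- cluster_tbl(runif(n, 0, 10), runif(n, 0, 10), rounds)
    p <- build_partition(cl, region = c(-1, 11, -1, 11))
    # feasibility invariant
    expect_true(all(p$areas$n_round1 >= 1 & p$areas$n_round2 >= 1))
    expect_equal(sort(unlist(p$areas$cluster_ids)), sort(cl$cluster_id))
    # optimality against the brute-force oracle
    vor <- nutricate:::voronoi_cells(cl$lon, cl$lat,
                                     matrix(c(-1, -1, 11, -1, 11, 11,
                                              -1, 11),
                                            ncol = 2, byrow = TRUE))
    feas <- function(m) {
      any(cl$survey_round[m] == 2008) && any(cl$survey_round[m] == 2013)
    }
    expect_equal(nrow(p$areas),
                 oracle_partition_count(vor$neighbors, feas, n))
  }
})

test_that("greedy merging on larger instances stays feasible", {
  set.seed(25)
  n <- 40
  cl <- cluster_tbl(runif(n, 0, 10), runif(n, 0, 10),
                    sample(c(2008L, 2013L), n, replace = TRUE))
  p <- build_partition(cl, region = c(-1, 11, -1, 11))
  expect_true(all(p$areas$n_round1 >= 1 & p$areas$n_round2 >= 1))
  expect_gte(nrow(p$areas), 1)
  expect_lte(nrow(p$areas), n)
})

test_that("partition exports valid GeoJSON", {
  cl <- cluster_tbl(c(1, 2, 5, 6), c(1, 2, 5, 6),
                    c(2008L, 2013L, 2008L, 2013L))
  p <- build_partition(cl, region = c(0, 7, 0, 7))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_partition_geojson(p, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(p$areas))
  expect_equal(gj$features[[1]]$geometry$type, "MultiPolygon")
})
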