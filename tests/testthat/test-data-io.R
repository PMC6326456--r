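make_children_tbl <- function(n = 3) {
  tibble::tibble(
    child_id = sprintf("K%03d", seq_len(n)),
    cluster_id = "C1",
    survey_round = 2008L,
    interview_month = month_index(2008, 7),
    age_months = as.integer(seq(2, 50, length.out = n)),
    sex = rep_len(c("male", "female"), n),
    weight_kg = seq(5, 14, length.out = n),
    height_cm = seq(55, 100, length.out = n),
    relation_to_head = "child", breastfed = "yes",
    mother_age_years = 25L, religion = "muslim",
    native_language = "hausa", mother_education_years = 6L,
    urban = TRUE, iwi = 43.21, electricity = FALSE,
    sanitation_access = TRUE, region = "north_east",
    lon = 8.1, lat = 10.5
  )
}

test_that("child records round-trip through CSV", {
  tb <- make_children_tbl(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_children(tb, path)
  back <- read_children(path)
  expect_equal(nrow(back), 5)
  expect_equal(nrow(attr(back, "rejected")), 0)
  for (col in names(child_schema())) {
    if (is.double(tb[[col]])) {
      expect_equal(back[[col]], tb[[col]], tolerance = 1e-9)
    } else {
      expect_identical(back[[col]], tb[[col]])
    }
  }
})

test_that("rows violating hard invariants are rejected with reasons", {
  tb <- make_children_tbl(4)
  tb$height_cm[2] <- -5
  tb$age_months[3] <- 70L
  path <- withr::local_tempfile(fileext = ".csv")
  write_children(tb, path)
  back <- read_children(path)
  rej <- attr(back, "rejected")
  expect_equal(nrow(back) + nrow(rej), attr(back, "n_input"))
  expect_equal(rej$row, c(2L, 3L))
  expect_match(rej$reason[1], "non-positive height")
  expect_match(rej$reason[2], "age_months")
})

test_that("column order does not affect parsing", {
  tb <- make_children_tbl(3)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_children(tb, p1)
  shuffled <- tb[, rev(names(tb))]
  readr::write_csv(shuffled, p2, na = "NA", progress = FALSE)
  a <- read_children(p1)
  b <- read_children(p2)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("missing files, columns and empty files error", {
  expect_error(read_children("no-such-file.csv"), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("child_id,age_months", path)
  expect_error(read_children(path), "missing column")
  file.create(empty <- withr::local_tempfile(fileext = ".csv"))
  expect_error(read_children(empty), "empty")
})

test_that("conflict events are read from CSV with validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lon,lat,month,deaths",
               "8.5,11.2,24100,40",
               "9.1,95,24101,10",
               "7.7,10.0,24102,3"), path)
  ev <- read_events(path)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$deaths, c(40, 3))
  rej <- attr(ev, "rejected")
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "lat")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("lon,lat,month,deaths", empty)
  expect_equal(nrow(read_events(empty)), 0)
})

test_that("conflict events are read from GeoJSON", {
  path <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = list(8.5, 11.2)),
         properties = list(month = 24100, deaths = 40)),
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = list(7.0, 9.9)),
         properties = list(month = 24101, deaths = 5))
  ))
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  ev <- read_events(path)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$deaths, c(40, 5))
  expect_equal(ev$month, c(24100L, 24101L))
})

test_that("dataset validation reports duplicates and missingness", {
  tb <- make_children_tbl(10)
  rep1 <- validate_dataset(tb)
  expect_true(rep1$passed)
  expect_equal(sum(rep1$missingness$n_missing), 0)

  tb$child_id[2] <- tb$child_id[1]
  tb$weight_kg[1] <- NA
  rep2 <- validate_dataset(tb)
  expect_false(rep2$passed)
  expect_equal(rep2$n_duplicate_ids, 1)
  miss <- rep2$missingness$n_missing[rep2$missingness$field == "weight_kg"]
  expect_equal(miss, 1L)
})

test_that("injected missingness is counted exactly", {
  tb <- make_children_tbl(50)
  idx <- seq(1, 50, by = 10)
  tb$weight_kg[idx] <- NA
  rep <- validate_dataset(tb)
  miss <- rep$missingness$n_missing[rep$missingness$field == "weight_kg"]
  expect_equal(miss, length(idx))
})

test_that("study config round-trips through JSON", {
  cfg <- study_config(seed = 7, n_boot = 25,
                      bart = bart_config(num_trees = 10, burn_in = 5,
                                         num_draws = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$seed, 7L)
  expect_equal(back$n_boot, 25L)
  expect_equal(back$bart$num_trees, 10L)
  expect_equal(back$schema_version, cfg$schema_version)
})
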