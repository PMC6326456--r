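test_that("LMS z-score matches hand-evaluated cases", {
  expect_equal(lms_zscore(10, L = 0.7, M = 10, S = 0.1), 0)
  expect_equal(lms_zscore(8, L = 1, M = 10, S = 0.1), -2)
  expect_equal(lms_zscore(10 * exp(0.1), L = 0, M = 10, S = 0.1), 1)
  expect_error(lms_zscore(-1, 1, 10, 0.1), "positive")
  expect_error(lms_zscore(5, 1, -10, 0.1), "positive")
})

test_that("LMS z-score is strictly increasing in the measurement", {
  set.seed(11)
  for (rep in 1:200) {
    L <- runif(1, -1.5, 1.5)
    M <- runif(1, 3, 100)
    S <- runif(1, 0.08, 0.15)
    x <- sort(runif(2, 0.4 * M, 2.5 * M))
    expect_lt(lms_zscore(x[1], L, M, S), lms_zscore(x[2], L, M, S))
  }
})

test_that("inverse LMS round-trips to 1e-9 over the valid domain", {
  set.seed(12)
  expect_equal(invert_lms(0, L = -0.4, M = 7.3, S = 0.12), 7.3)
  expect_equal(invert_lms(-2, L = 1, M = 10, S = 0.1), 8)
  for (rep in 1:1000) {
    L <- runif(1, -1.5, 1.5)
    M <- runif(1, 3, 100)
    S <- runif(1, 0.08, 0.15)
    z <- runif(1, -4, 4)
    if (L != 0 && 1 + L * S * z <= 0) next
    x <- invert_lms(z, L, M, S)
    expect_equal(lms_zscore(x, L, M, S), z, tolerance = 1e-9)
  }
  expect_error(invert_lms(-20, L = 1, M = 10, S = 0.1), "domain")
})

test_that("severe-undernutrition classification matches the any() oracle", {
  # boundary: strictly below -3
  expect_false(classify_severe_undernutrition(-2.99, -2.99, -2.99))
  expect_true(classify_severe_undernutrition(-3.01, 0, 0))
  expect_true(is.na(classify_severe_undernutrition(NA, NA, NA)))
  # exhaustive sign patterns at z in {-4, 0}
  grid <- expand.grid(wa = c(-4, 0), ha = c(-4, 0), wh = c(-4, 0))
  got <- classify_severe_undernutrition(grid$wa, grid$ha, grid$wh)
  expect_equal(got, oracle_severe(grid$wa, grid$ha, grid$wh))
  # 1,000 random triples with missing patterns
  set.seed(13)
  z <- matrix(runif(3000, -6, 2), ncol = 3)
  z[runif(3000) < 0.2] <- NA
  got <- classify_severe_undernutrition(z[, 1], z[, 2], z[, 3])
  expect_equal(got, oracle_severe(z[, 1], z[, 2], z[, 3]))
})

test_that("sanitation deprivation inverts toilet access", {
  expect_true(classify_sanitation_deprivation(FALSE))
  expect_false(classify_sanitation_deprivation(TRUE))
  x <- c(TRUE, FALSE, TRUE)
  expect_identical(classify_sanitation_deprivation(x),
                   classify_sanitation_deprivation(x))
})

make_flat_reference <- function() {
  # two-point reference blocks with easily interpolable parameters
  dplyr::bind_rows(lapply(c("male", "female"), function(sx) {
    dplyr::bind_rows(
      tibble::tibble(sex = sx, indicator = "weight_for_age",
                     index_value = c(0, 59), L = 1, M = c(4, 16), S = 0.1),
      tibble::tibble(sex = sx, indicator = "height_for_age",
                     index_value = c(0, 59), L = 1, M = c(50, 100),
                     S = 0.08),
      tibble::tibble(sex = sx, indicator = "weight_for_height",
                     index_value = c(45, 120), L = 1, M = c(3, 22),
                     S = 0.12)
    )
  }))
}

test_that("reference interpolation is linear with exact tabulated hits", {
  ref <- make_flat_reference()
  hit <- interpolate_reference(ref, "male", "weight_for_age", 0)
  expect_equal(hit$M, 4)
  mid <- interpolate_reference(ref, "male", "weight_for_age", 29.5)
  expect_equal(mid$M, 10)  # midpoint of 4 and 16
  oob <- interpolate_reference(ref, "male", "weight_for_age", -1)
  expect_true(is.na(oob$M))
})

test_that("indicator computation classifies and flags correctly", {
  ref <- make_flat_reference()
  base <- tibble::tibble(
    child_id = "a", age_months = 29.5, sex = "male",
    weight_kg = 10, height_cm = 75
  )
  # at the medians everywhere: M_wa(29.5)=10, M_ha(29.5)=75, M_wh(75)=10.6
  res <- compute_indicators(base, ref)
  expect_equal(res$z_wa, 0)
  expect_equal(res$z_ha, 0)
  expect_false(res$severe_undernutrition)

  # z_wa = -3.5, others moderate -> severe by the any-indicator rule
  low <- base
  low$weight_kg <- invert_lms(-3.5, 1, 10, 0.1)
  res <- compute_indicators(low, ref)
  expect_equal(res$z_wa, -3.5, tolerance = 1e-9)
  expect_true(res$severe_undernutrition)

  # implausible z_wa = -7 is flagged and excluded; remaining say healthy
  # (weight-for-height given a wide-S block so its z stays mild)
  impl <- base
  impl$weight_kg <- invert_lms(-7, 1, 10, 0.1)
  ref_wide <- ref
  ref_wide$S[ref_wide$indicator == "weight_for_height"] <- 2
  res <- compute_indicators(impl, ref_wide)
  expect_true(is.na(res$z_wa))
  expect_match(res$anthro_flags, "implausible")
  expect_false(res$severe_undernutrition)

  # all three indicators missing -> unclassifiable
  blank <- base
  blank$weight_kg <- NA_real_
  blank$height_cm <- NA_real_
  res <- compute_indicators(blank, ref)
  expect_true(is.na(res$severe_undernutrition))
  expect_match(res$anthro_flags, "unclassifiable")
})
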