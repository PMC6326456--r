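#' LMS z-score
#'
#' Converts a measured value to a z-score against an LMS growth reference
#' (Box-Cox power `L`, median `M`, coefficient of variation `S`), the
#' parameterization used by the WHO Child Growth Standards:
#' \deqn{z = \frac{(x/M)^L - 1}{L S} \quad (L \ne 0), \qquad
#'       z = \frac{\log(x/M)}{S} \quad (L = 0).}
#'
#' @param x Measured value(s), strictly positive.
#' @param L Box-Cox power.
#' @param M Reference median, strictly positive.
#' @param S Coefficient of variation, strictly positive.
#' @return Numeric z-score(s). `NA` inputs propagate to `NA`.
#' @seealso [invert_lms()] for the inverse transform.
#' @examples
#' lms_zscore(8, L = 1, M = 10, S = 0.1)   # -2
#' lms_zscore(10, L = -1.2, M = 10, S = 0.1)  # 0: the median maps to zero
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0, na.rm = TRUE)) abort_nutricate("`x` must be positive")
  if (any(M <= 0, na.rm = TRUE) || any(S <= 0, na.rm = TRUE)) {
    abort_nutricate("`M` and `S` must be positive")
  }
  ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Inverse LMS transform
#'
#' Recovers the measured value corresponding to a target z-score under an
#' LMS reference: `x = M (1 + L S z)^{1/L}` for `L != 0` and
#' `x = M exp(S z)` for `L = 0`. Used by the synthetic-data generator to
#' realize anthropometry from a target z-score.
#'
#' @param z Target z-score(s).
#' @inheritParams lms_zscore
#' @return Measured value(s) `x` with `lms_zscore(x, L, M, S) == z`.
#' @export
invert_lms <- function(z, L, M, S) {
  if (any(M <= 0, na.rm = TRUE) || any(S <= 0, na.rm = TRUE)) {
    abort_nutricate("`M` and `S` must be positive")
  }
  base <- 1 + L * S * z
  if (any(L != 0 & base <= 0, na.rm = TRUE)) {
    abort_nutricate("inverse LMS domain violation: 1 + L*S*z must be positive")
  }
  ifelse(L == 0, M * exp(S * z), M * base^(1 / L))
}

#' Validate a growth-reference table
#'
#' A growth reference is a data frame with columns `sex`
#' (`"male"`/`"female"`), `indicator` (`"weight_for_age"`,
#' `"height_for_age"`, `"weight_for_height"`), `index_value` (age in months
#' or height in cm), and LMS parameters `L`, `M`, `S`. Within each
#' `(sex, indicator)` block `index_value` must be strictly increasing with
#' at least two rows, and `M`, `S` strictly positive.
#'
#' @param ref Growth-reference data frame.
#' @return `ref` invisibly, as a tibble; errors describe the first violation.
#' @export
validate_reference <- function(ref) {
  needed <- c("sex", "indicator", "index_value", "L", "M", "S")
  missing <- setdiff(needed, names(ref))
  if (length(missing) > 0) {
    abort_nutricate(paste0("reference lacks column(s): ",
                           paste(missing, collapse = ", ")))
  }
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    abort_nutricate("reference M and S must be strictly positive")
  }
  bad <- ref |>
    dplyr::group_by(.data$sex, .data$indicator) |>
    dplyr::summarise(
      n = dplyr::n(),
      increasing = all(diff(.data$index_value) > 0),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n < 2 | !.data$increasing)
  if (nrow(bad) > 0) {
    abort_nutricate(paste0(
      "reference block not usable (needs >= 2 rows, strictly increasing ",
      "index_value): ", bad$sex[1], "/", bad$indicator[1]
    ))
  }
  invisible(tibble::as_tibble(ref))
}

#' Interpolate LMS parameters from a growth reference
#'
#' Linear interpolation of `L`, `M`, `S` between the bracketing tabulated
#' rows; a query at a tabulated index returns that row exactly. Queries
#' outside the tabulated grid return `NA` for all three parameters (callers
#' flag the child and treat the indicator as missing).
#'
#' @param ref Growth-reference data frame (see [validate_reference()]).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param indicator One of `"weight_for_age"`, `"height_for_age"`,
#'   `"weight_for_height"` (vectorized).
#' @param index_value Age in months (first two indicators) or height in cm
#'   (weight-for-height), vectorized.
#' @return A tibble with columns `L`, `M`, `S` (NA when out of range).
#' @export
interpolate_reference <- function(ref, sex, indicator, index_value) {
  n <- max(length(sex), length(indicator), length(index_value))
  sex <- rep_len(sex, n); indicator <- rep_len(indicator, n)
  index_value <- rep_len(index_value, n)
  out <- tibble::tibble(L = rep(NA_real_, n), M = NA_real_, S = NA_real_)
  key <- paste(sex, indicator)
  for (k in unique(key[!is.na(sex) & !is.na(indicator)])) {
    idx <- which(key == k & !is.na(index_value))
    if (length(idx) == 0) next
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    block <- ref[ref$sex == parts[1] & ref$indicator == parts[2], ]
    if (nrow(block) < 2) next
    x <- index_value[idx]
    inside <- x >= min(block$index_value) & x <= max(block$index_value)
    if (!any(inside)) next
    xi <- x[inside]
    out$L[idx[inside]] <- stats::approx(block$index_value, block$L, xi)$y
    out$M[idx[inside]] <- stats::approx(block$index_value, block$M, xi)$y
    out$S[idx[inside]] <- stats::approx(block$index_value, block$S, xi)$y
  }
  out
}

#' Classify severe undernutrition (Bristol any-indicator rule)
#'
#' A child is severely undernourished when any of the three nutritional
#' z-scores falls strictly below -3 (more than 3 SD below the reference
#' median). Missing indicators are ignored; at least one must be present.
#'
#' @param z_wa,z_ha,z_wh Weight-for-age, height-for-age and
#'   weight-for-height z-scores (vectorized; `NA` = missing).
#' @return Logical vector; `NA` where all three indicators are missing.
#' @export
classify_severe_undernutrition <- function(z_wa, z_ha, z_wh) {
  z <- cbind(z_wa, z_ha, z_wh)
  any_below <- rowSums(z < -3, na.rm = TRUE) > 0
  all_missing <- rowSums(!is.na(z)) == 0
  ifelse(all_missing, NA, any_below)
}

#' Severe sanitation deprivation
#'
#' Bristol indicator: a child is severely sanitation-deprived when the
#' household has no access to a toilet of any kind.
#'
#' @param sanitation_access Logical: has any toilet access.
#' @return Logical: deprived.
#' @export
classify_sanitation_deprivation <- function(sanitation_access) {
  !sanitation_access
}

#' Compute nutritional indicators and the severe-undernutrition outcome
#'
#' For each child computes weight-for-age, height-for-age and
#' weight-for-height z-scores from an LMS growth reference, flags
#' biologically implausible values (|z| > 6, treated as missing for
#' classification) and out-of-range reference lookups, and applies the
#' Bristol any-indicator rule ([classify_severe_undernutrition()]).
#' Weight-for-height is indexed by height in cm; the two age-indexed
#' indicators by age in months.
#'
#' @param children Data frame with columns `age_months`, `sex`,
#'   `weight_kg`, `height_cm` (the measurements may be `NA`).
#' @param ref Growth-reference data frame (see [validate_reference()]).
#' @return The input tibble with added columns `z_wa`, `z_ha`, `z_wh`
#'   (post-flagging, `NA` where missing/implausible/out-of-range),
#'   `severe_undernutrition` (logical, `NA` when unclassifiable) and
#'   `anthro_flags` (comma-separated quality flags, `""` when clean).
#' @export
compute_indicators <- function(children, ref) {
  validate_reference(ref)
  stopifnot(all(c("age_months", "sex", "weight_kg", "height_cm")
                %in% names(children)))
  n <- nrow(children)
  one <- function(indicator, x, index_value) {
    lms <- interpolate_reference(ref, children$sex, indicator, index_value)
    z <- rep(NA_real_, n)
    ok <- !is.na(x) & !is.na(lms$M) & x > 0
    z[ok] <- lms_zscore(x[ok], lms$L[ok], lms$M[ok], lms$S[ok])
    out_of_range <- !is.na(x) & !is.na(index_value) & is.na(lms$M)
    list(z = z, oor = out_of_range)
  }
  wa <- one("weight_for_age", children$weight_kg, children$age_months)
  ha <- one("height_for_age", children$height_cm, children$age_months)
  wh <- one("weight_for_height", children$weight_kg, children$height_cm)

  flag_tbl <- cbind(
    implausible_wa = !is.na(wa$z) & abs(wa$z) > 6,
    implausible_ha = !is.na(ha$z) & abs(ha$z) > 6,
    implausible_wh = !is.na(wh$z) & abs(wh$z) > 6,
    out_of_range_wa = wa$oor, out_of_range_ha = ha$oor,
    out_of_range_wh = wh$oor
  )
  z_wa <- unname(ifelse(flag_tbl[, "implausible_wa"], NA_real_, wa$z))
  z_ha <- unname(ifelse(flag_tbl[, "implausible_ha"], NA_real_, ha$z))
  z_wh <- unname(ifelse(flag_tbl[, "implausible_wh"], NA_real_, wh$z))

  severe <- classify_severe_undernutrition(z_wa, z_ha, z_wh)
  unclassifiable <- is.na(severe)
  flags <- apply(cbind(flag_tbl, unclassifiable = unclassifiable), 1L,
                 function(r) paste(names(r)[r], collapse = ","))

  dplyr::bind_cols(
    tibble::as_tibble(children),
    tibble::tibble(z_wa = z_wa, z_ha = z_ha, z_wh = z_wh,
                   severe_undernutrition = severe, anthro_flags = flags)
  )
}
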