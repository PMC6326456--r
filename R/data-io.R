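#' Child-record schema
#'
#' Column names and types of the child-record table shared by every stage
#' of the pipeline. Coordinates are cluster-level (DHS releases displace
#' them by up to 20 km); children inherit their cluster's location.
#'
#' @return Named character vector mapping field name to type
#'   (`"integer"`, `"double"`, `"logical"`, `"character"`).
#' @export
child_schema <- function() {
  c(child_id = "character", cluster_id = "character",
    survey_round = "integer", interview_month = "integer",
    age_months = "integer", sex = "character",
    weight_kg = "double", height_cm = "double",
    relation_to_head = "character", breastfed = "character",
    mother_age_years = "integer", religion = "character",
    native_language = "character", mother_education_years = "integer",
    urban = "logical", iwi = "double", electricity = "logical",
    sanitation_access = "logical", region = "character",
    lon = "double", lat = "double")
}

# internal: per-row hard-validation reasons for a child table (list of
# character vectors, empty when the row is valid)
child_row_problems <- function(df) {
  n <- nrow(df)
  reasons <- rep(list(character()), n)
  add <- function(bad, why) {
    idx <- which(bad)
    for (i in idx) reasons[[i]] <<- c(reasons[[i]], why)
  }
  add(is.na(df$child_id) | df$child_id == "", "missing child_id")
  add(!is.na(df$age_months) & (df$age_months < 0 | df$age_months > 59),
      "age_months outside [0, 59]")
  add(is.na(df$age_months), "missing age_months")
  add(!is.na(df$weight_kg) & df$weight_kg <= 0, "non-positive weight")
  add(!is.na(df$height_cm) & df$height_cm <= 0, "non-positive height")
  add(!is.na(df$sex) & !df$sex %in% c("male", "female"),
      "sex not male/female")
  add(!is.na(df$survey_round) & !df$survey_round %in% c(2008L, 2013L),
      "survey_round not 2008/2013")
  add(!is.na(df$iwi) & (df$iwi < 0 | df$iwi > 100), "iwi outside [0, 100]")
  add(!is.na(df$lon) & abs(df$lon) > 180, "lon outside [-180, 180]")
  add(!is.na(df$lat) & abs(df$lat) > 90, "lat outside [-90, 90]")
  dup <- duplicated(df$child_id) & !is.na(df$child_id)
  add(dup, "duplicate child_id")
  reasons
}

#' Read child records from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row) of child/mother/household
#' records, applies optional column renaming, coerces to the
#' [child_schema()] types, and validates every row. Missing values are the
#' empty string or `"NA"`; a missing measurement is never encoded as 0.
#' Rows failing a hard invariant (non-positive measurement, age outside
#' 0--59 months, bad coordinates, duplicated `child_id`, ...) are rejected
#' and reported, so `nrow(accepted) + nrow(rejected)` equals the raw row
#' count.
#'
#' @param path Path to the CSV file.
#' @param mapping Optional named character vector `c(field = "csv_column")`
#'   for files whose headers differ from [child_schema()] names.
#' @return A tibble of accepted records with attributes `rejected`
#'   (tibble of `row`, `reason`) and `n_input`.
#' @export
read_children <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort_nutricate(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) abort_nutricate("empty file")
  if (!is.null(mapping)) {
    miss <- setdiff(unname(mapping), names(raw))
    if (length(miss) > 0) {
      abort_nutricate(paste0("mapped column(s) absent: ",
                             paste(miss, collapse = ", ")))
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(mapping, names(mapping)))
  }
  schema <- child_schema()
  miss <- setdiff(names(schema), names(raw))
  if (length(miss) > 0) {
    abort_nutricate(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  df <- coerce_children(raw[names(schema)])
  problems <- child_row_problems(df)
  bad <- lengths(problems) > 0
  rejected <- tibble::tibble(
    row = which(bad),
    reason = vapply(problems[bad], paste, "", collapse = "; ")
  )
  accepted <- tibble::as_tibble(df[!bad, ])
  attr(accepted, "rejected") <- rejected
  attr(accepted, "n_input") <- nrow(df)
  accepted
}

# internal: coerce character columns to schema types
coerce_children <- function(df) {
  schema <- child_schema()
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      integer = suppressWarnings(as.integer(df[[col]])),
      double = suppressWarnings(as.numeric(df[[col]])),
      logical = parse_logical_col(df[[col]]),
      as.character(df[[col]])
    )
  }
  df
}

parse_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Write child records to CSV
#'
#' Inverse of [read_children()]: identifiers and integers round-trip
#' bit-exactly, reals to full `readr` precision. Missing values are written
#' as `NA`.
#'
#' @param children Tibble of child records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_children <- function(children, path) {
  readr::write_csv(children[names(child_schema())], path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' Read conflict events
#'
#' Reads georeferenced conflict events from CSV (columns `lon`, `lat`,
#' `month`, `deaths`) or a GeoJSON FeatureCollection of Points with
#' `month` and `deaths` properties. `month` is the calendar month index
#' ([month_index()]); `deaths` the best-estimate battle-related fatality
#' count. The source database's 25-deaths-per-year inclusion threshold
#' applies at the conflict level upstream and is not re-applied per event.
#' Rows with out-of-range coordinates or negative deaths are rejected with
#' a reason.
#'
#' @param path Path to a `.csv` or `.geojson`/`.json` file.
#' @return Tibble with columns `lon`, `lat`, `month`, `deaths`, carrying
#'   `rejected` / `n_input` attributes like [read_children()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort_nutricate(paste0("file not found: ", path))
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    df <- read_events_geojson(path)
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                          na = c("", "NA"), progress = FALSE)
    need <- c("lon", "lat", "month", "deaths")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) {
      abort_nutricate(paste0("missing column(s): ",
                             paste(miss, collapse = ", ")))
    }
    df <- df[need]
  }
  n <- nrow(df)
  reasons <- rep(list(character()), n)
  add <- function(bad, why) {
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  add(is.na(df$lon) | abs(df$lon) > 180, "malformed lon")
  add(is.na(df$lat) | abs(df$lat) > 90, "malformed lat")
  add(is.na(df$month), "missing month")
  add(is.na(df$deaths) | df$deaths < 0, "negative or missing deaths")
  bad <- lengths(reasons) > 0
  accepted <- tibble::as_tibble(df[!bad, ])
  accepted$month <- as.integer(accepted$month)
  attr(accepted, "rejected") <- tibble::tibble(
    row = which(bad),
    reason = vapply(reasons[bad], paste, "", collapse = "; ")
  )
  attr(accepted, "n_input") <- n
  accepted
}

read_events_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort_nutricate("GeoJSON must be a FeatureCollection")
  }
  rows <- purrr::map(gj$features, function(f) {
    coords <- f$geometry$coordinates
    tibble::tibble(
      lon = as.numeric(coords[[1]]), lat = as.numeric(coords[[2]]),
      month = as.numeric(f$properties$month %||% NA),
      deaths = as.numeric(f$properties$deaths %||% NA)
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(lon = numeric(), lat = numeric(),
                          month = numeric(), deaths = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Validate a child-record table
#'
#' Report-only audit of an in-memory child table: per-field missingness,
#' out-of-range counts, duplicated `child_id`s. The dataset passes when it
#' has zero hard violations (duplicates or out-of-range values);
#' missingness alone does not fail it.
#'
#' @param children Tibble of child records.
#' @return A list of class `nutricate_validation` with elements
#'   `missingness` (tibble field/n_missing), `out_of_range` (tibble
#'   field/n), `n_duplicate_ids`, and `passed` (logical).
#' @export
validate_dataset <- function(children) {
  fields <- intersect(names(child_schema()), names(children))
  missingness <- tibble::tibble(
    field = fields,
    n_missing = vapply(fields, function(f) sum(is.na(children[[f]])), 0L,
                       USE.NAMES = FALSE)
  )
  oor <- tibble::tibble(
    field = c("age_months", "weight_kg", "height_cm", "iwi", "lon", "lat"),
    n = c(
      sum(children$age_months < 0 | children$age_months > 59, na.rm = TRUE),
      sum(children$weight_kg <= 0, na.rm = TRUE),
      sum(children$height_cm <= 0, na.rm = TRUE),
      sum(children$iwi < 0 | children$iwi > 100, na.rm = TRUE),
      sum(abs(children$lon) > 180, na.rm = TRUE),
      sum(abs(children$lat) > 90, na.rm = TRUE)
    )
  )
  n_dup <- sum(duplicated(children$child_id))
  out <- list(missingness = missingness, out_of_range = oor,
              n_duplicate_ids = n_dup,
              passed = n_dup == 0 && sum(oor$n) == 0)
  class(out) <- "nutricate_validation"
  out
}

#' @export
print.nutricate_validation <- function(x, ...) {
  cat("Child dataset validation:",
      if (x$passed) "PASSED" else "FAILED", "\n")
  cat(" duplicate child_ids:", x$n_duplicate_ids, "\n")
  cat(" out-of-range values:", sum(x$out_of_range$n), "\n")
  cat(" fields with missing values:",
      sum(x$missingness$n_missing > 0), "\n")
  invisible(x)
}

#' Study configuration
#'
#' Bundles the knobs of a full pipeline run. Defaults follow the study
#' design: a 70/30 train/test split, 12-month retrospective exposure
#' windows, a conflict-intensity inclusion threshold of 10 for the
#' conflict subgroup, and 1,000 bootstrap iterations (scale `n_boot`,
#' `bart` down for desk-scale runs).
#'
#' @param seed Integer master seed.
#' @param split_fraction Training fraction in (0, 1).
#' @param n_boot Bootstrap iterations.
#' @param window_months Retrospective exposure window length.
#' @param conflict_threshold Minimum per-child intensity for the
#'   conflict-exposed subgroup (children strictly between 0 and the
#'   threshold fall in neither subgroup).
#' @param bart A [bart_config()].
#' @param schema_version Config schema version string.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L, split_fraction = 0.7, n_boot = 1000L,
                         window_months = 12L, conflict_threshold = 10,
                         bart = bart_config(), schema_version = "1") {
  stopifnot(split_fraction > 0, split_fraction < 1,
            n_boot >= 1, window_months >= 1)
  structure(list(seed = as.integer(seed), split_fraction = split_fraction,
                 n_boot = as.integer(n_boot),
                 window_months = as.integer(window_months),
                 conflict_threshold = conflict_threshold, bart = bart,
                 schema_version = schema_version),
            class = "study_config")
}

#' Read/write a study configuration
#'
#' Flat key-value JSON with a `schema_version` key; BART hyperparameters
#' are nested under `bart`.
#'
#' @param path File path.
#' @param config A [study_config()].
#' @return `read_study_config()` returns a [study_config()].
#' @export
write_study_config <- function(config, path) {
  x <- unclass(config)
  x$bart <- unclass(x$bart)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_config(seed = x$seed, split_fraction = x$split_fraction,
               n_boot = x$n_boot, window_months = x$window_months,
               conflict_threshold = x$conflict_threshold,
               bart = do.call(bart_config, as.list(x$bart)),
               schema_version = x$schema_version %||% "1")
}
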