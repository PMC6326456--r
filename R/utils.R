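#' Calendar month index
#'
#' Months are represented throughout the package as a single integer,
#' `year * 12 + (month - 1)`, so that window arithmetic never has to deal
#' with year boundaries.
#'
#' @param year Calendar year (e.g. 2013).
#' @param month Month of year, 1--12.
#' @return Integer month index.
#' @examples
#' month_index(2013, 2) - month_index(2012, 2)  # 12
#' @export
month_index <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12, na.rm = TRUE))
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

#' @rdname month_index
#' @param index Integer month index as produced by [month_index()].
#' @return `month_label()` returns a "YYYY-MM" string.
#' @export
month_label <- function(index) {
  sprintf("%04d-%02d", index %/% 12L, index %% 12L + 1L)
}

# internal: stop with a consistent error class
abort_nutricate <- function(msg, class = "nutricate_error") {
  rlang::abort(msg, class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
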