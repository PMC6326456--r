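#' Grid specification for intensity surfaces
#'
#' A regular lon/lat grid with half-open square cells
#' `[lon0 + i*cell, lon0 + (i+1)*cell) x [lat0 + j*cell, lat0 + (j+1)*cell)`.
#' The default 0.1 degree cell is ~11 km at Nigerian latitudes.
#'
#' @param lon_min,lon_max,lat_min,lat_max Bounding box, decimal degrees
#'   WGS84.
#' @param cell_deg Cell size in decimal degrees.
#' @return List of class `grid_spec`.
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cell_deg = 0.1) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, cell_deg > 0)
  n_lon <- ceiling((lon_max - lon_min) / cell_deg - 1e-9)
  n_lat <- ceiling((lat_max - lat_min) / cell_deg - 1e-9)
  if (n_lon < 1 || n_lat < 1) abort_nutricate("empty grid spec")
  structure(list(lon_min = lon_min, lat_min = lat_min, cell_deg = cell_deg,
                 n_lon = as.integer(n_lon), n_lat = as.integer(n_lat),
                 lon_max = lon_min + n_lon * cell_deg,
                 lat_max = lat_min + n_lat * cell_deg),
            class = "grid_spec")
}

KM_PER_DEG <- 111.32

#' Estimate a monthly conflict-intensity surface
#'
#' Treats conflict events as manifestations of a latent spatial point
#' process and estimates its intensity for the retrospective window
#' `[ref_month - window_months, ref_month - 1]` (the completed months
#' strictly before `ref_month`) by a Gaussian kernel density over event
#' locations, each event weighted by its battle-related deaths. Distances
#' are measured in km under an equirectangular projection with a fixed
#' reference parallel; the kernel is integrated exactly over each cell
#' and edge-corrected per event (an event inside the box has its truncated
#' kernel renormalized to its own in-box mass), so the surface's total
#' mass equals the total window deaths of in-box events exactly
#' (interpretation: expected deaths per grid cell over the window).
#'
#' @param events Tibble with columns `lon`, `lat`, `month`, `deaths`.
#' @param ref_month Reference calendar month index ([month_index()]).
#' @param window_months Window length in months (default 12).
#' @param spec A [grid_spec()].
#' @param bandwidth_km Kernel standard deviation in km (default 30; larger
#'   than the <= 20 km DHS coordinate displacement so displaced cluster
#'   coordinates still fall under an event's kernel mass).
#' @param proj_lat Reference parallel (degrees) for the km-per-degree-of-
#'   longitude scale; defaults to the grid's central latitude. Fix it
#'   explicitly when comparing grids over different boxes.
#' @param trunc_sigmas Radial kernel truncation in bandwidths (default 4):
#'   cells whose centre lies farther than `trunc_sigmas * bandwidth_km`
#'   from an event receive exactly zero mass from it, so locations far
#'   from every event have intensity exactly 0 (the "no conflict"
#'   subgroup is well defined).
#' @return An `intensity_grid`: list with the spec, `month`,
#'   `window_months` and a `values` matrix (`n_lon` x `n_lat`) of
#'   non-negative expected deaths per cell.
#' @export
estimate_intensity <- function(events, ref_month, window_months = 12L,
                               spec, bandwidth_km = 30, proj_lat = NULL,
                               trunc_sigmas = 4) {
  stopifnot(inherits(spec, "grid_spec"), window_months >= 1)
  inside <- events$month >= ref_month - window_months &
    events$month <= ref_month - 1
  ev <- events[inside, , drop = FALSE]
  values <- matrix(0, nrow = spec$n_lon, ncol = spec$n_lat)
  if (nrow(ev) > 0 && sum(ev$deaths) > 0) {
    lat_c <- proj_lat %||% ((spec$lat_min + spec$lat_max) / 2)
    kx <- KM_PER_DEG * cos(lat_c * pi / 180)   # km per degree lon
    ky <- KM_PER_DEG                           # km per degree lat
    lon_edges <- spec$lon_min + (0:spec$n_lon) * spec$cell_deg
    lat_edges <- spec$lat_min + (0:spec$n_lat) * spec$cell_deg
    lon_mid <- (lon_edges[-1] + lon_edges[-length(lon_edges)]) / 2
    lat_mid <- (lat_edges[-1] + lat_edges[-length(lat_edges)]) / 2
    r2max <- (trunc_sigmas * bandwidth_km)^2
    for (e in seq_len(nrow(ev))) {
      px <- diff(stats::pnorm((lon_edges - ev$lon[e]) * kx / bandwidth_km))
      py <- diff(stats::pnorm((lat_edges - ev$lat[e]) * ky / bandwidth_km))
      contrib <- px %o% py
      d2 <- outer(((lon_mid - ev$lon[e]) * kx)^2,
                  ((lat_mid - ev$lat[e]) * ky)^2, `+`)
      contrib[d2 > r2max] <- 0
      in_box <- ev$lon[e] >= spec$lon_min && ev$lon[e] <= spec$lon_max &&
        ev$lat[e] >= spec$lat_min && ev$lat[e] <= spec$lat_max
      frac <- sum(contrib)
      if (in_box && frac > 1e-12) {
        contrib <- contrib / frac
      }
      values <- values + ev$deaths[e] * contrib
    }
  }
  structure(list(spec = spec, month = ref_month,
                 window_months = as.integer(window_months),
                 bandwidth_km = bandwidth_km, values = values),
            class = "intensity_grid")
}

#' Look up an intensity value at a point
#'
#' Returns the value of the half-open grid cell containing the point; a
#' point exactly on an interior cell boundary belongs to the cell on its
#' east/north side.
#'
#' @param grid An `intensity_grid` from [estimate_intensity()].
#' @param lon,lat Point coordinates (vectorized, equal length).
#' @return Numeric intensity value(s); errors if any point falls outside
#'   the grid bounding box.
#' @export
lookup_intensity <- function(grid, lon, lat) {
  spec <- grid$spec
  i <- floor((lon - spec$lon_min) / spec$cell_deg) + 1
  j <- floor((lat - spec$lat_min) / spec$cell_deg) + 1
  if (any(i < 1 | i > spec$n_lon | j < 1 | j > spec$n_lat | is.na(i * j))) {
    abort_nutricate("point outside intensity grid bounding box")
  }
  grid$values[cbind(i, j)]
}

#' Assign each child a retrospective conflict-intensity exposure
#'
#' For every distinct interview month, estimates the intensity surface over
#' the 12 completed months strictly before that month and reads off the
#' value at each child's (cluster) location.
#'
#' @param children Tibble with columns `interview_month`, `lon`, `lat`.
#' @param events Conflict-event tibble (see [read_events()]).
#' @param window_months Window length (default 12).
#' @param spec A [grid_spec()]; defaults to the bounding box of children
#'   and events padded by one cell.
#' @param bandwidth_km Kernel bandwidth in km.
#' @param proj_lat Reference parallel, see [estimate_intensity()].
#' @return Numeric vector of per-child intensity values (expected deaths
#'   in the child's grid cell over the window).
#' @export
assign_child_intensity <- function(children, events, window_months = 12L,
                                   spec = NULL, bandwidth_km = 30,
                                   proj_lat = NULL) {
  if (is.null(spec)) {
    lons <- c(children$lon, events$lon); lats <- c(children$lat, events$lat)
    spec <- grid_spec(min(lons) - 0.1, max(lons) + 0.1,
                      min(lats) - 0.1, max(lats) + 0.1)
  }
  out <- rep(NA_real_, nrow(children))
  for (m in unique(children$interview_month)) {
    grid <- estimate_intensity(events, m, window_months, spec,
                               bandwidth_km, proj_lat)
    idx <- which(children$interview_month == m)
    out[idx] <- lookup_intensity(grid, children$lon[idx], children$lat[idx])
  }
  out
}

#' Long-format export of an intensity grid
#'
#' @param x An `intensity_grid`.
#' @param ... Unused.
#' @return Tibble with cell-center `lon`, `lat` and `value`.
#' @method as_tibble intensity_grid
#' @export
as_tibble.intensity_grid <- function(x, ...) {
  spec <- x$spec
  tibble::tibble(
    lon = rep(spec$lon_min + (seq_len(spec$n_lon) - 0.5) * spec$cell_deg,
              times = spec$n_lat),
    lat = rep(spec$lat_min + (seq_len(spec$n_lat) - 0.5) * spec$cell_deg,
              each = spec$n_lon),
    value = as.vector(x$values)
  )
}

#' Retrospective window extremum of a monthly series
#'
#' Applies `max` (floods: surface runoff, mm/day) or `min` (drought index,
#' %) over the window of completed months strictly before `ref_month`,
#' skipping missing months.
#'
#' @param series Tibble with columns `month` (calendar month index,
#'   strictly increasing) and `value`.
#' @param ref_month Reference month index.
#' @param window_months Window length (default 12).
#' @param mode `"max"` or `"min"`.
#' @return The window extremum (scalar).
#' @export
window_extremum <- function(series, ref_month, window_months = 12L,
                            mode = c("max", "min")) {
  mode <- match.arg(mode)
  stopifnot(window_months >= 1)
  if (is.unsorted(series$month, strictly = TRUE)) {
    abort_nutricate("series months must be strictly increasing")
  }
  sel <- series$month >= ref_month - window_months &
    series$month <= ref_month - 1 & !is.na(series$value)
  if (!any(sel)) abort_nutricate("no non-missing values in window")
  if (mode == "max") max(series$value[sel]) else min(series$value[sel])
}
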