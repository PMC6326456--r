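#' Simulation configuration
#'
#' Parameters of the synthetic DHS-like population generator. The
#' defaults define the package's standard study conditions: 4,000
#' children in 60 spatial clusters per survey round over a Nigeria-sized
#' region, wealth-confounded education assignment, a probit outcome whose
#' education effects (`delta`, probit scale, level 1 = 0 by construction)
#' are meaningful only above the compulsory 9 years (levels 5-6),
#' insurgency-scale conflict concentrated around a north-east epicentre,
#' and a realized prevalence of severe undernutrition around 25% — in
#' line with the multiple-anthropometric-failure range reported for
#' Nigeria in 2008-2013.
#'
#' @param n_children Number of children.
#' @param n_clusters_per_round Survey clusters per round.
#' @param region Bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param delta Probit-scale education effects for levels 1..6
#'   (`delta[1]` must be 0; negative = protective).
#' @param intercept Baseline probit intercept.
#' @param wealth_outcome Probit coefficient of scaled wealth
#'   (`(iwi - 50) / 50`); negative, so wealth confounds education
#'   (wealth -> more education, wealth -> less undernutrition).
#' @param conflict_outcome Probit increase per expected window death in
#'   the child's grid cell.
#' @param sanitation_outcome Probit increase for severe sanitation
#'   deprivation.
#' @param event_rate Mean conflict events per month.
#' @param mean_deaths Mean battle-related deaths per event.
#' @param hotspot_center Conflict epicentre `c(lon, lat)`.
#' @param hotspot_share Mixture weights `c(core, broad)` of events drawn
#'   from the tight core and the broad halo around the epicentre (the
#'   remainder is uniform over the region).
#' @param hotspot_sd Spatial SDs (degrees) `c(core, broad)`.
#' @param cluster_hotspot_share Fraction of survey clusters placed near
#'   the epicentre city (survey clusters follow population, and the
#'   insurgency's epicentre is urban); the rest are uniform.
#' @param education_shares Marginal shares of the six education levels
#'   (sums to 1). Roughly balanced by default so every per-level contrast
#'   is identified at the default sample size; wealth confounding acts
#'   through which children occupy which level, not through the shares.
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_children = 4000L,
                              n_clusters_per_round = 60L,
                              region = c(3, 14, 4, 14),
                              delta = c(0, -0.05, -0.07, -0.05,
                                        -0.12, -0.15),
                              intercept = -0.8,
                              wealth_outcome = -0.35,
                              conflict_outcome = 0.008,
                              sanitation_outcome = 0.15,
                              event_rate = 15, mean_deaths = 20,
                              hotspot_center = c(12.5, 11.5),
                              hotspot_share = c(0.6, 0.25),
                              hotspot_sd = c(0.35, 1.0),
                              cluster_hotspot_share = 0.1,
                              education_shares = c(0.20, 0.16, 0.16,
                                                   0.16, 0.16, 0.16),
                              seed = 1L) {
  stopifnot(n_children >= n_clusters_per_round, delta[1] == 0,
            length(delta) == 6, sum(hotspot_share) <= 1,
            length(education_shares) == 6,
            abs(sum(education_shares) - 1) < 1e-9)
  structure(list(n_children = as.integer(n_children),
                 n_clusters_per_round = as.integer(n_clusters_per_round),
                 region = region, delta = delta, intercept = intercept,
                 wealth_outcome = wealth_outcome,
                 conflict_outcome = conflict_outcome,
                 sanitation_outcome = sanitation_outcome,
                 event_rate = event_rate, mean_deaths = mean_deaths,
                 hotspot_center = hotspot_center,
                 hotspot_share = hotspot_share,
                 hotspot_sd = hotspot_sd,
                 cluster_hotspot_share = cluster_hotspot_share,
                 education_shares = education_shares,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic smooth LMS growth reference
#'
#' Smooth monotone median curves with LMS parameters inside plausible
#' ranges (`S` in \[0.08, 0.15\], `L` in \[-1.5, 1.5\]) for both sexes
#' over ages 0-59 months (weight-for-age, height-for-age) and heights
#' 45-120 cm (weight-for-height). The weight-for-height median is derived
#' from the two age curves so that a child at the median of weight and
#' height for its age is also near the weight-for-height median. This is
#' a synthetic stand-in with the same CSV schema as real WHO tables,
#' which remain pluggable.
#'
#' @param seed Integer seed (perturbs sex offsets slightly).
#' @return Growth-reference tibble (see [validate_reference()]).
#' @export
generate_reference <- function(seed = 1L) {
  withr::with_seed(seed, {
    sex_mult <- c(male = 1 + abs(stats::rnorm(1, 0.03, 0.005)),
                  female = 1)
    ages <- 0:59
    out <- list()
    for (sx in c("male", "female")) {
      m_wa <- (3.2 + 11.5 * (ages / 59)^0.7) * sex_mult[[sx]]
      m_ha <- (49 + 46 * (ages / 59)^0.75) * (1 + (sex_mult[[sx]] - 1) / 3)
      out[[paste0(sx, "_wa")]] <- tibble::tibble(
        sex = sx, indicator = "weight_for_age", index_value = ages,
        L = 0.35 - 0.1 * ages / 59, M = m_wa,
        S = 0.11 + 0.02 * ages / 59
      )
      out[[paste0(sx, "_ha")]] <- tibble::tibble(
        sex = sx, indicator = "height_for_age", index_value = ages,
        L = 1, M = m_ha, S = 0.08
      )
      heights <- 45:120
      h_lo <- min(m_ha); h_hi <- max(m_ha)
      age_of_h <- stats::approx(m_ha, ages, pmin(pmax(heights, h_lo), h_hi))$y
      m_wh <- (3.2 + 11.5 * (age_of_h / 59)^0.7) * sex_mult[[sx]]
      below <- heights < h_lo
      m_wh[below] <- m_wh[!below][1] * (heights[below] / h_lo)^1.5
      above <- heights > h_hi
      if (any(above)) {
        m_wh[above] <- max(m_wh[!above]) + 0.25 * (heights[above] - h_hi)
      }
      out[[paste0(sx, "_wh")]] <- tibble::tibble(
        sex = sx, indicator = "weight_for_height", index_value = heights,
        L = 0.2, M = m_wh, S = 0.12
      )
    }
  })
  validate_reference(dplyr::bind_rows(out))
}

# Realize (weight, height) for all children at once so that the Bristol
# classifier reproduces the generated outcome exactly. A designated
# indicator fails (z in (-5.5, -3.1)) for y = 1 children; all realized
# non-missing z stay outside [-3, -2.9) and inside (-6, 6) otherwise.
# Weight is dropped (missing) in the rare corner where no weight satisfies
# all constraints for a healthy child.
realize_anthro_all <- function(y, fail, age, sex, ref) {
  n <- length(y)
  severe_z <- function(k) stats::runif(k, -5.5, -3.1)
  safe_z <- function(k) stats::runif(k, -2.5, 1.5)
  ha <- interpolate_reference(ref, sex, "height_for_age", age)
  wa <- interpolate_reference(ref, sex, "weight_for_age", age)
  z_ha <- ifelse(y == 1 & fail == "ha", severe_z(n), safe_z(n))
  height <- invert_lms(z_ha, ha$L, ha$M, ha$S)
  wh <- interpolate_reference(ref, sex, "weight_for_height", height)
  in_range <- !is.na(wh$M)
  fail[fail == "wh" & !in_range] <- "wa"

  t_wa <- ifelse(y == 1 & fail == "wa", severe_z(n), safe_z(n))
  weight <- invert_lms(t_wa, wa$L, wa$M, wa$S)
  sel_wh <- y == 1 & fail == "wh"
  if (any(sel_wh)) {
    weight[sel_wh] <- invert_lms(severe_z(sum(sel_wh)), wh$L[sel_wh],
                                 wh$M[sel_wh], wh$S[sel_wh])
  }
  # keep weight-for-height out of the dangerous [-6, -2.9) band where it
  # must stay non-severe
  need_safe <- (y == 0 | (y == 1 & fail == "ha")) & in_range
  z_wh <- rep(NA_real_, n)
  z_wh[in_range] <- lms_zscore(weight[in_range], wh$L[in_range],
                               wh$M[in_range], wh$S[in_range])
  danger <- which(need_safe & z_wh > -6 & z_wh < -2.9)
  for (i in danger) {
    w_safe <- invert_lms(-2.9, wh$L[i], wh$M[i], wh$S[i])
    z_wa_new <- lms_zscore(w_safe, wa$L[i], wa$M[i], wa$S[i])
    if (y[i] == 1) {                 # failing via height-for-age already
      weight[i] <- w_safe
    } else if (z_wa_new > -3 && z_wa_new < 6) {
      weight[i] <- w_safe
    } else {
      w_flag <- invert_lms(-6.2, wh$L[i], wh$M[i], wh$S[i])
      if (lms_zscore(w_flag, wa$L[i], wa$M[i], wa$S[i]) > -3) {
        weight[i] <- w_flag          # z_wh flagged implausible, ignored
      } else {
        weight[i] <- NA_real_        # no consistent weight: leave missing
      }
    }
  }
  list(weight = weight, height = height)
}

#' Generate a synthetic DHS-like population with known ground truth
#'
#' Simulates two spatially clustered survey rounds (interview windows
#' June-November 2008 and February-July 2013), wealth-confounded maternal
#' education, a probit outcome with education-level threshold effects and
#' a conflict-exposure term, conflict events from a spatially
#' heterogeneous Poisson process (tight insurgency core, broad halo,
#' uniform background), monthly drought/runoff series per cluster, and
#' anthropometry realized through the inverse LMS transform so that the
#' Bristol classifier reproduces the generated outcome for every child.
#'
#' @param cfg A [simulation_config()].
#' @param ref Optional growth reference (defaults to
#'   `generate_reference(cfg$seed)`).
#' @return List with tibbles `children` ([child_schema()] columns),
#'   `clusters`, `events`, `series` (cluster-month `drought_index`,
#'   `surface_runoff`), and `truth` (per-child `eta_base`, true outcome
#'   probability under every education level, true exposure; never fed to
#'   the analysis stages).
#' @export
generate_population <- function(cfg = simulation_config(), ref = NULL) {
  if (is.null(ref)) ref <- generate_reference(cfg$seed)
  box <- cfg$region
  withr::with_seed(cfg$seed, {
    # --- clusters, two rounds -------------------------------------------
    months_2008 <- month_index(2008, 6):month_index(2008, 11)
    months_2013 <- month_index(2013, 2):month_index(2013, 7)
    nc <- cfg$n_clusters_per_round
    draw_clusters <- function(round, months) {
      near_city <- stats::runif(nc) < cfg$cluster_hotspot_share
      lon <- ifelse(near_city,
                    pmin(box[2], pmax(box[1],
                         stats::rnorm(nc, cfg$hotspot_center[1], 0.3))),
                    stats::runif(nc, box[1], box[2]))
      lat <- ifelse(near_city,
                    pmin(box[4], pmax(box[3],
                         stats::rnorm(nc, cfg$hotspot_center[2], 0.3))),
                    stats::runif(nc, box[3], box[4]))
      tibble::tibble(
        cluster_id = sprintf("C%d_%03d", round, seq_len(nc)),
        survey_round = round,
        lon = lon, lat = lat,
        urban = stats::runif(nc) < ifelse(near_city, 0.8, 0.4),
        interview_month = sample(months, nc, replace = TRUE)
      )
    }
    clusters <- dplyr::bind_rows(draw_clusters(2008L, months_2008),
                                 draw_clusters(2013L, months_2013))
    regions <- c("north_east", "north_west", "north_central", "south_east",
                 "south_west", "south_south")
    clusters$region <- regions[1 + (findInterval(clusters$lat,
                                                 c(9, 11.5)) * 2 +
                                      (clusters$lon > 8.5))]

    # --- children -------------------------------------------------------
    n <- cfg$n_children
    ci <- sample(nrow(clusters), n, replace = TRUE)
    iwi <- pmin(100, pmax(0, 100 * stats::rbeta(n, 2, 3) +
                            10 * clusters$urban[ci]))
    # wealth-confounded education: children ranked by a noisy wealth
    # latent are allocated to levels in fixed shares, so richer mothers
    # are more educated while every level retains enough mass for its
    # contrast to be identified at the default sample size
    edu_latent <- iwi + stats::rnorm(n, 0, 25)
    shares <- cfg$education_shares
    level_sorted <- rep(1:6, times = round(shares * n))[seq_len(n)]
    level <- integer(n)
    level[order(edu_latent)] <- sort(level_sorted)
    years_lo <- c(0, 1, 7, 9, 10, 13)
    years_hi <- c(0, 6, 8, 9, 12, 16)
    edu_years <- as.integer(years_lo[level] +
      floor(stats::runif(n) * (years_hi[level] - years_lo[level] + 1)))
    level <- bin_education(edu_years)
    children <- tibble::tibble(
      child_id = sprintf("K%05d", seq_len(n)),
      cluster_id = clusters$cluster_id[ci],
      survey_round = clusters$survey_round[ci],
      interview_month = clusters$interview_month[ci],
      age_months = sample(0:59, n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE),
      relation_to_head = sample(c("child", "grandchild", "other"), n,
                                replace = TRUE, prob = c(0.8, 0.15, 0.05)),
      breastfed = sample(c("yes", "no"), n, replace = TRUE,
                         prob = c(0.7, 0.3)),
      mother_age_years = sample(16:45, n, replace = TRUE),
      religion = sample(c("muslim", "christian", "traditional"), n,
                        replace = TRUE, prob = c(0.5, 0.45, 0.05)),
      native_language = sample(c("hausa", "yoruba", "igbo", "other"), n,
                               replace = TRUE),
      mother_education_years = edu_years,
      urban = clusters$urban[ci],
      iwi = round(iwi, 2),
      electricity = stats::runif(n) < stats::plogis(-2.5 + 0.05 * iwi),
      sanitation_access = stats::runif(n) < stats::plogis(-1 + 0.04 * iwi),
      region = clusters$region[ci],
      lon = clusters$lon[ci],
      lat = clusters$lat[ci]
    )

    # --- conflict events ------------------------------------------------
    horizon <- (min(months_2008) - 13):max(months_2013)
    n_ev <- stats::rpois(length(horizon), cfg$event_rate)
    total_ev <- sum(n_ev)
    comp <- sample(c("core", "broad", "unif"), total_ev, replace = TRUE,
                   prob = c(cfg$hotspot_share[1], cfg$hotspot_share[2],
                            1 - sum(cfg$hotspot_share)))
    sdv <- ifelse(comp == "core", cfg$hotspot_sd[1], cfg$hotspot_sd[2])
    lon <- ifelse(comp == "unif", stats::runif(total_ev, box[1], box[2]),
                  pmin(box[2], pmax(box[1],
                       stats::rnorm(total_ev, cfg$hotspot_center[1], sdv))))
    lat <- ifelse(comp == "unif", stats::runif(total_ev, box[3], box[4]),
                  pmin(box[4], pmax(box[3],
                       stats::rnorm(total_ev, cfg$hotspot_center[2], sdv))))
    events <- tibble::tibble(
      lon = lon, lat = lat,
      month = rep(horizon, times = n_ev),
      deaths = 1 + stats::rpois(total_ev, max(cfg$mean_deaths - 1, 0))
    )

    # --- environmental series per cluster -------------------------------
    phase <- stats::runif(nrow(clusters), 0, 2 * pi)
    series <- tidyr::crossing(
      cluster_id = clusters$cluster_id, month = horizon
    ) |>
      dplyr::mutate(
        ph = phase[match(.data$cluster_id, clusters$cluster_id)],
        drought_index = pmin(100, pmax(0, 55 +
          25 * sin(2 * pi * .data$month / 12 + .data$ph) +
          stats::rnorm(dplyr::n(), 0, 8))),
        surface_runoff = pmax(0, 2 +
          1.5 * sin(2 * pi * .data$month / 12 + .data$ph + pi) +
          stats::rnorm(dplyr::n(), 0, 0.8))
      ) |>
      dplyr::select(-"ph")

    # --- true exposure and latent outcome -------------------------------
    spec <- grid_spec(box[1], box[2], box[3], box[4], 0.1)
    exposure <- assign_child_intensity(children, events, 12L, spec)
    eta_base <- cfg$intercept +
      cfg$wealth_outcome * (children$iwi - 50) / 50 +
      cfg$sanitation_outcome *
        classify_sanitation_deprivation(children$sanitation_access) +
      cfg$conflict_outcome * exposure +
      0.08 * (children$sex == "male") -
      0.1 * children$urban +
      0.05 * (children$age_months - 30) / 30
    eta <- eta_base + cfg$delta[level]
    p <- stats::pnorm(eta)
    if (any(p <= 0 | p >= 1)) {
      abort_nutricate("infeasible config: degenerate outcome probabilities")
    }
    y <- as.integer(stats::runif(n) < p)

    # --- anthropometry consistent with y --------------------------------
    fail_choice <- sample(c("wa", "ha", "wh"), n, replace = TRUE,
                          prob = c(0.45, 0.35, 0.2))
    wh_real <- realize_anthro_all(y, fail_choice, children$age_months,
                                  children$sex, ref)
    children$weight_kg <- round(wh_real$weight, 3)
    children$height_cm <- round(wh_real$height, 2)

    truth <- tibble::tibble(
      child_id = children$child_id,
      eta_base = eta_base,
      education_level = level,
      exposure = exposure,
      y = y
    )
    for (L in 1:6) {
      truth[[paste0("p_level", L)]] <-
        stats::pnorm(eta_base + cfg$delta[L])
    }
  })
  list(children = children,
       clusters = clusters[c("cluster_id", "survey_round", "lon", "lat",
                             "urban", "interview_month", "region")],
       events = events, series = series, truth = truth)
}

#' True conditional average treatment effect
#'
#' Exact (no-sampling) ground-truth CATE for a level contrast from the
#' generator's stored latent components: the mean over the selected
#' children of `pnorm(eta_base + delta[t]) - pnorm(eta_base + delta[c])`.
#'
#' @param truth Truth tibble from [generate_population()].
#' @param level_t,level_c Treated and control education levels (1..6).
#' @param keep Optional logical vector or `child_id` character vector
#'   selecting a subgroup.
#' @return Scalar true CATE.
#' @export
true_cate <- function(truth, level_t, level_c, keep = NULL) {
  sel <- rep(TRUE, nrow(truth))
  if (!is.null(keep)) {
    sel <- if (is.character(keep)) truth$child_id %in% keep else keep
  }
  if (!any(sel)) abort_nutricate("empty subgroup")
  mean(truth[[paste0("p_level", level_t)]][sel] -
         truth[[paste0("p_level", level_c)]][sel])
}
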