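#' Assemble the BART covariate table
#'
#' Builds the covariate tibble handed to the probit BART model: the
#' treatment column `education_level` (ordinal 1..6) plus the child,
#' mother and household covariates, survey round (time as a control),
#' conflict intensity, flood/drought window extrema and the partition
#' area. Anthropometry never enters (it defines the outcome).
#'
#' @param children Analysis tibble carrying the [child_schema()] fields
#'   plus `education_level`, `conflict_intensity`, and optionally
#'   `flood`, `drought`, `partition_area_id`.
#' @return Tibble of model covariates (categoricals still categorical;
#'   encode with [encode_covariates()]).
#' @export
bart_covariates <- function(children) {
  out <- tibble::tibble(
    education_level = as.numeric(children$education_level),
    age_months = as.numeric(children$age_months),
    sex = children$sex,
    relation_to_head = children$relation_to_head,
    breastfed = children$breastfed,
    mother_age_years = as.numeric(children$mother_age_years),
    religion = children$religion,
    native_language = children$native_language,
    urban = children$urban,
    iwi = children$iwi,
    electricity = children$electricity,
    sanitation_deprived =
      classify_sanitation_deprivation(children$sanitation_access),
    region = children$region,
    survey_round = as.numeric(children$survey_round),
    conflict_intensity = children$conflict_intensity
  )
  for (extra in c("flood", "drought")) {
    if (extra %in% names(children)) out[[extra]] <- children[[extra]]
  }
  if ("partition_area_id" %in% names(children)) {
    out$partition_area_id <- children$partition_area_id
  }
  out
}

#' Run the full heterogeneous-treatment-effect analysis
#'
#' Executes the pipeline end to end: outcome construction (LMS z-scores,
#' Bristol rule), spatial partition, conflict/flood/drought exposure
#' assignment, treatment coding, 70/30 train/test split, one probit-BART
#' fit for diagnostics, and a bootstrap of refitted models producing
#' per-level CATEs with 95% percentile credible regions, the untreated
#' (policy, level 1 -> 4) analysis, and the conflict-exposure subgroup
#' contrast. Each test child contributes one individual effect, oriented
#' treated minus control (negative = protective): children observed at
#' levels 2-6 are contrasted with counterfactual level 1; children at
#' level 1 with counterfactual level 4.
#'
#' @param children Validated child table ([read_children()] or
#'   [generate_population()]).
#' @param events Conflict events tibble.
#' @param reference Growth-reference table.
#' @param config A [study_config()].
#' @param series Optional per-cluster monthly environmental series
#'   (columns `cluster_id`, `month`, `drought_index`, `surface_runoff`);
#'   when supplied, 12-month flood maxima and drought minima enter the
#'   covariates.
#' @param policy_level Counterfactual level for the untreated analysis
#'   (default 4, the compulsory 9 years).
#' @return A `nutricate_results` list: `cate_by_level` (tibble level,
#'   delta_probability, lower, upper, n), `subgroups` (conflict contrast),
#'   `ite` (child_id, theta), `roc`, `estimate` (master `cate_estimate`),
#'   `analysis` (per-child analysis table), `partition`, `log`, `config`.
#' @export
run_analysis <- function(children, events, reference,
                         config = study_config(), series = NULL,
                         policy_level = 4L) {
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_nutricate(paste0("stage [", name, "] failed: ",
                             conditionMessage(e)))
    })
  }

  # --- outcomes ---------------------------------------------------------
  anal <- stage("outcomes", {
    res <- compute_indicators(children, reference)
    n_un <- sum(is.na(res$severe_undernutrition))
    note("outcomes: ", nrow(res) - n_un, " classifiable children, ",
         n_un, " unclassifiable excluded")
    dplyr::filter(res, !is.na(.data$severe_undernutrition))
  })

  # --- partition --------------------------------------------------------
  partition <- stage("partition", {
    cl <- dplyr::distinct(anal, .data$cluster_id, .data$survey_round,
                          .data$lon, .data$lat)
    p <- build_partition(cl)
    note("partition: ", nrow(p$areas), " areas from ", nrow(cl),
         " clusters")
    p
  })
  anal <- dplyr::left_join(anal, partition$assignment, by = "cluster_id")
  anal$partition_area_id <- anal$area_id
  anal$area_id <- NULL

  # --- exposures --------------------------------------------------------
  anal <- stage("exposures", {
    anal$conflict_intensity <- assign_child_intensity(
      anal, events, config$window_months)
    if (!is.null(series)) {
      key <- dplyr::distinct(anal, .data$cluster_id, .data$interview_month)
      key$flood <- NA_real_; key$drought <- NA_real_
      for (r in seq_len(nrow(key))) {
        s <- series[series$cluster_id == key$cluster_id[r], ]
        key$flood[r] <- window_extremum(
          tibble::tibble(month = s$month, value = s$surface_runoff),
          key$interview_month[r], config$window_months, "max")
        key$drought[r] <- window_extremum(
          tibble::tibble(month = s$month, value = s$drought_index),
          key$interview_month[r], config$window_months, "min")
      }
      anal <- dplyr::left_join(anal, key,
                               by = c("cluster_id", "interview_month"))
    }
    note("exposures: mean conflict intensity ",
         round(mean(anal$conflict_intensity), 3))
    anal
  })

  # --- treatment coding and split --------------------------------------
  anal$education_level <- bin_education(anal$mother_education_years)
  anal <- dplyr::filter(anal, !is.na(.data$education_level))
  sp <- stage("split", split_train_test(anal, config$split_fraction,
                                        seed = config$seed))
  note("split: ", nrow(sp$train), " train / ", nrow(sp$test), " test")

  # --- design matrices --------------------------------------------------
  cov_all <- bart_covariates(anal)
  enc <- encode_covariates(cov_all)
  lv_map <- enc$levels_map
  X_train <- encode_covariates(bart_covariates(sp$train), lv_map)$X
  y_train <- as.integer(sp$train$severe_undernutrition)
  test_cov <- bart_covariates(sp$test)
  cf_cov <- test_cov
  cf_cov$education_level <- ifelse(test_cov$education_level == 1,
                                   as.numeric(policy_level), 1)
  X_factual <- encode_covariates(test_cov, lv_map)$X
  X_cf <- encode_covariates(cf_cov, lv_map)$X
  treated_is_factual <- sp$test$education_level >= 2

  # --- diagnostics fit --------------------------------------------------
  main_fit <- stage("fit", withr::with_seed(config$seed, {
    fit_probit_bart(X_train, y_train, config$bart, X_test = X_factual,
                    keep_trees = FALSE)
  }))
  roc <- stage("evaluate", {
    scores <- colMeans(stats::pnorm(main_fit$test_draws))
    roc_auc(sp$test$severe_undernutrition, scores)
  })
  note(sprintf("evaluate: AUC %.3f, cutoff %.3f", roc$auc, roc$cutoff))

  # --- bootstrap CATE ---------------------------------------------------
  n_test <- nrow(sp$test)
  X_pred <- rbind(X_factual, X_cf)
  boot_theta <- matrix(NA_real_, config$n_boot, n_test)
  stage("cate", withr::with_seed(config$seed, {
    for (b in seq_len(config$n_boot)) {
      idx <- sample.int(nrow(X_train), replace = TRUE)
      fit <- fit_probit_bart(X_train[idx, , drop = FALSE], y_train[idx],
                             config$bart, X_test = X_pred,
                             keep_trees = FALSE)
      p_f <- colMeans(stats::pnorm(
        fit$test_draws[, seq_len(n_test), drop = FALSE]))
      p_c <- colMeans(stats::pnorm(
        fit$test_draws[, n_test + seq_len(n_test), drop = FALSE]))
      boot_theta[b, ] <- ifelse(treated_is_factual, p_f - p_c, p_c - p_f)
    }
  }))
  ite <- tibble::tibble(child_id = sp$test$child_id,
                        theta = colMeans(boot_theta))
  boots <- rowMeans(boot_theta)
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  estimate <- new_cate_estimate(mean(boots), qs[1], qs[2], ite,
                                boots = boots, boot_theta = boot_theta,
                                subgroup = "all test children")

  # --- per-level and subgroup summaries --------------------------------
  lvl <- sp$test$education_level
  rows <- list()
  for (L in 1:6) {
    keep <- lvl == L
    label <- if (L == 1) {
      paste0("untreated: level 1 -> ", policy_level)
    } else {
      paste0("level ", L, " vs level 1")
    }
    if (!any(keep)) {
      note("cate: no test children at level ", L, "; analysis skipped")
      next
    }
    est <- subgroup_cate(estimate, keep, label)
    rows[[length(rows) + 1]] <- tibble::tibble(
      level = L, analysis = label, delta_probability = est$cate,
      lower = est$lower, upper = est$upper, n = est$n_children
    )
  }
  cate_by_level <- dplyr::bind_rows(rows)

  educated <- lvl >= 2
  intensity_test <- sp$test$conflict_intensity
  sub_rows <- list()
  for (sg in list(list(keep = educated & intensity_test == 0,
                       label = "no conflict (intensity = 0)"),
                  list(keep = educated &
                         intensity_test > config$conflict_threshold,
                       label = paste0("conflict (intensity > ",
                                      config$conflict_threshold, ")")))) {
    if (!any(sg$keep)) {
      note("subgroup '", sg$label, "' empty; skipped")
      next
    }
    est <- subgroup_cate(estimate, sg$keep, sg$label)
    sub_rows[[length(sub_rows) + 1]] <- tidy(est) |>
      dplyr::mutate(n_children = est$n_children)
  }
  subgroups <- dplyr::bind_rows(sub_rows)

  structure(list(cate_by_level = cate_by_level, subgroups = subgroups,
                 ite = ite, roc = roc, estimate = estimate,
                 analysis = anal, split = sp, partition = partition,
                 main_fit = main_fit, log = log_lines, config = config),
            class = "nutricate_results")
}

#' @export
print.nutricate_results <- function(x, ...) {
  cat("Heterogeneous treatment effect analysis\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  print(x$cate_by_level)
  invisible(x)
}

#' Write the result tables of a pipeline run
#'
#' Emits `cate_by_level.csv`, `ite.csv`, `subgroup_cate.csv`, `roc.csv`,
#' `metrics.json` (AUC, cutoff, sensitivity, specificity) and
#' `run_log.txt` (stage log plus a config echo) into `out_dir`.
#'
#' @param results A `nutricate_results` from [run_analysis()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(results$cate_by_level,
                   file.path(out_dir, "cate_by_level.csv"), progress = FALSE)
  readr::write_csv(results$ite, file.path(out_dir, "ite.csv"),
                   progress = FALSE)
  readr::write_csv(results$subgroups,
                   file.path(out_dir, "subgroup_cate.csv"), progress = FALSE)
  readr::write_csv(results$roc$curve, file.path(out_dir, "roc.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(auc = results$roc$auc, cutoff = results$roc$cutoff,
         sensitivity = results$roc$sensitivity,
         specificity = results$roc$specificity),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  cfg <- results$config
  writeLines(c(results$log, "",
               paste0("config: seed=", cfg$seed,
                      " split=", cfg$split_fraction,
                      " n_boot=", cfg$n_boot,
                      " window=", cfg$window_months,
                      " conflict_threshold=", cfg$conflict_threshold,
                      " trees=", cfg$bart$num_trees,
                      " burn_in=", cfg$bart$burn_in,
                      " draws=", cfg$bart$num_draws)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
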