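#' Run the full lesion structure-function pipeline
#'
#' Executes, from a single configuration and seed: cohort simulation,
#' per-subject virtual tractography (lesion intersection + connectome
#' construction), damage stratification and edge eligibility, ROI functional
#' connectivity via the adaptive graphical lasso, streamline functional
#' connectivity, edge-wise gamma GLMs at three response levels (ROI
#' correlation, ROI partial correlation, streamline), and the
#' communication-model comparison. All tabular outputs are written as TSV /
#' JSON under `out_dir` and hashed into a reproducible run manifest.
#'
#' @param config A list with components `cohort` (arguments for
#'   [cohort_config()]), and optionally `lambda_sc` (default 0.125),
#'   `lambda_non_sc` (0.2), `min_subjects` (3), `mode` (connectome
#'   normalization, default `"length_inverse"`), `alpha` (0.05) and
#'   `select_lambda` (logical; run cross-validated penalty selection,
#'   default `FALSE`). Alternatively a path to a JSON file with the same
#'   structure. When `cohort` is absent the configuration must name
#'   pre-existing inputs (`template_tsv`, `lesion_dir`, `series_dir`);
#'   missing inputs raise a dependency error.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with all stage results (`cohort`, `damage`,
#'   `eligible`, `fc`, `sfc`, `glm` (3 levels), `summary`, `cv`, `comm`)
#'   and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (!is.list(config)) {
    stop("config error: `config` must be a list or JSON path", call. = FALSE)
  }
  if (is.null(config$cohort)) {
    needed <- c("template_tsv", "lesion_dir", "series_dir")
    missing <- needed[!needed %in% names(config)]
    if (length(missing) > 0) {
      stop("dependency error: non-simulation run is missing ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    stop("file-based (non-simulation) runs are handled by calling the ",
         "stage functions directly; see the vignette", call. = FALSE)
  }
  bad <- setdiff(names(config),
                 c("cohort", "lambda_sc", "lambda_non_sc", "min_subjects",
                   "mode", "alpha", "select_lambda"))
  if (length(bad) > 0) {
    stop("config error: unknown field(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lambda_sc <- config$lambda_sc %||% 0.125
  lambda_non_sc <- config$lambda_non_sc %||% 0.2
  min_subjects <- config$min_subjects %||% 3L
  mode <- config$mode %||% "length_inverse"
  alpha <- config$alpha %||% 0.05

  cfg <- do.call(cohort_config, as.list(config$cohort))
  cohort <- simulate_cohort(cfg)
  disconnected <- lapply(cohort$subjects, `[[`, "disconnected_ids")

  # virtual tractography: per-subject connectomes and damage stratification
  weights <- subject_edge_weights(cohort$template, disconnected,
                                  cfg$n_rois, mode, cohort$atlas$rois)
  damage <- stratify_damage(weights)
  eligible <- eligible_edges(damage, min_subjects)

  # optional penalty selection by split-half cross-validation
  cv <- NULL
  if (isTRUE(config$select_lambda)) {
    cv <- select_penalty(lapply(cohort$subjects, `[[`, "roi_series"),
                         cohort$support, lambda_non_sc = lambda_non_sc)
    lambda_sc <- cv$selected_lambda_sc
  }

  # ROI-level FC per subject
  fc <- lapply(cohort$subjects, function(s) {
    fit_fc(s$roi_series, cohort$support, lambda_sc, lambda_non_sc)
  })
  roi_resp <- purrr::imap_dfr(fc, function(f, s) {
    idx <- cbind(eligible$roi_i, eligible$roi_j)
    tibble::tibble(
      roi_i = eligible$roi_i, roi_j = eligible$roi_j,
      subject = as.integer(s),
      corr = f$correlation[idx],
      pcorr = f$partial_correlation[idx])
  })
  dmg_ind <- dplyr::select(damage, "roi_i", "roi_j", "subject",
                           "high_damage")
  roi_resp <- dplyr::left_join(roi_resp, dmg_ind,
                               by = c("roi_i", "roi_j", "subject"))

  glm_corr <- damage_glm(
    dplyr::transmute(roi_resp, .data$roi_i, .data$roi_j,
                     value = transform_fc(.data$corr),
                     damaged = .data$high_damage), alpha)
  glm_pcorr <- damage_glm(
    dplyr::transmute(roi_resp, .data$roi_i, .data$roi_j,
                     value = transform_fc(.data$pcorr, is_partial = TRUE),
                     damaged = .data$high_damage), alpha)

  # streamline-level FC restricted to eligible edges
  sfc <- assemble_sfc(cohort)
  sfc_el <- dplyr::semi_join(sfc, eligible, by = c("roi_i", "roi_j"))
  glm_sfc <- damage_glm(
    dplyr::transmute(sfc_el, .data$roi_i, .data$roi_j,
                     value = transform_fc(.data$r),
                     damaged = .data$disconnected), alpha)

  summary_tbl <- dplyr::bind_rows(
    dplyr::mutate(modulation_summary(glm_corr, cohort$atlas$rois),
                  level = "roi_correlation"),
    dplyr::mutate(modulation_summary(glm_pcorr, cohort$atlas$rois),
                  level = "roi_partial_correlation"),
    dplyr::mutate(modulation_summary(glm_sfc, cohort$atlas$rois),
                  level = "streamline"))

  # communication models on the undamaged template connectome
  sc <- build_connectome(cohort$template, integer(0), cfg$n_rois, mode,
                         cohort$atlas$rois)
  mfpt <- mean_first_passage_time(sc$weights)
  ebc <- edge_betweenness_matrix(sc$weights)
  pred <- standardize_predictors(mfpt, ebc, sc$weights, eligible)
  resp <- dplyr::left_join(
    pred,
    dplyr::select(tibble::as_tibble(glm_sfc), "roi_i", "roi_j",
                  "q_significant"),
    by = c("roi_i", "roi_j"))
  resp$q_significant[is.na(resp$q_significant)] <- FALSE
  comm <- fit_damage_logistic(pred, resp$q_significant)

  results <- list(cohort = cohort, damage = damage, eligible = eligible,
                  cv = cv, fc = fc, sfc = sfc,
                  glm = list(roi_correlation = glm_corr,
                             roi_partial_correlation = glm_pcorr,
                             streamline = glm_sfc),
                  summary = summary_tbl, connectome = sc, comm = comm)
  results$manifest <- write_pipeline_outputs(results, config, out_dir)
  invisible(results)
}

#' Flagged-edge fractions at the three response levels for one cohort
#'
#' Runs the damage analysis of a simulated cohort end to end — per-subject
#' connectomes, median damage stratification, edge eligibility, ROI FC via
#' the adaptive graphical lasso, streamline FC — and returns the fraction of
#' eligible edges whose gamma GLM survives FDR at each response level: ROI
#' correlation, ROI partial correlation, and streamline correlation.
#'
#' @param cohort A `synthetic_cohort`.
#' @param min_subjects Minimum high-damage subjects per eligible edge.
#' @param lambda_sc,lambda_non_sc Adaptive graphical lasso penalties.
#' @param alpha FDR level.
#' @return One-row tibble: `n_eligible`, `frac_corr`, `frac_pcorr`,
#'   `frac_sfc`.
#' @export
modulation_fractions <- function(cohort, min_subjects = 3L,
                                 lambda_sc = 0.125, lambda_non_sc = 0.2,
                                 alpha = 0.05) {
  disconnected <- lapply(cohort$subjects, `[[`, "disconnected_ids")
  w <- subject_edge_weights(cohort$template, disconnected,
                            cohort$config$n_rois)
  damage <- stratify_damage(w)
  elig <- eligible_edges(damage, min_subjects)
  idx <- cbind(elig$roi_i, elig$roi_j)
  fc <- lapply(cohort$subjects, function(s) {
    fit_fc(s$roi_series, cohort$support, lambda_sc, lambda_non_sc)
  })
  roi_resp <- purrr::imap_dfr(fc, function(f, s) {
    tibble::tibble(roi_i = elig$roi_i, roi_j = elig$roi_j,
                   subject = as.integer(s),
                   corr = f$correlation[idx],
                   pcorr = f$partial_correlation[idx])
  })
  roi_resp <- dplyr::left_join(
    roi_resp,
    dplyr::select(damage, "roi_i", "roi_j", "subject", "high_damage"),
    by = c("roi_i", "roi_j", "subject"))
  g_corr <- damage_glm(
    dplyr::transmute(roi_resp, .data$roi_i, .data$roi_j,
                     value = transform_fc(.data$corr),
                     damaged = .data$high_damage), alpha)
  g_pcorr <- damage_glm(
    dplyr::transmute(roi_resp, .data$roi_i, .data$roi_j,
                     value = transform_fc(.data$pcorr, is_partial = TRUE),
                     damaged = .data$high_damage), alpha)
  sfc <- assemble_sfc(cohort)
  sfc_el <- dplyr::semi_join(sfc, elig, by = c("roi_i", "roi_j"))
  g_sfc <- damage_glm(
    dplyr::transmute(sfc_el, .data$roi_i, .data$roi_j,
                     value = transform_fc(.data$r),
                     damaged = .data$disconnected), alpha)
  tibble::tibble(
    n_eligible = nrow(elig),
    frac_corr = mean(g_corr$q_significant),
    frac_pcorr = mean(g_pcorr$q_significant),
    frac_sfc = mean(g_sfc$q_significant))
}

# serialize stage outputs and build the hashed run manifest
write_pipeline_outputs <- function(results, config, out_dir) {
  version <- as.character(utils::packageVersion("lesionfc"))
  if (is.null(out_dir)) {
    return(list(package_version = version, config = config, files = NULL))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  tsv <- function(tbl, path) {
    write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    tsv(dplyr::select(results$damage, -dplyr::any_of("points")),
        p("damage_profile.tsv")),
    tsv(results$eligible, p("eligible_edges.tsv")),
    tsv(tibble::as_tibble(results$sfc), p("sfc_records.tsv")),
    tsv(tibble::as_tibble(results$glm$roi_correlation),
        p("glm_roi_correlation.tsv")),
    tsv(tibble::as_tibble(results$glm$roi_partial_correlation),
        p("glm_roi_partial_correlation.tsv")),
    tsv(tibble::as_tibble(results$glm$streamline), p("glm_streamline.tsv")),
    tsv(results$summary, p("modulation_summary.tsv")),
    write_matrix_tsv(results$connectome$weights, p("sc_weights.tsv")),
    write_matrix_tsv(results$connectome$support, p("sc_support.tsv")))
  jsonlite::write_json(
    list(coefficients = results$comm$coefficients,
         screening = results$comm$screening,
         separation = results$comm$separation),
    p("communication_models.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, p("communication_models.json"))
  if (!is.null(results$cv)) {
    jsonlite::write_json(
      list(curve = results$cv$curve,
           selected_lambda_sc = results$cv$selected_lambda_sc),
      p("cv_result.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, p("cv_result.json"))
  }
  manifest <- list(
    package_version = version,
    config = config,
    seed = results$cohort$config$rng_seed,
    files = lapply(setNames(nm = basename(files)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}
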