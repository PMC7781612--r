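#' Configuration for a synthetic lesion cohort
#'
#' Collects and validates every parameter of the synthetic study. Defaults
#' mirror the study conditions the pipeline is designed for: 20 subjects,
#' 172 usable BOLD volumes (180 acquired minus 8 discarded), a homologue-
#' paired parcellation, heterogeneous spherical lesions restricted to the
#' left hemisphere, and a planted Gaussian graphical model whose precision
#' support equals the structural connectome support.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param n_rois Even number of ROIs (default 20; up to 114).
#' @param n_timepoints BOLD samples per subject (default 172).
#' @param streamlines_per_edge Integer range of streamlines per SC edge.
#' @param lesion_radius_mm Range of lesion radii in mm.
#' @param coupling_attenuation Fractional reduction, in `[0, 1]`, of the
#'   planted coupling on damaged edges and disconnected streamlines;
#'   0 plants no effect (null cohort).
#' @param voxel_noise_sd Standard deviation of independent voxel noise.
#' @param streamline_coupling Weight of the shared component injected at the
#'   two endpoint voxels of each streamline.
#' @param precision_coupling Magnitude `c` of off-diagonal ground-truth
#'   precision entries on SC edges.
#' @param edge_density Probability a candidate SC edge exists.
#' @param grid_shape Voxel grid, or `NULL` for [default_grid()].
#' @param rng_seed Integer seed fixing all random draws end-to-end.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20L, n_rois = 20L,
                          n_timepoints = 172L,
                          streamlines_per_edge = c(2L, 5L),
                          lesion_radius_mm = c(5, 18),
                          coupling_attenuation = 0.8,
                          voxel_noise_sd = 0.4,
                          streamline_coupling = 0.6,
                          precision_coupling = 0.3,
                          edge_density = 0.35,
                          grid_shape = NULL,
                          rng_seed = 1L) {
  for (nm in c("n_subjects", "n_rois", "n_timepoints")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  stopifnot_scalar_number(voxel_noise_sd, "voxel_noise_sd")
  if (voxel_noise_sd < 0) stop("`voxel_noise_sd` must be >= 0", call. = FALSE)
  stopifnot_scalar_number(coupling_attenuation, "coupling_attenuation")
  if (coupling_attenuation < 0 || coupling_attenuation > 1) {
    stop("`coupling_attenuation` must be in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar_number(precision_coupling, "precision_coupling",
                          positive = TRUE)
  if (any(range(streamlines_per_edge) < 1)) {
    stop("`streamlines_per_edge` must be >= 1", call. = FALSE)
  }
  if (any(range(lesion_radius_mm) <= 0)) {
    stop("`lesion_radius_mm` must be positive", call. = FALSE)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    n_timepoints = as.integer(n_timepoints),
    streamlines_per_edge = as.integer(range(streamlines_per_edge)),
    lesion_radius_mm = range(lesion_radius_mm),
    coupling_attenuation = coupling_attenuation,
    voxel_noise_sd = voxel_noise_sd,
    streamline_coupling = streamline_coupling,
    precision_coupling = precision_coupling,
    edge_density = edge_density,
    grid_shape = if (is.null(grid_shape)) default_grid(n_rois)
                 else as.integer(grid_shape),
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Ground-truth precision on a structural support
#'
#' Off-diagonal entries are `-c` on support edges, scaled down by
#' `attenuation * damage_fraction` on damaged edges; the diagonal is the
#' absolute row sum of the off-diagonals plus one, so the matrix is strictly
#' diagonally dominant and hence positive definite.
#'
#' @param support Symmetric binary matrix (zero diagonal) of SC edges.
#' @param coupling Coupling magnitude `c` (default 0.3).
#' @param damage_fraction Symmetric matrix in `[0, 1]`: per-edge fraction of
#'   streamlines disconnected (0 = intact).
#' @param attenuation Fractional coupling reduction on damaged edges.
#' @return A symmetric positive-definite precision matrix.
#' @export
planted_precision <- function(support, coupling = 0.3,
                              damage_fraction = NULL, attenuation = 0) {
  check_symmetric(support, "support")
  p <- nrow(support)
  if (is.null(damage_fraction)) damage_fraction <- matrix(0, p, p)
  phi <- -coupling * (support != 0) * (1 - attenuation * damage_fraction)
  diag(phi) <- 0
  diag(phi) <- rowSums(abs(phi)) + 1
  if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("internal error: constructed precision is not positive definite",
         call. = FALSE)
  }
  phi
}

#' Draw multivariate-Gaussian ROI time series from a precision matrix
#'
#' Rows are i.i.d. zero-mean draws whose covariance is the inverse of
#' `precision`.
#'
#' @param precision Symmetric positive-definite ROI x ROI matrix.
#' @param n_timepoints Number of samples (rows).
#' @return `n_timepoints` x ROI matrix.
#' @export
simulate_bold <- function(precision, n_timepoints) {
  check_symmetric(precision, "precision")
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("internal error: precision must be positive definite", call. = FALSE)
  }
  sigma <- solve(precision)
  sigma <- (sigma + t(sigma)) / 2
  p <- nrow(sigma)
  z <- matrix(rnorm(n_timepoints * p), n_timepoints, p)
  z %*% chol(sigma)
}

# endpoint voxel bookkeeping for a template: per streamline, the two voxel
# keys and their ROIs
template_endpoints <- function(template, spacing) {
  purrr::pmap_dfr(
    list(template$id, template$roi_a, template$roi_b, template$points),
    function(id, a, b, pts) {
      va <- mm_to_vox(pts[1, ], spacing)
      vb <- mm_to_vox(pts[nrow(pts), ], spacing)
      tibble::tibble(id = id,
                     key_a = voxel_key(va), key_b = voxel_key(vb),
                     roi_a = a, roi_b = b)
    })
}

#' Simulate a complete synthetic lesion cohort
#'
#' Generates, under a single seed: a homologue-paired block atlas, a
#' streamline template, one spherical left-hemisphere lesion per subject,
#' the per-subject set of disconnected streamlines, a per-subject
#' ground-truth precision (coupling attenuated on damaged edges), ROI BOLD
#' series drawn from that precision, and endpoint-voxel series equal to the
#' ROI signal plus a shared per-streamline component (attenuated when the
#' streamline is disconnected) plus independent noise.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with `config`,
#'   `atlas`, `template`, `support` (template SC support matrix) and
#'   `subjects`, a list with per-subject `lesion_mask`, `lesion_center`,
#'   `lesion_radius`, `disconnected_ids`, `true_precision`, `roi_series`
#'   (time x ROI) and `voxel_series` (time x endpoint-voxel, columns named by
#'   voxel key).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$rng_seed)
  atlas <- make_atlas(config$n_rois, config$grid_shape)
  template <- make_streamline_template(
    atlas, config$streamlines_per_edge, config$edge_density)
  support <- template_support(template, config$n_rois)
  endp <- template_endpoints(template, atlas$spacing)
  bounds <- hemisphere_bounds(atlas, "L")

  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    center <- c(runif(1, bounds[1, 1], bounds[1, 2]),
                runif(1, bounds[2, 1], bounds[2, 2]),
                runif(1, bounds[3, 1], bounds[3, 2]))
    radius <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
    lesion <- make_lesion(atlas, center, radius)
    disc <- intersect_lesion(template, lesion, spacing = atlas$spacing)

    # per-edge fraction of disconnected streamlines
    frac <- matrix(0, config$n_rois, config$n_rois)
    per_edge <- template |>
      tibble::as_tibble() |>
      dplyr::mutate(disc = .data$id %in% disc) |>
      dplyr::count(.data$roi_a, .data$roi_b, wt = .data$disc,
                   name = "n_disc") |>
      dplyr::left_join(
        dplyr::count(tibble::as_tibble(template), .data$roi_a, .data$roi_b),
        by = c("roi_a", "roi_b"))
    for (r in seq_len(nrow(per_edge))) {
      f <- per_edge$n_disc[r] / per_edge$n[r]
      frac[per_edge$roi_a[r], per_edge$roi_b[r]] <- f
      frac[per_edge$roi_b[r], per_edge$roi_a[r]] <- f
    }

    phi <- planted_precision(support, config$precision_coupling, frac,
                             config$coupling_attenuation)
    roi_series <- simulate_bold(phi, config$n_timepoints)

    # endpoint-voxel series: ROI signal + shared streamline component + noise
    keys <- unique(c(endp$key_a, endp$key_b))
    voxel_roi <- setNames(integer(length(keys)), keys)
    voxel_roi[endp$key_a] <- endp$roi_a
    voxel_roi[endp$key_b] <- endp$roi_b
    vox <- roi_series[, voxel_roi[keys], drop = FALSE] +
      matrix(rnorm(config$n_timepoints * length(keys),
                   sd = config$voxel_noise_sd),
             config$n_timepoints, length(keys))
    colnames(vox) <- keys
    for (r in seq_len(nrow(endp))) {
      w <- config$streamline_coupling
      if (endp$id[r] %in% disc) w <- w * (1 - config$coupling_attenuation)
      eta <- rnorm(config$n_timepoints)
      vox[, endp$key_a[r]] <- vox[, endp$key_a[r]] + w * eta
      vox[, endp$key_b[r]] <- vox[, endp$key_b[r]] + w * eta
    }

    subjects[[s]] <- list(
      lesion_mask = lesion, lesion_center = center, lesion_radius = radius,
      disconnected_ids = disc, true_precision = phi,
      roi_series = roi_series, voxel_series = vox)
  }
  structure(
    list(config = config, atlas = atlas, template = template,
         support = support, endpoints = endp, subjects = subjects),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d ROIs, %d streamlines, %d timepoints\n",
    length(x$subjects), x$config$n_rois, nrow(x$template),
    x$config$n_timepoints))
  invisible(x)
}
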