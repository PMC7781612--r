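#' Identify streamlines disconnected by a lesion mask
#'
#' A streamline is disconnected if at least one of its 100 points falls in a
#' lesion voxel; points are mapped to voxels by nearest-voxel rounding of the
#' mm coordinates on the mask's isotropic grid.
#'
#' @param template A `streamline_template`.
#' @param lesion Logical/binary 3D array, same grid as the template space.
#' @param spacing Voxel size in mm (default: the template's spacing).
#' @return Integer vector of disconnected streamline ids.
#' @export
intersect_lesion <- function(template, lesion,
                             spacing = attr(template, "spacing") %||% 3) {
  d <- dim(lesion)
  if (length(d) != 3L) {
    stop("space mismatch: `lesion` must be a 3D volume", call. = FALSE)
  }
  hit <- vapply(template$points, function(pts) {
    v <- matrix(mm_to_vox(pts, spacing), ncol = 3)
    inside <- v[, 1] >= 1 & v[, 1] <= d[1] &
      v[, 2] >= 1 & v[, 2] <= d[2] &
      v[, 3] >= 1 & v[, 3] <= d[3]
    if (!any(inside)) return(FALSE)
    any(lesion[v[inside, , drop = FALSE]] != 0)
  }, logical(1))
  template$id[hit]
}

# binary ROI x ROI support implied by a streamline template
template_support <- function(template, n_rois) {
  support <- matrix(0, n_rois, n_rois)
  support[cbind(template$roi_a, template$roi_b)] <- 1
  support[cbind(template$roi_b, template$roi_a)] <- 1
  diag(support) <- 0
  support
}

#' Build a structural connectome from connected streamlines
#'
#' Aggregates the streamlines that survive lesion removal into a symmetric
#' ROI x ROI weight matrix W. Under the default `length_inverse` mode each
#' streamline contributes the reciprocal of its length, `W_ij = sum_s 1/l_s`,
#' de-biasing the count toward long streamlines; `raw_count` uses the plain
#' streamline count, and `roi_size_normalized` divides the count by the
#' product of the two ROI sizes in voxels.
#'
#' @param template A `streamline_template`.
#' @param disconnected_ids Integer ids of streamlines removed by the lesion.
#' @param n_rois Number of ROIs (defaults to the template's max label).
#' @param mode Normalization mode.
#' @param roi_table ROI tibble with `roi` and `n_voxels` (required for
#'   `roi_size_normalized`).
#' @return Object of class `structural_connectome`: list with `weights`,
#'   `support` (binarized weights), `mode`, `n_rois`.
#' @export
#' @examples
#' atlas <- make_atlas(4)
#' tpl <- make_streamline_template(atlas, c(2, 2))
#' sc <- build_connectome(tpl, integer(0), nrow(atlas$rois))
build_connectome <- function(template, disconnected_ids = integer(0),
                             n_rois = max(template$roi_b),
                             mode = c("length_inverse", "raw_count",
                                      "roi_size_normalized"),
                             roi_table = NULL) {
  mode <- match.arg(mode)
  bad <- setdiff(disconnected_ids, template$id)
  if (length(bad) > 0) {
    stop("`disconnected_ids` contains ids not present in the template",
         call. = FALSE)
  }
  alive <- !(template$id %in% disconnected_ids)
  w <- matrix(0, n_rois, n_rois)
  contrib <- switch(mode,
    length_inverse = 1 / template$length_mm,
    raw_count = rep(1, nrow(template)),
    roi_size_normalized = rep(1, nrow(template)))
  for (r in which(alive)) {
    i <- template$roi_a[r]
    j <- template$roi_b[r]
    w[i, j] <- w[i, j] + contrib[r]
    w[j, i] <- w[i, j]
  }
  if (mode == "roi_size_normalized") {
    if (is.null(roi_table)) {
      stop("`roi_table` with voxel counts is required for ",
           "`roi_size_normalized`", call. = FALSE)
    }
    sz <- setNames(roi_table$n_voxels, roi_table$roi)
    norm <- outer(sz[as.character(seq_len(n_rois))],
                  sz[as.character(seq_len(n_rois))])
    w <- w / norm
  }
  diag(w) <- 0
  structure(list(weights = w, support = (w > 0) * 1, mode = mode,
                 n_rois = n_rois),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("<structural_connectome> %d ROIs, %d edges, mode = %s\n",
              x$n_rois, sum(x$support[upper.tri(x$support)] > 0), x$mode))
  invisible(x)
}

#' Per-subject edge weights for a cohort of lesioned connectomes
#'
#' @param template A `streamline_template`.
#' @param disconnected List (one element per subject) of disconnected ids.
#' @inheritParams build_connectome
#' @return A tibble in long form: `roi_i`, `roi_j`, `subject`, `weight`,
#'   restricted to template support edges.
#' @export
subject_edge_weights <- function(template, disconnected,
                                 n_rois = max(template$roi_b),
                                 mode = "length_inverse", roi_table = NULL) {
  edges <- dplyr::distinct(tibble::as_tibble(template),
                           roi_i = pmin(.data$roi_a, .data$roi_b),
                           roi_j = pmax(.data$roi_a, .data$roi_b))
  purrr::imap_dfr(disconnected, function(ids, s) {
    sc <- build_connectome(template, ids, n_rois, mode, roi_table)
    dplyr::mutate(edges,
                  subject = as.integer(s),
                  weight = sc$weights[cbind(.data$roi_i, .data$roi_j)])
  })
}

#' Stratify per-edge damage across subjects
#'
#' For every edge the across-subject median connection strength is computed;
#' a subject is flagged as high damage on that edge when their weight is
#' strictly less than the median (ties at the median count as low damage).
#'
#' @param weights Long tibble with columns `roi_i`, `roi_j`, `subject`,
#'   `weight` (one row per edge x subject).
#' @return The input tibble with `edge_median` and logical `high_damage`
#'   columns added.
#' @export
#' @examples
#' w <- tibble::tibble(roi_i = 1, roi_j = 2, subject = 1:5, weight = 1:5)
#' stratify_damage(w)
stratify_damage <- function(weights) {
  if (dplyr::n_distinct(weights$subject) < 2) {
    stop("damage stratification needs at least two subjects", call. = FALSE)
  }
  weights |>
    dplyr::group_by(.data$roi_i, .data$roi_j) |>
    dplyr::mutate(edge_median = median(.data$weight),
                  high_damage = .data$weight < .data$edge_median) |>
    dplyr::ungroup()
}

#' Edges with at least a minimum number of high-damage subjects
#'
#' @param damage Output of [stratify_damage()].
#' @param min_subjects Minimum count of high-damage subjects (>= 1).
#' @return Tibble of eligible edges: `roi_i`, `roi_j`, `n_high_damage`.
#' @export
eligible_edges <- function(damage, min_subjects = 3L) {
  if (min_subjects < 1) stop("`min_subjects` must be >= 1", call. = FALSE)
  damage |>
    dplyr::group_by(.data$roi_i, .data$roi_j) |>
    dplyr::summarise(n_high_damage = sum(.data$high_damage),
                     .groups = "drop") |>
    dplyr::filter(.data$n_high_damage >= min_subjects)
}

#' Streamline-level damage indicators across subjects
#'
#' @param template A `streamline_template`.
#' @param disconnected List of per-subject disconnected id vectors.
#' @return Long tibble: `id`, `roi_i`, `roi_j`, `subject`, `disconnected`.
#' @export
streamline_damage <- function(template, disconnected) {
  base <- tibble::tibble(
    id = template$id,
    roi_i = pmin(template$roi_a, template$roi_b),
    roi_j = pmax(template$roi_a, template$roi_b))
  purrr::imap_dfr(disconnected, function(ids, s) {
    dplyr::mutate(base, subject = as.integer(s),
                  disconnected = .data$id %in% ids)
  })
}
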