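#' Map streamline endpoints to brain-mask voxels
#'
#' The first and last point of the streamline are mapped to voxel indices by
#' nearest-voxel rounding; the pair is rejected (not an error) when either
#' voxel falls outside the volume or outside the brain mask, since no BOLD
#' signal exists there.
#'
#' @param points 100 x 3 matrix of streamline points (mm).
#' @param brain_mask Logical/binary 3D array.
#' @param spacing Voxel size (mm).
#' @return List with `accepted` (logical), `voxel_a`, `voxel_b` (integer
#'   3-vectors or NULL) and `reason` (`NA` when accepted).
#' @export
endpoints_to_voxels <- function(points, brain_mask, spacing = 3) {
  d <- dim(brain_mask)
  va <- mm_to_vox(points[1, ], spacing)
  vb <- mm_to_vox(points[nrow(points), ], spacing)
  check <- function(v) {
    if (any(v < 1L) || any(v > d)) return("outside_volume")
    if (brain_mask[v[1], v[2], v[3]] == 0) return("outside_mask")
    NA_character_
  }
  ra <- check(va)
  rb <- check(vb)
  reason <- if (!is.na(ra)) ra else rb
  if (!is.na(reason)) {
    list(accepted = FALSE, voxel_a = NULL, voxel_b = NULL, reason = reason)
  } else {
    list(accepted = TRUE, voxel_a = va, voxel_b = vb, reason = NA_character_)
  }
}

#' Pearson correlation between two endpoint-voxel time series
#'
#' @param series_a,series_b Equal-length numeric vectors (>= 3 samples),
#'   both non-constant.
#' @return Pearson correlation coefficient.
#' @export
streamline_correlation <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 3) {
    stop("series must have equal length of at least 3", call. = FALSE)
  }
  if (sd(series_a) == 0 || sd(series_b) == 0) {
    stop("undefined correlation: constant series", call. = FALSE)
  }
  cor(series_a, series_b)
}

#' Assemble the streamline functional connectivity (sFC) table
#'
#' For every (streamline, subject) pair, correlates the BOLD series at the
#' streamline's two endpoint voxels. Pairs are rejected when an endpoint
#' falls outside the brain mask; pairs whose endpoints round to the same
#' voxel are flagged degenerate and excluded (their correlation is
#' identically 1); exact duplicate voxel pairs within an edge and subject
#' are deduplicated so each unique termination-point pair contributes once.
#'
#' @param cohort A `synthetic_cohort`.
#' @param brain_mask Optional logical 3D array (default: atlas labels > 0).
#' @return Tibble of class `sfc_tbl` with columns `id`, `subject`, `roi_i`,
#'   `roi_j`, `r`, `disconnected`; attribute `rejections` holds a tibble of
#'   rejected/deduplicated records with reasons, and
#'   `accepted + rejected = streamlines x subjects`.
#' @export
assemble_sfc <- function(cohort, brain_mask = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  atlas <- cohort$atlas
  if (is.null(brain_mask)) brain_mask <- (atlas$labels > 0) * 1
  template <- cohort$template
  n_sub <- length(cohort$subjects)

  ep <- lapply(template$points, endpoints_to_voxels,
               brain_mask = brain_mask, spacing = atlas$spacing)
  acc <- vapply(ep, `[[`, logical(1), "accepted")
  key_a <- vapply(ep, function(e) {
    if (e$accepted) voxel_key(e$voxel_a) else NA_character_
  }, character(1))
  key_b <- vapply(ep, function(e) {
    if (e$accepted) voxel_key(e$voxel_b) else NA_character_
  }, character(1))
  base <- tibble::tibble(
    id = template$id,
    roi_i = pmin(template$roi_a, template$roi_b),
    roi_j = pmax(template$roi_a, template$roi_b),
    accepted = acc,
    reason = vapply(ep, `[[`, character(1), "reason"),
    key_a = key_a, key_b = key_b)
  base$reason[base$accepted & base$key_a == base$key_b] <- "same_voxel"
  base$accepted <- base$accepted & is.na(base$reason)

  records <- vector("list", n_sub)
  rejects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sub <- cohort$subjects[[s]]
    b <- dplyr::mutate(base, subject = s)
    ok <- b[b$accepted, , drop = FALSE]
    # unique termination-point pairs per edge and subject
    pair_key <- paste(ok$roi_i, ok$roi_j,
                      pmin(ok$key_a, ok$key_b), pmax(ok$key_a, ok$key_b))
    dup <- duplicated(pair_key)
    dup_rows <- ok[dup, , drop = FALSE]
    dup_rows$reason <- "duplicate_voxel_pair"
    ok <- ok[!dup, , drop = FALSE]
    missing <- setdiff(c(ok$key_a, ok$key_b), colnames(sub$voxel_series))
    if (length(missing) > 0) {
      stop("data integrity: no voxel series for accepted endpoint voxel(s) ",
           paste(head(missing, 3), collapse = ", "), call. = FALSE)
    }
    a <- sub$voxel_series[, ok$key_a, drop = FALSE]
    bb <- sub$voxel_series[, ok$key_b, drop = FALSE]
    az <- scale(a)
    bz <- scale(bb)
    ok$r <- unname(colSums(az * bz) / (nrow(a) - 1))
    ok$disconnected <- ok$id %in% sub$disconnected_ids
    records[[s]] <- dplyr::select(ok, "id", "subject", "roi_i", "roi_j",
                                  "r", "disconnected")
    rej <- dplyr::bind_rows(b[!b$accepted, , drop = FALSE], dup_rows)
    rejects[[s]] <- dplyr::select(rej, "id", "subject", "roi_i", "roi_j",
                                  "reason")
  }
  out <- dplyr::bind_rows(records)
  attr(out, "rejections") <- dplyr::bind_rows(rejects)
  class(out) <- c("sfc_tbl", class(out))
  out
}
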