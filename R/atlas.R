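#' Build a block-design cortical parcellation on a voxel grid
#'
#' Constructs a toy two-hemisphere parcellation: the grid is split at the
#' midline plane into a left (low x) and right (high x) hemisphere, and each
#' hemisphere is tiled with `n_rois / 2` equal rectangular voxel blocks. Right
#' ROIs are exact mirror images of their left homologues, so every ROI carries
#' a homologue id, emulating a homologue-paired cortical parcellation.
#'
#' @param n_rois Even integer >= 2; total number of ROIs across both
#'   hemispheres.
#' @param grid_shape Integer 3-vector of voxel grid dimensions. The x extent
#'   must be even (it is split at the midline). Defaults to a grid just large
#'   enough to hold the requested ROIs as 6-voxel blocks.
#' @param spacing Isotropic voxel size in mm (default 3).
#'
#' @return An object of class `brain_atlas`: a list with `labels` (3D integer
#'   array, 0 = background), `spacing`, `affine` (4x4 voxel-to-mm, 0-based
#'   voxel indices) and `rois`, a tibble with one row per ROI
#'   (`roi`, `hemisphere`, `homologue`, `n_voxels`, `x_mm`, `y_mm`, `z_mm`).
#' @export
#' @examples
#' atlas <- make_atlas(4, c(10, 10, 10))
#' atlas$rois
make_atlas <- function(n_rois, grid_shape = default_grid(n_rois), spacing = 3) {
  if (!is.numeric(n_rois) || length(n_rois) != 1L || n_rois < 2) {
    stop("`n_rois` must be an integer >= 2 (homologue pairs are required)",
         call. = FALSE)
  }
  n_rois <- as.integer(n_rois)
  if (n_rois %% 2L != 0L) {
    stop("`n_rois` must be even: every ROI needs a contralateral homologue",
         call. = FALSE)
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("`grid_shape` must be three positive integers", call. = FALSE)
  }
  if (grid_shape[1] %% 2L != 0L) {
    stop("`grid_shape[1]` must be even so the midline splits the grid",
         call. = FALSE)
  }
  k <- n_rois %/% 2L           # ROIs per hemisphere
  gy <- as.integer(ceiling(sqrt(k)))
  gz <- as.integer(ceiling(k / gy))
  by <- grid_shape[2] %/% gy
  bz <- grid_shape[3] %/% gz
  hx <- grid_shape[1] %/% 2L
  if (hx < 1L || by < 1L || bz < 1L) {
    stop(sprintf(
      paste0("grid too small for %d ROIs: need at least ",
             "%d x %d x %d voxels"),
      n_rois, 2L, gy, gz), call. = FALSE)
  }

  labels <- array(0L, dim = grid_shape)
  rois <- vector("list", n_rois)
  for (b in seq_len(k)) {
    iy <- (b - 1L) %% gy
    iz <- (b - 1L) %/% gy
    ys <- iy * by + seq_len(by)
    zs <- iz * bz + seq_len(bz)
    # left hemisphere: x voxels 1..hx; right: mirrored
    labels[seq_len(hx), ys, zs] <- b
    labels[grid_shape[1] + 1L - seq_len(hx), ys, zs] <- b + k
    rois[[b]] <- list(roi = b, hemisphere = "L", homologue = b + k)
    rois[[b + k]] <- list(roi = b + k, hemisphere = "R", homologue = b)
  }

  roi_tbl <- dplyr::bind_rows(lapply(rois, tibble::as_tibble))
  cen <- t(vapply(roi_tbl$roi, function(r) {
    v <- which(labels == r, arr.ind = TRUE)
    colMeans(vox_to_mm(v, spacing))
  }, numeric(3)))
  roi_tbl$n_voxels <- vapply(roi_tbl$roi,
                             function(r) sum(labels == r), numeric(1))
  roi_tbl$x_mm <- cen[, 1]
  roi_tbl$y_mm <- cen[, 2]
  roi_tbl$z_mm <- cen[, 3]

  affine <- diag(c(spacing, spacing, spacing, 1))
  structure(
    list(labels = labels, spacing = spacing, affine = affine, rois = roi_tbl),
    class = "brain_atlas")
}

#' @rdname make_atlas
#' @export
default_grid <- function(n_rois, block = 6L) {
  k <- max(1L, as.integer(ceiling(n_rois / 2)))
  gy <- as.integer(ceiling(sqrt(k)))
  gz <- as.integer(ceiling(k / gy))
  c(2L * block, gy * block, gz * block)
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas> %d ROIs on a %s voxel grid (%g mm isotropic)\n",
              nrow(x$rois), paste(dim(x$labels), collapse = "x"), x$spacing))
  invisible(x)
}

# mm bounding box of one hemisphere ("L" keeps x below the midline)
hemisphere_bounds <- function(atlas, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  d <- dim(atlas$labels)
  hx <- d[1] %/% 2L
  xr <- if (hemisphere == "L") c(1L, hx) else c(hx + 1L, d[1])
  rbind(x = vox_to_mm(xr, atlas$spacing),
        y = vox_to_mm(c(1L, d[2]), atlas$spacing),
        z = vox_to_mm(c(1L, d[3]), atlas$spacing))
}

#' Carve a spherical lesion mask into an atlas grid
#'
#' Marks all voxels whose centres fall within `radius_mm` of `center_mm`,
#' truncated at the midline plane so the lesion stays within the hemisphere
#' containing its centre (lesions are analyzed on one side of the brain).
#' The voxel nearest the centre is always included, so a radius smaller than
#' half a voxel yields a single-voxel mask.
#'
#' @param atlas A `brain_atlas`.
#' @param center_mm Numeric 3-vector, lesion centre in mm; must lie inside the
#'   volume.
#' @param radius_mm Positive lesion radius in mm.
#' @return A logical 3D array of the same shape as `atlas$labels`.
#' @export
make_lesion <- function(atlas, center_mm, radius_mm) {
  stopifnot_scalar_number(radius_mm, "radius_mm", positive = TRUE)
  d <- dim(atlas$labels)
  sp <- atlas$spacing
  cv <- mm_to_vox(center_mm, sp)
  if (any(cv < 1L) || any(cv > d)) {
    stop("lesion centre lies outside the volume bounds", call. = FALSE)
  }
  ax <- vox_to_mm(seq_len(d[1]), sp)
  ay <- vox_to_mm(seq_len(d[2]), sp)
  az <- vox_to_mm(seq_len(d[3]), sp)
  dx2 <- (ax - center_mm[1])^2
  dy2 <- (ay - center_mm[2])^2
  dz2 <- (az - center_mm[3])^2
  mask <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_mm^2
  mask[cv[1], cv[2], cv[3]] <- TRUE
  # confine to the hemisphere holding the centre
  hx <- d[1] %/% 2L
  if (cv[1] <= hx) {
    if (hx < d[1]) mask[(hx + 1L):d[1], , ] <- FALSE
  } else {
    mask[seq_len(hx), , ] <- FALSE
  }
  mask
}
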