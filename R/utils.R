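# internal helpers shared across modules

# canonical unordered edge key "i-j" with i < j
edge_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "-")
}

# split "i-j" keys back into a two-column integer matrix
edge_key_split <- function(key) {
  parts <- strsplit(key, "-", fixed = TRUE)
  cbind(
    roi_i = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
    roi_j = vapply(parts, function(p) as.integer(p[[2]]), integer(1))
  )
}

# mm coordinate of the centre of (1-based) voxel v on an isotropic grid
vox_to_mm <- function(v, spacing = 3) (v - 1) * spacing

# nearest (1-based) voxel index for an mm coordinate
mm_to_vox <- function(mm, spacing = 3) as.integer(round(mm / spacing)) + 1L

# voxel index triple -> string key used to address voxel time series
voxel_key <- function(v) paste(v[1], v[2], v[3], sep = "_")

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  invisible(m)
}

# polyline arc length (rows = ordered points, columns = x/y/z)
polyline_length <- function(points) {
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

upper_edges <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  tibble::tibble(roi_i = idx[, 1], roi_j = idx[, 2])
}
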