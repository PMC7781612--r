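#' Resample a polyline to a 100-point cubic spline
#'
#' Fits a natural cubic spline to each coordinate against the normalized
#' cumulative chord length (an arc-length parameterization) and evaluates it
#' at 100 uniformly spaced parameter values. The first and last output points
#' equal the input endpoints exactly.
#'
#' @param points Numeric matrix, rows = ordered 3D points (mm).
#' @param n_points Number of output points (default 100).
#' @return A `n_points` x 3 matrix.
#' @export
#' @examples
#' seg <- rbind(c(0, 0, 0), c(99, 0, 0))
#' out <- resample_streamline(seg)
#' head(diff(out[, 1]))  # 1 mm spacing
resample_streamline <- function(points, n_points = 100L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 3L) {
    stop("`points` must be a matrix of at least two 3D points", call. = FALSE)
  }
  # drop consecutive duplicates (zero-length chords break the parameterization)
  seg <- sqrt(rowSums(diff(points)^2))
  keep <- c(TRUE, seg > 0)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L) {
    stop("degenerate streamline: all input points are identical",
         call. = FALSE)
  }
  tt <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  tt <- tt / tt[length(tt)]
  tout <- seq(0, 1, length.out = n_points)
  out <- vapply(1:3, function(k) {
    stats::spline(tt, points[, k], xout = tout, method = "natural")$y
  }, numeric(n_points))
  # interpolation guarantees this, but pin endpoints against rounding
  out[1, ] <- points[1, ]
  out[n_points, ] <- points[nrow(points), ]
  out
}

# sample one raw streamline trajectory between two endpoint mm coordinates:
# linear backbone with jittered interior control points, then spline-resampled
raw_trajectory <- function(p0, p1, curve_sd) {
  n_ctrl <- 3L
  w <- seq_len(n_ctrl) / (n_ctrl + 1L)
  mid <- outer(1 - w, p0) + outer(w, p1)
  mid <- mid + matrix(rnorm(3L * n_ctrl, sd = curve_sd), n_ctrl, 3L)
  rbind(p0, mid, p1)
}

#' Generate a template of streamlines connecting atlas ROIs
#'
#' Draws a sparse set of structural edges (all edges within a hemisphere are
#' candidates; interhemispheric edges are restricted to homologous ROI pairs)
#' and, per edge, a configurable number of 100-point streamlines whose
#' endpoints lie inside the two connected ROIs. A within-hemisphere chain plus
#' one homologous edge is always present so the resulting connectome graph is
#' connected.
#'
#' @param atlas A `brain_atlas`.
#' @param streamlines_per_edge Integer range (length-1 or -2 vector) of
#'   streamline counts per edge.
#' @param edge_density Probability that a candidate non-backbone edge is
#'   included (default 0.35).
#' @param curve_sd Spatial jitter (mm) of interior control points.
#' @return An object of class `streamline_template`: a tibble with columns
#'   `id`, `roi_a`, `roi_b`, `interhemispheric`, `length_mm` and a `points`
#'   list-column of 100 x 3 matrices. The atlas spacing is kept as an
#'   attribute.
#' @export
make_streamline_template <- function(atlas, streamlines_per_edge = c(2L, 5L),
                                     edge_density = 0.35, curve_sd = 3) {
  rng <- range(as.integer(streamlines_per_edge))
  if (rng[1] < 1L) {
    stop("`streamlines_per_edge` must be a positive integer range",
         call. = FALSE)
  }
  if (edge_density < 0 || edge_density > 1) {
    stop("`edge_density` must be in [0, 1]", call. = FALSE)
  }
  rois <- atlas$rois
  n <- nrow(rois)
  k <- n %/% 2L

  # candidate edges: within-hemisphere pairs + homologous pairs only
  cand <- dplyr::filter(
    tidyr::crossing(roi_a = rois$roi, roi_b = rois$roi),
    .data$roi_a < .data$roi_b)
  hemi <- setNames(rois$hemisphere, rois$roi)
  hom <- setNames(rois$homologue, rois$roi)
  cand <- dplyr::filter(
    cand,
    hemi[as.character(.data$roi_a)] == hemi[as.character(.data$roi_b)] |
      hom[as.character(.data$roi_a)] == .data$roi_b)

  backbone <- c(
    if (k > 1L) paste(seq_len(k - 1L), 2:k, sep = "-"),
    if (k > 1L) paste(k + seq_len(k - 1L), k + 2:k, sep = "-"),
    paste(1L, k + 1L, sep = "-"))
  key <- edge_key(cand$roi_a, cand$roi_b)
  keep <- key %in% backbone | runif(nrow(cand)) < edge_density
  edges <- cand[keep, , drop = FALSE]
  edges$n_streamlines <- if (rng[1] == rng[2]) {
    rep(rng[1], nrow(edges))
  } else {
    sample(rng[1]:rng[2], nrow(edges), replace = TRUE)
  }

  roi_voxels <- lapply(rois$roi, function(r) {
    which(atlas$labels == r, arr.ind = TRUE)
  })
  sp <- atlas$spacing

  rows <- vector("list", sum(edges$n_streamlines))
  id <- 0L
  for (e in seq_len(nrow(edges))) {
    a <- edges$roi_a[e]
    b <- edges$roi_b[e]
    for (s in seq_len(edges$n_streamlines[e])) {
      id <- id + 1L
      va <- roi_voxels[[a]][sample(nrow(roi_voxels[[a]]), 1L), ]
      vb <- roi_voxels[[b]][sample(nrow(roi_voxels[[b]]), 1L), ]
      # jitter endpoints within their voxel so nearest-voxel rounding is stable
      p0 <- vox_to_mm(va, sp) + runif(3, -0.3, 0.3) * sp
      p1 <- vox_to_mm(vb, sp) + runif(3, -0.3, 0.3) * sp
      pts <- resample_streamline(raw_trajectory(p0, p1, curve_sd))
      rows[[id]] <- tibble::tibble(
        id = id, roi_a = a, roi_b = b,
        interhemispheric = hemi[as.character(a)] != hemi[as.character(b)],
        length_mm = polyline_length(pts),
        points = list(pts))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "spacing") <- sp
  class(out) <- c("streamline_template", class(out))
  out
}

#' Write / read a streamline template as a plain-text TSV of polylines
#'
#' One row per streamline point: `id`, `roi_a`, `roi_b`, `point` (1..100),
#' `x`, `y`, `z` in mm.
#'
#' @param template A `streamline_template`.
#' @param path File path.
#' @param spacing Voxel spacing (mm) restored onto the template on read.
#' @return `read_streamlines_tsv()` returns a `streamline_template`.
#' @export
write_streamlines_tsv <- function(template, path) {
  long <- purrr::map2_dfr(template$id, template$points, function(id, pts) {
    tibble::tibble(id = id, point = seq_len(nrow(pts)),
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
  long <- dplyr::left_join(
    long,
    dplyr::select(tibble::as_tibble(template), "id", "roi_a", "roi_b"),
    by = "id")
  long <- as.data.frame(
    dplyr::select(long, "id", "roi_a", "roi_b", "point", "x", "y", "z"))
  for (col in c("x", "y", "z")) long[[col]] <- sprintf("%.15g", long[[col]])
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_streamlines_tsv
#' @export
read_streamlines_tsv <- function(path, spacing = 3) {
  long <- read.delim(path, sep = "\t")
  out <- long |>
    dplyr::group_by(.data$id, .data$roi_a, .data$roi_b) |>
    dplyr::arrange(.data$point, .by_group = TRUE) |>
    dplyr::summarise(
      points = list(cbind(.data$x, .data$y, .data$z)), .groups = "drop") |>
    dplyr::mutate(length_mm = vapply(.data$points, polyline_length,
                                     numeric(1)))
  attr(out, "spacing") <- spacing
  class(out) <- c("streamline_template", class(out))
  out
}
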