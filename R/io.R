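#' Write / read a labeled numeric matrix as TSV
#'
#' The first column holds row labels under the header `roi`; values are
#' written with 15 significant digits so a write/read round trip is
#' value-identical well past 12 significant digits. `NaN` entries are
#' preserved (with a warning on read); a `symmetric = TRUE` read validates
#' symmetry.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @param symmetric Validate symmetry on read.
#' @return `read_matrix_tsv()` returns the matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  labels <- rownames(m) %||% paste0("R", seq_len(nrow(m)))
  collabels <- colnames(m) %||% paste0("R", seq_len(ncol(m)))
  lines <- c(
    paste(c("roi", collabels), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(labels[i], sprintf("%.15g", m[i, ])), collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, symmetric = FALSE) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(parts[[1]])
  bad <- which(lengths(parts) != width)
  if (length(bad) > 0) {
    stop(sprintf("parse error: ragged row at line %d of %s", bad[1], path),
         call. = FALSE)
  }
  header <- parts[[1]][-1]
  body <- parts[-1]
  m <- t(vapply(body, function(r) as.numeric(r[-1]), numeric(width - 1)))
  rownames(m) <- vapply(body, `[[`, character(1), 1)
  colnames(m) <- header
  if (anyNA(m)) {
    warning(sprintf("%d non-finite entries preserved on read", sum(is.na(m))))
  }
  if (symmetric) {
    fin <- is.finite(m)
    if (nrow(m) != ncol(m) ||
        max(abs(m[fin & t(fin)] - t(m)[fin & t(fin)])) > 1e-8) {
      stop("validation error: matrix flagged symmetric is not symmetric",
           call. = FALSE)
    }
  }
  m
}

#' Write a 3D label or mask volume as NIfTI
#'
#' @param volume 3D array (integer labels or 0/1 mask).
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param spacing Isotropic voxel size in mm.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(volume, path, spacing = 3) {
  img <- RNifti::asNifti(volume * 1)
  RNifti::pixdim(img) <- c(spacing, spacing, spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)[1]
  arr
}
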