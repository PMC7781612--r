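#' Maximum-likelihood sample covariance of ROI time series
#'
#' Columns are mean-centered and the covariance uses the 1/n normalization
#' consistent with the Gaussian deviance used for model selection.
#'
#' @param series Numeric matrix, rows = timepoints, columns = ROIs.
#' @return Symmetric covariance matrix with an `n_samples` attribute.
#' @export
sample_covariance <- function(series) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 2) stop("at least two timepoints are required", call. = FALSE)
  v <- apply(series, 2, stats::var)
  if (any(v == 0)) {
    stop(sprintf("ROI %s has a constant time series (zero variance)",
                 paste(which(v == 0), collapse = ", ")), call. = FALSE)
  }
  xc <- scale(series, center = TRUE, scale = FALSE)
  s <- crossprod(xc) / n
  s <- (s + t(s)) / 2
  attr(s, "n_samples") <- n
  s
}

penalty_matrix <- function(support, lambda_sc, lambda_non_sc) {
  check_symmetric(support, "support")
  if (lambda_sc < 0 || lambda_non_sc < 0) {
    stop("penalties must be nonnegative", call. = FALSE)
  }
  lam <- matrix(lambda_non_sc, nrow(support), ncol(support))
  lam[support != 0] <- lambda_sc
  diag(lam) <- 0
  lam
}

#' Adaptive graphical lasso with a structural-connectome penalty prior
#'
#' Estimates a sparse precision matrix by minimizing
#' `-log det(Phi) + tr(S Phi) + lambda_sc * sum_(j<k, SC) |Phi_jk| +
#' lambda_non_sc * sum_(j<k, not SC) |Phi_jk|` over positive-definite `Phi`.
#' Off-diagonal entries at structural edges receive penalty `lambda_sc`, all
#' other off-diagonals `lambda_non_sc`; the diagonal is unpenalized. Solved
#' by block coordinate descent with a duality-gap convergence certificate.
#'
#' @param S Sample covariance (see [sample_covariance()]).
#' @param support Binarized structural connectome (ignored by
#'   [graphical_lasso()]).
#' @param lambda_sc Penalty on SC edges.
#' @param lambda_non_sc Penalty on non-SC edges (default 0.2).
#' @param tol Duality-gap tolerance (default 1e-6).
#' @param max_iter Maximum number of full sweeps (default 500).
#' @return Object of class `agl_fit`: `precision`, logical `support_graph`
#'   of nonzero off-diagonals, penalties, duality `gap`, `iterations` and the
#'   per-sweep `objective_trace`.
#' @export
adaptive_glasso <- function(S, support, lambda_sc, lambda_non_sc = 0.2,
                            tol = 1e-6, max_iter = 500L) {
  check_symmetric(S, "S")
  lam <- penalty_matrix(support, lambda_sc, lambda_non_sc)
  fit <- agl_solve(S, lam, tol, max_iter)
  if (!fit$converged) {
    stop(sprintf(
      "adaptive graphical lasso did not converge in %d sweeps (gap %.3g)",
      max_iter, fit$gap), call. = FALSE)
  }
  phi <- (fit$precision + t(fit$precision)) / 2
  sg <- abs(phi) > 1e-10
  diag(sg) <- FALSE
  sg <- sg | t(sg)
  structure(list(precision = phi, support_graph = sg,
                 lambda_sc = lambda_sc, lambda_non_sc = lambda_non_sc,
                 gap = fit$gap, iterations = fit$iterations,
                 objective_trace = fit$objective_trace),
            class = "agl_fit")
}

#' @rdname adaptive_glasso
#' @param lambda Uniform penalty for the plain graphical lasso.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-6, max_iter = 500L) {
  support0 <- matrix(0, nrow(S), ncol(S))
  adaptive_glasso(S, support0, lambda_sc = lambda, lambda_non_sc = lambda,
                  tol = tol, max_iter = max_iter)
}

#' @export
print.agl_fit <- function(x, ...) {
  cat(sprintf(
    "<agl_fit> %d ROIs, %d support edges, lambda = (%g, %g), gap = %.2g\n",
    nrow(x$precision), sum(x$support_graph[upper.tri(x$support_graph)]),
    x$lambda_sc, x$lambda_non_sc, x$gap))
  invisible(x)
}

#' Support-constrained Gaussian maximum-likelihood refit
#'
#' Re-estimates the precision without shrinkage on a fixed support graph:
#' maximizes the Gaussian likelihood against the ridged covariance
#' `S + delta I` subject to zero off-diagonals outside the support. At
#' convergence the inverse of the refit precision matches `S + delta I`
#' exactly on the support and diagonal. `delta` defaults to 0.001 times the
#' maximum of the upper triangle of `S`, guarding against rank deficiency.
#'
#' @param S Sample covariance.
#' @param support_graph Logical/binary symmetric matrix of retained edges.
#' @param delta Ridge added to the diagonal (default: see above).
#' @param tol Convergence tolerance on the fitted covariance.
#' @param max_iter Maximum sweeps.
#' @return Object of class `ggm_fit`: `precision`, `partial_correlation`,
#'   `support_graph`, `ridge_delta`, `fitted_cov`.
#' @export
refit_ggm <- function(S, support_graph, delta = NULL, tol = 1e-10,
                      max_iter = 2000L) {
  check_symmetric(S, "S")
  check_symmetric(support_graph * 1, "support_graph")
  if (is.null(delta)) delta <- 0.001 * max(S[upper.tri(S)])
  sd_ <- S + delta * diag(nrow(S))
  adj <- matrix(as.integer(support_graph != 0), nrow(S), ncol(S))
  diag(adj) <- 0L
  fit <- tryCatch(
    ggm_refit_cpp(sd_, adj, tol, max_iter),
    error = function(e) {
      stop("support-constrained refit failed: ", conditionMessage(e),
           call. = FALSE)
    })
  phi <- (fit$precision + t(fit$precision)) / 2
  phi[adj == 0 & row(phi) != col(phi)] <- 0
  ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
  if (!fit$converged || min(ev) <= 0) {
    stop("support-constrained refit did not reach a positive-definite ",
         "optimum", call. = FALSE)
  }
  structure(list(precision = phi,
                 partial_correlation = partial_correlation(phi),
                 support_graph = adj != 0, ridge_delta = delta,
                 fitted_cov = fit$fitted_cov),
            class = "ggm_fit")
}

#' Partial correlation from a precision matrix
#'
#' `PC_xy = -Phi_xy / sqrt(Phi_xx Phi_yy)` off the diagonal (conventional
#' sign), 1 on the diagonal.
#'
#' @param precision Symmetric positive-definite matrix.
#' @return Partial-correlation matrix.
#' @export
partial_correlation <- function(precision) {
  check_symmetric(precision, "precision")
  d <- diag(precision)
  if (any(d <= 0)) {
    stop("precision diagonal must be positive", call. = FALSE)
  }
  pc <- -precision / sqrt(outer(d, d))
  diag(pc) <- 1
  pc
}

#' Split-half Gaussian deviance of two precision estimates
#'
#' `Dev = 0.5 * (-log det(Phi1) + tr(S2 Phi1) - log det(Phi2) + tr(S1 Phi2))`:
#' each half's precision is scored against the other half's covariance.
#'
#' @param phi1,phi2 Precision estimates from the two halves.
#' @param S1,S2 Sample covariances of the two halves.
#' @return Scalar deviance.
#' @export
deviance_split <- function(phi1, phi2, S1, S2) {
  ld <- function(m) determinant(m, logarithm = TRUE)$modulus[[1]]
  0.5 * (-ld(phi1) + sum(S2 * phi1) - ld(phi2) + sum(S1 * phi2))
}

#' Split-half cross-validated deviance of a penalized GGM fit
#'
#' Splits the series into contiguous first/second halves, runs the (adaptive)
#' graphical lasso plus support-constrained refit on each half, and evaluates
#' each refit precision against the opposite half's covariance.
#'
#' @param series Time x ROI matrix.
#' @param support Binarized SC (used by method `"agl"`).
#' @param lambda_sc SC-edge penalty (or the uniform penalty for `"gl"`).
#' @param lambda_non_sc Non-SC penalty (method `"agl"` only).
#' @param method `"agl"` (structured penalty) or `"gl"` (uniform penalty).
#' @param standardize Scale each ROI series to unit variance first, so the
#'   covariance is on the correlation scale and penalties are scale-free
#'   (default `TRUE`).
#' @return Scalar cross-validated deviance.
#' @export
cv_deviance <- function(series, support, lambda_sc, lambda_non_sc = 0.2,
                        method = c("agl", "gl"), standardize = TRUE) {
  method <- match.arg(method)
  series <- as.matrix(series)
  if (standardize) series <- scale(series)
  n <- nrow(series)
  if (n < 4) stop("series too short to split into two halves", call. = FALSE)
  half1 <- series[seq_len(n %/% 2), , drop = FALSE]
  half2 <- series[(n %/% 2 + 1):n, , drop = FALSE]
  fit_half <- function(x) {
    s <- sample_covariance(x)
    g <- if (method == "agl") {
      adaptive_glasso(s, support, lambda_sc, lambda_non_sc)
    } else {
      graphical_lasso(s, lambda_sc)
    }
    list(S = s, phi = refit_ggm(s, g$support_graph)$precision)
  }
  f1 <- fit_half(half1)
  f2 <- fit_half(half2)
  deviance_split(f1$phi, f2$phi, f1$S, f2$S)
}

#' Select the SC-edge penalty by cross-validated deviance across subjects
#'
#' Computes, per subject and per grid value, the split-half deviance of the
#' adaptive graphical lasso (SC penalty = grid value, non-SC penalty fixed)
#' and of the plain graphical lasso (uniform penalty = grid value), then
#' averages across subjects. The selected SC penalty minimizes the mean
#' adaptive-lasso deviance.
#'
#' @param series_list List of time x ROI matrices, one per subject.
#' @param support Binarized SC prior.
#' @param lambda_grid Penalty grid (default 16 log-spaced values in
#'   `[0.01, 0.5]`).
#' @param lambda_non_sc Fixed non-SC penalty (default 0.2).
#' @return Object of class `cv_result`: tibble `curve` (`lambda`, `method`,
#'   `mean_deviance`, `sd_deviance`), `selected_lambda_sc`,
#'   `selected_lambda_gl`, `lambda_non_sc`, `n_subjects`.
#' @export
select_penalty <- function(series_list, support,
                           lambda_grid = exp(seq(log(0.01), log(0.5),
                                                 length.out = 16)),
                           lambda_non_sc = 0.2) {
  if (length(lambda_grid) < 1) stop("empty penalty grid", call. = FALSE)
  per <- purrr::map_dfr(seq_along(series_list), function(s) {
    purrr::map_dfr(lambda_grid, function(lam) {
      tibble::tibble(
        subject = s, lambda = lam,
        agl = cv_deviance(series_list[[s]], support, lam, lambda_non_sc,
                          method = "agl"),
        gl = cv_deviance(series_list[[s]], support, lam, method = "gl"))
    })
  })
  curve <- per |>
    tidyr::pivot_longer(c("agl", "gl"), names_to = "method",
                        values_to = "deviance") |>
    dplyr::group_by(.data$lambda, .data$method) |>
    dplyr::summarise(mean_deviance = mean(.data$deviance),
                     sd_deviance = sd(.data$deviance), .groups = "drop")
  agl_curve <- dplyr::filter(curve, .data$method == "agl")
  gl_curve <- dplyr::filter(curve, .data$method == "gl")
  structure(list(
    curve = curve,
    per_subject = per,
    selected_lambda_sc = agl_curve$lambda[which.min(agl_curve$mean_deviance)],
    selected_lambda_gl = gl_curve$lambda[which.min(gl_curve$mean_deviance)],
    lambda_non_sc = lambda_non_sc,
    n_subjects = length(series_list)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    paste0("<cv_result> %d subjects; selected SC penalty %.4g ",
           "(plain lasso optimum %.4g)\n"),
    x$n_subjects, x$selected_lambda_sc, x$selected_lambda_gl))
  invisible(x)
}

#' Estimate ROI functional connectivity (correlation and partial correlation)
#'
#' Convenience wrapper running the full ROI-level pipeline for one subject:
#' sample covariance, adaptive graphical lasso with the SC prior, support-
#' constrained refit, and partial correlation.
#'
#' @param series Time x ROI matrix.
#' @param support Binarized SC prior.
#' @param lambda_sc SC-edge penalty (default 0.125).
#' @param lambda_non_sc Non-SC penalty (default 0.2).
#' @param standardize Scale ROI series to unit variance before covariance
#'   estimation (default `TRUE`).
#' @return Object of class `fc_fit`: `correlation`, `precision`,
#'   `partial_correlation`, `support_graph`, `ridge_delta`, `agl` (the
#'   penalized fit), `n_timepoints`.
#' @export
fit_fc <- function(series, support, lambda_sc = 0.125, lambda_non_sc = 0.2,
                   standardize = TRUE) {
  series <- as.matrix(series)
  if (standardize) series <- scale(series)
  s <- sample_covariance(series)
  agl <- adaptive_glasso(s, support, lambda_sc, lambda_non_sc)
  refit <- refit_ggm(s, agl$support_graph)
  structure(list(
    correlation = stats::cor(series),
    precision = refit$precision,
    partial_correlation = refit$partial_correlation,
    support_graph = refit$support_graph,
    ridge_delta = refit$ridge_delta,
    agl = agl,
    n_timepoints = nrow(series)),
    class = "fc_fit")
}

#' @export
print.fc_fit <- function(x, ...) {
  cat(sprintf("<fc_fit> %d ROIs, %d precision edges, n = %d\n",
              nrow(x$precision),
              sum(x$support_graph[upper.tri(x$support_graph)]),
              x$n_timepoints))
  invisible(x)
}
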