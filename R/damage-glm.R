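#' Transform correlations to strictly positive gamma-ready responses
#'
#' Takes the absolute value and applies the Fisher r-to-z transform
#' (`atanh`). Partial correlations receive a constant `1e-4` offset so all
#' values are nonzero (the gamma distribution is undefined at 0); for plain
#' correlations the same offset is applied only to exact zeros.
#'
#' @param r Correlation values, all strictly inside (-1, 1).
#' @param is_partial Whether `r` are partial correlations.
#' @return Transformed values, strictly positive.
#' @export
#' @examples
#' transform_fc(c(0.5, -0.5))   # both 0.549306
#' transform_fc(0, is_partial = TRUE)  # 1e-4
transform_fc <- function(r, is_partial = FALSE) {
  if (any(abs(r) >= 1)) {
    stop("correlations must be strictly inside (-1, 1)", call. = FALSE)
  }
  z <- atanh(abs(r))
  if (is_partial) {
    z <- z + 1e-4
  } else {
    z[z == 0] <- 1e-4
  }
  z
}

#' Gamma GLM for one edge's damage effect
#'
#' Fits `log E(value) = beta0 + beta1 * damaged` with a gamma family and log
#' link; `beta1` is the log ratio of mean transformed FC between the
#' high-damage and low-damage groups, tested by a Wald test (dispersion
#' estimated from the Pearson statistic).
#'
#' @param values Strictly positive responses (transformed FC).
#' @param damaged Binary indicator, same length.
#' @return One-row tibble: `beta0`, `beta1`, `se_beta0`, `se_beta1`,
#'   `p_value`, `converged`, `n_low`, `n_high`.
#' @export
fit_gamma_glm <- function(values, damaged) {
  damaged <- as.integer(damaged)
  if (length(values) != length(damaged)) {
    stop("`values` and `damaged` must have the same length", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("gamma responses must be strictly positive", call. = FALSE)
  }
  n1 <- sum(damaged == 1)
  n0 <- sum(damaged == 0)
  if (n0 == 0 || n1 == 0) {
    stop("no contrast: `damaged` is constant", call. = FALSE)
  }
  if (n0 < 3 || n1 < 3) {
    stop("need at least 3 observations per damage level", call. = FALSE)
  }
  fit <- suppressWarnings(
    glm(values ~ damaged, family = Gamma(link = "log"),
        control = stats::glm.control(maxit = 200)))
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  tibble::tibble(
    beta0 = co[1, 1], beta1 = co[2, 1],
    se_beta0 = co[1, 2], se_beta1 = co[2, 2],
    p_value = co[2, 4],
    converged = isTRUE(fit$converged),
    n_low = n0, n_high = n1)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up FDR control: a p-value is flagged when its BH-adjusted value is at
#' most `alpha`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Logical vector of flags (empty input gives an empty vector).
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH") <= alpha
}

#' Edge-wise gamma GLMs of damage effects with FDR control
#'
#' Fits [fit_gamma_glm()] per edge on a long table of observations and flags
#' significant edges by Benjamini-Hochberg FDR over the family of cleanly
#' fitted edges. Edges with a constant damage indicator, too few
#' observations per group, or a non-converged fit are excluded from the FDR
#' family and reported in the `excluded` attribute with a reason.
#'
#' @param data Long tibble with columns `roi_i`, `roi_j`, `value`
#'   (transformed FC, positive) and `damaged` (0/1); one row per observation.
#' @param alpha FDR level (default 0.05).
#' @return Tibble of per-edge results (`roi_i`, `roi_j`, GLM columns,
#'   `q_significant`), class `damage_glm_tbl`, with attribute `excluded`.
#' @export
damage_glm <- function(data, alpha = 0.05) {
  grouped <- data |>
    dplyr::group_by(.data$roi_i, .data$roi_j) |>
    tidyr::nest() |>
    dplyr::ungroup()
  res <- purrr::map(grouped$data, function(d) {
    tryCatch(fit_gamma_glm(d$value, d$damaged),
             error = function(e) conditionMessage(e))
  })
  ok <- vapply(res, is.data.frame, logical(1))
  conv <- ok
  conv[ok] <- vapply(res[ok], function(r) r$converged, logical(1))
  excluded <- tibble::tibble(
    roi_i = grouped$roi_i[!conv], roi_j = grouped$roi_j[!conv],
    reason = vapply(which(!conv), function(i) {
      if (ok[i]) "did not converge" else res[[i]]
    }, character(1)))
  out <- dplyr::bind_cols(
    grouped[conv, c("roi_i", "roi_j")],
    dplyr::bind_rows(res[conv]))
  out$q_significant <- fdr_correct(out$p_value, alpha)
  attr(out, "excluded") <- excluded
  attr(out, "alpha") <- alpha
  class(out) <- c("damage_glm_tbl", class(out))
  out
}

#' Summarize which edges are modulated by damage
#'
#' Counts and fractions of FDR-flagged edges overall, split by
#' intra- vs interhemispheric status, and by hemisphere-pair group.
#'
#' @param results A `damage_glm_tbl` (or tibble with `roi_i`, `roi_j`,
#'   `q_significant`).
#' @param roi_table ROI tibble with `roi` and `hemisphere` columns.
#' @return Tibble: `stratum`, `n_modeled`, `n_flagged`, `fraction`.
#' @export
modulation_summary <- function(results, roi_table) {
  hemi <- setNames(roi_table$hemisphere, roi_table$roi)
  tbl <- results |>
    tibble::as_tibble() |>
    dplyr::mutate(
      hemi_i = hemi[as.character(.data$roi_i)],
      hemi_j = hemi[as.character(.data$roi_j)],
      scope = ifelse(.data$hemi_i == .data$hemi_j,
                     "intrahemispheric", "interhemispheric"),
      pair = paste(pmin(.data$hemi_i, .data$hemi_j),
                   pmax(.data$hemi_i, .data$hemi_j), sep = "-"))
  strata <- dplyr::bind_rows(
    dplyr::summarise(tbl, stratum = "all",
                     n_modeled = dplyr::n(),
                     n_flagged = sum(.data$q_significant)),
    tbl |>
      dplyr::group_by(stratum = .data$scope) |>
      dplyr::summarise(n_modeled = dplyr::n(),
                       n_flagged = sum(.data$q_significant),
                       .groups = "drop"),
    tbl |>
      dplyr::group_by(stratum = .data$pair) |>
      dplyr::summarise(n_modeled = dplyr::n(),
                       n_flagged = sum(.data$q_significant),
                       .groups = "drop"))
  dplyr::mutate(strata, fraction = .data$n_flagged / .data$n_modeled)
}
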