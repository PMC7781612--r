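#' Mean first passage time of the weight-proportional random walk
#'
#' The walker at node `a` steps to neighbour `b` with probability
#' `W_ab / strength(a)`. MFPT(a -> b) is the expected number of steps to
#' first reach `b` from `a`, computed exactly from the fundamental matrix
#' `Z = (I - P + 1 pi')^-1` of the chain:
#' `MFPT(a,b) = (Z_bb - Z_ab) / pi_b`, with `pi` the stationary distribution
#' (proportional to node strength for an undirected walk). The matrix is
#' asymmetric in general; its diagonal is 0.
#'
#' @param weights Symmetric nonnegative weight matrix with zero diagonal;
#'   the graph must be connected.
#' @return ROI x ROI matrix of mean first passage times.
#' @export
#' @examples
#' path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
#' path3[2, 3] <- path3[3, 2] <- 1
#' mean_first_passage_time(path3)  # MFPT(1,3) = 4, MFPT(2,1) = 3
mean_first_passage_time <- function(weights) {
  check_symmetric(weights, "weights")
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop(sprintf(
      "structural connectome is disconnected (%d components: sizes %s)",
      comp$no, paste(comp$csize, collapse = ", ")), call. = FALSE)
  }
  strength <- rowSums(weights)
  p <- nrow(weights)
  P <- weights / strength
  pi_ <- strength / sum(strength)
  Z <- solve(diag(p) - P + matrix(1, p, 1) %*% t(pi_))
  M <- (matrix(diag(Z), p, p, byrow = TRUE) - Z) /
    matrix(pi_, p, p, byrow = TRUE)
  diag(M) <- 0
  dimnames(M) <- dimnames(weights)
  M
}

#' Edge betweenness centrality under strongest-path routing
#'
#' Shortest paths are computed with edge lengths `1 / weight` (stronger
#' connections are shorter), and each edge's centrality counts the
#' unordered-pair shortest paths traversing it, with ties split fractionally
#' across equally short paths.
#'
#' @param weights Symmetric positive-weight matrix, connected graph.
#' @return Symmetric ROI x ROI matrix; entry (i, j) is the betweenness of
#'   edge (i, j), 0 where no edge exists.
#' @export
edge_betweenness_matrix <- function(weights) {
  check_symmetric(weights, "weights")
  g <- igraph::graph_from_adjacency_matrix(weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop(sprintf(
      "structural connectome is disconnected (%d components: sizes %s)",
      comp$no, paste(comp$csize, collapse = ", ")), call. = FALSE)
  }
  eb <- igraph::edge_betweenness(g, directed = FALSE,
                                 weights = 1 / igraph::E(g)$weight)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  out <- matrix(0, nrow(weights), ncol(weights))
  out[ends] <- eb
  out[ends[, c(2, 1), drop = FALSE]] <- eb
  dimnames(out) <- dimnames(weights)
  out
}

#' Standardized communication predictors over the eligible edge set
#'
#' Symmetrizes the MFPT as the elementwise mean of the matrix and its
#' transpose, extracts MFPT, edge betweenness and SC weight at the eligible
#' edges, and z-scores each predictor over that edge set.
#'
#' @param mfpt Raw MFPT matrix.
#' @param ebc Raw edge-betweenness matrix.
#' @param weights SC weight matrix.
#' @param edges Tibble of eligible edges (`roi_i`, `roi_j`).
#' @return Tibble: `roi_i`, `roi_j`, standardized `mfpt`, `ebc`,
#'   `sc_weight`.
#' @export
standardize_predictors <- function(mfpt, ebc, weights, edges) {
  if (nrow(edges) == 0) stop("no eligible edges", call. = FALSE)
  ms <- (mfpt + t(mfpt)) / 2
  idx <- cbind(edges$roi_i, edges$roi_j)
  zscore <- function(x, name) {
    if (sd(x) == 0) {
      stop(sprintf(
        "degenerate predictor: `%s` has zero variance over eligible edges",
        name), call. = FALSE)
    }
    (x - mean(x)) / sd(x)
  }
  tibble::tibble(
    roi_i = edges$roi_i, roi_j = edges$roi_j,
    mfpt = zscore(ms[idx], "mfpt"),
    ebc = zscore(ebc[idx], "ebc"),
    sc_weight = zscore(weights[idx], "sc_weight"))
}

#' Rank-sum screen of a predictor against the modulation response
#'
#' Two-sided Wilcoxon rank-sum test comparing predictor values between
#' modulated (`response == 1`) and unmodulated edges.
#'
#' @param values Predictor values per edge.
#' @param response Binary modulation indicator, same length.
#' @return Two-sided p-value; `NA` (with a warning) if a group is empty.
#' @export
ranksum_screen <- function(values, response) {
  x1 <- values[response == 1]
  x0 <- values[response == 0]
  if (length(x1) == 0 || length(x0) == 0) {
    warning("rank-sum screening skipped: one response group is empty")
    return(NA_real_)
  }
  if (length(unique(values)) == 1) return(1)
  suppressWarnings(
    wilcox.test(x1, x0, alternative = "two.sided", exact = FALSE,
                correct = FALSE)$p.value)
}

# ridge-penalized logistic fallback used under perfect separation
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wts <- pmax(mu * (1 - mu), 1e-10)
    pen <- lambda * diag(ncol(X))
    pen[1, 1] <- 0
    upd <- solve(crossprod(X, X * wts) + pen,
                 crossprod(X, y - mu) - pen %*% beta)
    beta <- beta + drop(upd)
    if (max(abs(upd)) < 1e-10) break
  }
  beta
}

#' Logistic regression of edge modulation on communication predictors
#'
#' Screens each standardized predictor with a rank-sum test, then fits
#' `logit(E(response)) = b0 + b1*MFPT + b2*SC_weight + b3*EBC` and reports
#' Wald statistics, 95% confidence intervals and odds multipliers
#' `exp(beta)`. Predictors entered collinearly raise an error; perfect
#' separation falls back to a ridge-penalized fit, flagged in the result.
#'
#' @param predictors Output of [standardize_predictors()].
#' @param response Binary vector, one per eligible edge (1 = modulated).
#' @return Object of class `comm_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `std_error`, `ci_lower`, `ci_upper`, `p_value`,
#'   `odds_multiplier`), `screening` tibble, `separation` flag, `model`.
#' @export
fit_damage_logistic <- function(predictors, response) {
  if (nrow(predictors) != length(response)) {
    stop("`response` must have one value per eligible edge", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, mfpt = predictors$mfpt,
             sc_weight = predictors$sc_weight, ebc = predictors$ebc)
  if (qr(X)$rank < ncol(X)) {
    stop("collinear predictors: design matrix is rank deficient",
         call. = FALSE)
  }
  screening <- tibble::tibble(
    predictor = c("mfpt", "sc_weight", "ebc"),
    p_value = c(ranksum_screen(predictors$mfpt, response),
                ranksum_screen(predictors$sc_weight, response),
                ranksum_screen(predictors$ebc, response)))
  y <- as.integer(response)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ mfpt + sc_weight + ebc, family = binomial(),
        data = predictors),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || max(abs(coef(fit))) > 15) {
    sep <- TRUE
    beta <- ridge_logistic(X, y)
    coefs <- tibble::tibble(
      term = colnames(X), estimate = beta,
      std_error = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
      p_value = NA_real_, odds_multiplier = exp(beta))
  } else {
    sm <- summary(fit)$coefficients
    coefs <- tibble::tibble(
      term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
      ci_lower = sm[, 1] - qnorm(0.975) * sm[, 2],
      ci_upper = sm[, 1] + qnorm(0.975) * sm[, 2],
      p_value = sm[, 4], odds_multiplier = exp(sm[, 1]))
  }
  structure(list(coefficients = coefs, screening = screening,
                 separation = sep,
                 model = if (sep) NULL else fit,
                 n_edges = length(y), n_modulated = sum(y)),
            class = "comm_fit")
}

#' @export
print.comm_fit <- function(x, ...) {
  cat(sprintf("<comm_fit> %d eligible edges, %d modulated%s\n",
              x$n_edges, x$n_modulated,
              if (x$separation) " (separation: ridge fallback)" else ""))
  print(x$coefficients)
  invisible(x)
}
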