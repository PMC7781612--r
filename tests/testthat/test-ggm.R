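test_that("sample covariance is the centered 1/n cross-product", {
  x <- cbind(a = c(-1, 0, 1), b = c(-2, 0, 2))
  s <- sample_covariance(x)
  expect_equal(s[1, 2] / sqrt(s[1, 1] * s[2, 2]), 1)   # perfectly correlated
  expect_equal(s[1, 1], 2 / 3)                          # 1/n normalization
  expect_error(sample_covariance(x[1, , drop = FALSE]), "two timepoints")
  expect_error(sample_covariance(cbind(1:5, rep(2, 5))), "constant")

  set.seed(4)
  long <- matrix(rnorm(20000 * 2), ncol = 2)
  s2 <- sample_covariance(long)
  expect_lt(abs(s2[1, 2]), 3 / sqrt(20000))
})

test_that("penalty limits recover the closed-form solutions", {
  set.seed(7)
  p <- 6
  x <- matrix(rnorm(4000 * p), ncol = p) %*% chol(0.4 + 0.6 * diag(p))
  s <- sample_covariance(x)
  # no penalty: the inverse covariance
  f0 <- graphical_lasso(s, 0)
  expect_lt(max(abs(f0$precision - solve(s))), 1e-6)
  # total shrinkage: diagonal model with unpenalized diagonal
  fI <- graphical_lasso(s, 1e6)
  expect_equal(fI$precision, diag(1 / diag(s)), tolerance = 1e-10)
  # huge non-SC penalty restricts the support to SC edges
  sup <- matrix(0, p, p)
  sup[1, 2] <- sup[2, 1] <- sup[3, 4] <- sup[4, 3] <- 1
  fr <- adaptive_glasso(s, sup, 0.05, 1e6)
  off <- fr$precision
  diag(off) <- 0
  expect_true(all(off[sup == 0] == 0))
})

test_that("solver objective decreases monotonically and the gap certifies optimality", {
  set.seed(12)
  p <- 8
  sup <- random_support(p)
  phi <- planted_precision(sup)
  x <- simulate_bold(phi, 1000)
  s <- sample_covariance(x)
  fit <- adaptive_glasso(s, sup, 0.1, 0.2)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-8))
  expect_lt(abs(fit$gap), 1e-6)
})

test_that("sparsity is monotone in the SC penalty at fixed non-SC penalty", {
  set.seed(3)
  p <- 10
  sup <- random_support(p)
  x <- simulate_bold(planted_precision(sup), 500)
  s <- sample_covariance(scale(x))
  nnz <- vapply(c(0.01, 0.05, 0.1, 0.25, 0.5), function(l1) {
    f <- adaptive_glasso(s, sup, l1, 0.2)
    sum(f$support_graph[upper.tri(f$support_graph)])
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("support-constrained refit matches closed forms and a numerical oracle", {
  set.seed(21)
  p <- 3
  x <- matrix(rnorm(600 * p), ncol = p) %*% chol(0.5 + 0.5 * diag(p))
  s <- sample_covariance(x)
  delta <- 0.001 * max(s[upper.tri(s)])
  sd_ <- s + delta * diag(p)
  # full support: plain ridged inverse
  full <- refit_ggm(s, matrix(1, p, p))
  expect_lt(max(abs(full$precision - solve(sd_))), 1e-8)
  # empty support: independence model
  none <- refit_ggm(s, matrix(0, p, p))
  expect_equal(none$precision, diag(1 / diag(sd_)), tolerance = 1e-12)

  # chain support: compare against direct minimization of the constrained
  # negative log-likelihood over the free parameters
  sup <- matrix(0, p, p)
  sup[1, 2] <- sup[2, 1] <- sup[2, 3] <- sup[3, 2] <- 1
  fit <- refit_ggm(s, sup)
  obj <- function(th) {
    phi <- matrix(0, p, p)
    diag(phi) <- th[1:3]
    phi[1, 2] <- phi[2, 1] <- th[4]
    phi[2, 3] <- phi[3, 2] <- th[5]
    ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) return(1e10)
    -determinant(phi)$modulus[[1]] + sum(sd_ * phi)
  }
  oracle <- stats::optim(c(diag(fit$precision), 0, 0), obj,
                         method = "Nelder-Mead",
                         control = list(maxit = 50000, reltol = 1e-14))
  expect_lt(abs(obj(c(diag(fit$precision), fit$precision[1, 2],
                      fit$precision[2, 3])) - oracle$value), 1e-6)
  # refit consistency: fitted covariance matches S + delta I on support
  inv <- solve(fit$precision)
  on_sup <- sup == 1 | diag(p) == 1
  expect_lt(max(abs((inv - sd_)[on_sup])) / max(abs(sd_)), 1e-6)
  # zero constraint honored exactly
  expect_identical(fit$precision[1, 3], 0)
})

test_that("partial correlation follows the normalized-precision formula", {
  phi <- matrix(c(2, -1, -1, 2), 2, 2)
  pc <- partial_correlation(phi)
  expect_equal(abs(pc[1, 2]), 0.5)
  expect_equal(pc[1, 2], 0.5)   # conventional sign: -(-1)/2
  expect_equal(diag(pc), c(1, 1))
  expect_equal(partial_correlation(diag(c(2, 3)))[1, 2], 0)
  # 3-node chain: non-adjacent pair has PC exactly 0
  chain <- matrix(c(2, -0.5, 0, -0.5, 2, -0.5, 0, -0.5, 2), 3, 3)
  expect_equal(partial_correlation(chain)[1, 3], 0)
  expect_error(partial_correlation(matrix(c(-1, 0, 0, 1), 2, 2)), "positive")
})

test_that("split-half deviance recovers the identity value and is relabel-invariant", {
  p <- 7
  expect_equal(deviance_split(diag(p), diag(p), diag(p), diag(p)), p)

  set.seed(31)
  sup <- random_support(6)
  x <- simulate_bold(planted_precision(sup), 400)
  d1 <- cv_deviance(x, sup, 0.1)
  perm <- sample(6)
  d2 <- cv_deviance(x[, perm], sup[perm, perm], 0.1)
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("the planted support achieves lower deviance than random supports", {
  set.seed(17)
  p <- 20
  wins <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    sup <- random_support(p, density = 0.25)
    x <- simulate_bold(planted_precision(sup), 2000)
    x <- scale(x)
    n <- nrow(x)
    s1 <- sample_covariance(x[1:(n / 2), ])
    s2 <- sample_covariance(x[(n / 2 + 1):n, ])
    dev_at <- function(g) {
      deviance_split(refit_ggm(s1, g)$precision, refit_ggm(s2, g)$precision,
                     s1, s2)
    }
    n_edges <- sum(sup[upper.tri(sup)])
    rand <- matrix(0, p, p)
    pick <- sample(which(upper.tri(rand)), n_edges)
    rand[pick] <- 1
    rand <- rand + t(rand)
    if (dev_at(sup) < dev_at(rand)) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("penalty selection returns full curves and the argmin", {
  set.seed(41)
  sup <- random_support(8)
  series <- replicate(3, simulate_bold(planted_precision(sup), 200),
                      simplify = FALSE)
  single <- select_penalty(series, sup, lambda_grid = 0.1)
  expect_equal(single$selected_lambda_sc, 0.1)
  grid <- c(0.05, 0.1, 0.2)
  cv <- select_penalty(series, sup, lambda_grid = grid)
  expect_equal(sort(unique(cv$curve$lambda)), grid)
  expect_equal(nrow(cv$curve), 2 * length(grid))   # agl + gl curves
  agl <- dplyr::filter(cv$curve, method == "agl")
  expect_equal(cv$selected_lambda_sc,
               agl$lambda[which.min(agl$mean_deviance)])
  expect_error(select_penalty(series, sup, lambda_grid = numeric(0)), "empty")
})

test_that("adaptive lasso plus refit recovers the planted support (F1 >= 0.9)", {
  set.seed(77)
  co <- simulate_cohort(cohort_config(
    n_subjects = 1L, n_rois = 20L, n_timepoints = 5000L,
    coupling_attenuation = 0, rng_seed = 77L))
  fit <- fit_fc(co$subjects[[1]]$roi_series, co$support)
  expect_gte(edge_f1(fit$support_graph, co$support), 0.9)
})
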