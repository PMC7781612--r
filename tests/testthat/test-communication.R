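test_that("MFPT solves the first-step equations on small graphs", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  m <- mean_first_passage_time(path3)
  expect_equal(m[1, 2], 1)   # forced first step
  expect_equal(m[1, 3], 4)
  expect_equal(m[2, 1], 3)
  expect_equal(diag(m), rep(0, 3))

  two <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(mean_first_passage_time(two),
               matrix(c(0, 1, 1, 0), 2, 2))

  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- disc[3, 4] <- disc[4, 3] <- 1
  expect_error(mean_first_passage_time(disc), "disconnected")
})

test_that("MFPT matches Monte-Carlo walkers within 2% on random 8-node graphs", {
  set.seed(60)
  for (rep in 1:3) {
    w <- random_connected_graph(8)
    m <- mean_first_passage_time(w)
    a <- sample(8, 1)
    b <- sample(setdiff(1:8, a), 1)
    sim <- mc_mfpt(w, a, b)
    expect_lt(abs(sim - m[a, b]) / m[a, b], 0.02)
  }
})

test_that("edge betweenness matches exhaustive enumeration on all graphs up to 5 nodes", {
  # all connected labeled graphs on 4 nodes, plus weighted 5-node samples
  pairs4 <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  n_checked <- 0
  for (code in 0:(2^nrow(pairs4) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(nrow(pairs4))]
    if (sum(bits) < 3) next
    w <- matrix(0, 4, 4)
    w[pairs4[bits == 1, , drop = FALSE]] <- 1
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
    if (igraph::components(g)$no > 1) next
    expect_equal(edge_betweenness_matrix(w), brute_ebc(w), tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 30)

  set.seed(61)
  for (rep in 1:10) {
    w <- random_connected_graph(5)
    expect_equal(edge_betweenness_matrix(w), brute_ebc(w), tolerance = 1e-10)
  }

  # closed forms: 3-node path and 4-node star
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  e3 <- edge_betweenness_matrix(path3)
  expect_equal(e3[1, 2], 2)
  expect_equal(e3[2, 3], 2)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  es <- edge_betweenness_matrix(star)
  expect_true(all(es[1, 2:4] == 3))
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(edge_betweenness_matrix(two)[1, 2], 1)
})

test_that("predictor standardization symmetrizes MFPT then z-scores over edges", {
  set.seed(62)
  w <- random_connected_graph(6)
  m <- mean_first_passage_time(w)
  e <- edge_betweenness_matrix(w)
  edges <- tidy_support_edges(w)
  pred <- standardize_predictors(m, e, w, edges)
  for (col in c("mfpt", "ebc", "sc_weight")) {
    expect_lt(abs(mean(pred[[col]])), 1e-10)
    expect_lt(abs(sd(pred[[col]]) - 1), 1e-10)
  }
  # symmetrization: the standardized MFPT is the same for (i,j) and (j,i)
  ms <- (m + t(m)) / 2
  expect_equal(ms, t(ms))
  expect_error(
    standardize_predictors(matrix(1, 6, 6), e, w, edges), "degenerate")
  expect_error(standardize_predictors(m, e, w, edges[0, ]), "eligible")
})

test_that("rank-sum screening is calibrated and detects separation", {
  set.seed(63)
  rej <- mean(replicate(1000, {
    ranksum_screen(rnorm(200), rep(c(0, 1), each = 100)) < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  sep <- ranksum_screen(c(rnorm(20), rnorm(20) + 100),
                        rep(c(0, 1), each = 20))
  expect_lt(sep, 1e-6)
  expect_equal(ranksum_screen(rep(3, 40), rep(c(0, 1), each = 20)), 1)
  expect_warning(out <- ranksum_screen(1:5, rep(0, 5)), "empty")
  expect_true(is.na(out))
})

test_that("logistic model covers the truth and recovers planted coefficients", {
  set.seed(64)
  n <- 5000
  pred <- tibble::tibble(
    roi_i = 1L, roi_j = 2L,
    mfpt = rnorm(n), ebc = rnorm(n), sc_weight = rnorm(n))
  beta <- c(-0.6, 0.3, 0.2)   # mfpt, sc_weight, ebc
  eta <- -0.3 + beta[1] * pred$mfpt + beta[2] * pred$sc_weight +
    beta[3] * pred$ebc
  y <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- fit_damage_logistic(pred, y)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_lt(abs(est[["mfpt"]] - (-0.6)), 0.1)
  expect_lt(abs(est[["sc_weight"]] - 0.3), 0.1)
  expect_lt(abs(est[["ebc"]] - 0.2), 0.1)
  expect_false(fit$separation)
  expect_equal(fit$coefficients$odds_multiplier,
               exp(fit$coefficients$estimate))

  # CI coverage under the null
  set.seed(65)
  cover <- replicate(300, {
    predn <- tibble::tibble(roi_i = 1L, roi_j = 2L, mfpt = rnorm(341),
                            ebc = rnorm(341), sc_weight = rnorm(341))
    yn <- stats::rbinom(341, 1, 0.35)
    f <- fit_damage_logistic(predn, yn)
    row <- f$coefficients[f$coefficients$term == "mfpt", ]
    row$ci_lower <= 0 && row$ci_upper >= 0
  })
  expect_gt(mean(cover), 0.9)

  # duplicated predictor -> collinearity error
  dup <- dplyr::mutate(pred, ebc = mfpt)
  expect_error(fit_damage_logistic(dup, y), "collinear")
})
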