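# shared fixtures built in code

# voxel <-> mm conversions on the default 3 mm grid (1-based voxel indices)
mm_to_vox_test <- function(mm, spacing = 3) as.integer(round(mm / spacing)) + 1L
vox_mm_test <- function(v, spacing = 3) (v - 1) * spacing

# tiny two-ROI atlas + template with fixed streamline count
tiny_cohort_config <- function(...) {
  cohort_config(n_subjects = 4L, n_rois = 4L, n_timepoints = 60L,
                streamlines_per_edge = c(2L, 3L), rng_seed = 11L, ...)
}

# a small random symmetric hollow support with a guaranteed connected graph
random_support <- function(p, density = 0.4) {
  s <- matrix(0, p, p)
  for (i in seq_len(p - 1)) s[i, i + 1] <- 1      # path backbone
  extra <- which(upper.tri(s) & s == 0, arr.ind = TRUE)
  pick <- extra[runif(nrow(extra)) < density, , drop = FALSE]
  s[pick] <- 1
  s + t(s)
}

# random connected weighted graph on n nodes
random_connected_graph <- function(n, wmin = 0.5, wmax = 2) {
  w <- random_support(n, density = 0.5)
  vals <- runif(sum(upper.tri(w) & w > 0), wmin, wmax)
  w[upper.tri(w) & w > 0] <- vals
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

# upper-triangle edges of a weight matrix as a tibble
tidy_support_edges <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  tibble::tibble(roi_i = idx[, 1], roi_j = idx[, 2])
}

# edge-set F1 between two logical/binary matrices (upper triangle)
edge_f1 <- function(est, truth) {
  ut <- upper.tri(truth)
  e <- est[ut] != 0
  t_ <- truth[ut] != 0
  tp <- sum(e & t_)
  2 * tp / (2 * tp + sum(e & !t_) + sum(!e & t_))
}

# brute-force Benjamini-Hochberg step-up flags
bh_brute_force <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  flags <- logical(m)
  passing <- which(p[ord] <= seq_len(m) * alpha / m)
  if (length(passing) > 0) flags[ord[seq_len(max(passing))]] <- TRUE
  flags
}

# Monte-Carlo MFPT oracle: average steps of simulated weight-proportional
# random walkers from a to b
mc_mfpt <- function(w, a, b, n_walks = 1e5, max_steps = 1e4) {
  p <- w / rowSums(w)
  cum <- t(apply(p, 1, cumsum))
  pos <- rep(a, n_walks)
  steps <- rep(0L, n_walks)
  active <- rep(TRUE, n_walks)
  for (s in seq_len(max_steps)) {
    idx <- which(active)
    if (length(idx) == 0) break
    u <- runif(length(idx))
    nxt <- max.col(cum[pos[idx], , drop = FALSE] >= u, ties.method = "first")
    pos[idx] <- nxt
    steps[idx] <- steps[idx] + 1L
    active[idx] <- nxt != b
  }
  mean(steps)
}

# exhaustive edge betweenness: enumerate all simple paths per unordered pair,
# keep the shortest-length ones (1/weight edge lengths), split ties evenly
brute_ebc <- function(w) {
  n <- nrow(w)
  out <- matrix(0, n, n)
  all_paths <- function(a, b) {
    res <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == b) {
        res[[length(res) + 1]] <<- path
        return()
      }
      for (nxt in which(w[last, ] > 0)) {
        if (!nxt %in% path) grow(c(path, nxt))
      }
    }
    grow(a)
    res
  }
  plen <- function(path) {
    sum(1 / w[cbind(path[-length(path)], path[-1])])
  }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      paths <- all_paths(a, b)
      if (length(paths) == 0) next
      lens <- vapply(paths, plen, numeric(1))
      best <- paths[abs(lens - min(lens)) < 1e-12]
      for (pth in best) {
        for (k in seq_len(length(pth) - 1)) {
          i <- pth[k]; j <- pth[k + 1]
          out[i, j] <- out[i, j] + 1 / length(best)
          out[j, i] <- out[i, j]
        }
      }
    }
  }
  out
}
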