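test_that("resampling yields 100 arc-length-uniform points with exact endpoints", {
  seg <- rbind(c(0, 0, 0), c(99, 0, 0))
  out <- resample_streamline(seg)
  expect_equal(dim(out), c(100, 3))
  expect_equal(out[, 1], seq(0, 99, by = 1))
  expect_equal(out[, 2], rep(0, 100))

  line100 <- cbind(seq(0, 50, length.out = 100), 1, 2)
  out2 <- resample_streamline(line100)
  expect_identical(out2[1, ], line100[1, ])
  expect_identical(out2[100, ], line100[100, ])

  expect_error(resample_streamline(rbind(c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
})

test_that("resampled arc length of a circular arc matches the analytic value", {
  theta <- seq(0, pi, length.out = 25)
  arc <- cbind(10 * cos(theta), 10 * sin(theta), 0)
  out <- resample_streamline(arc)
  analytic <- pi * 10
  resampled <- sum(sqrt(rowSums(diff(out)^2)))
  expect_lt(abs(resampled - analytic) / analytic, 0.01)
})

test_that("template streamlines have 100 points, valid endpoints, homologous-only crossings", {
  set.seed(8)
  atlas <- make_atlas(6)
  tpl <- make_streamline_template(atlas, c(3L, 3L), edge_density = 1)
  expect_true(all(vapply(tpl$points, nrow, numeric(1)) == 100))
  hemi <- setNames(atlas$rois$hemisphere, atlas$rois$roi)
  hom <- setNames(atlas$rois$homologue, atlas$rois$roi)
  for (k in seq_len(nrow(tpl))) {
    pts <- tpl$points[[k]]
    va <- mm_to_vox_test(pts[1, ])
    vb <- mm_to_vox_test(pts[100, ])
    expect_equal(atlas$labels[va[1], va[2], va[3]], tpl$roi_a[k])
    expect_equal(atlas$labels[vb[1], vb[2], vb[3]], tpl$roi_b[k])
    if (hemi[as.character(tpl$roi_a[k])] != hemi[as.character(tpl$roi_b[k])]) {
      expect_equal(hom[[as.character(tpl$roi_a[k])]], tpl$roi_b[k])
    }
  }
  # fixed count: every present edge carries exactly 3 streamlines
  expect_true(all(dplyr::count(tibble::as_tibble(tpl),
                               roi_a, roi_b)$n == 3))
})

test_that("lesion intersection matches brute-force point containment", {
  set.seed(13)
  atlas <- make_atlas(6)
  tpl <- make_streamline_template(atlas, c(2L, 4L), edge_density = 0.8)
  expect_identical(intersect_lesion(tpl, array(0, dim(atlas$labels))),
                   integer(0))
  lesion <- make_lesion(atlas, c(8, 10, 10), 7)
  got <- intersect_lesion(tpl, lesion)
  brute <- tpl$id[vapply(tpl$points, function(pts) {
    any(apply(pts, 1, function(pt) {
      v <- mm_to_vox_test(pt)
      all(v >= 1) && all(v <= dim(lesion)) && lesion[v[1], v[2], v[3]]
    }))
  }, logical(1))]
  expect_setequal(got, brute)

  # a lesion covering a full hemisphere disconnects exactly the streamlines
  # with at least one point there
  hemi_mask <- array(FALSE, dim(atlas$labels))
  hemi_mask[seq_len(dim(atlas$labels)[1] %/% 2), , ] <- TRUE
  got_h <- intersect_lesion(tpl, hemi_mask)
  brute_h <- tpl$id[vapply(tpl$points, function(pts) {
    any(mm_to_vox_test(pts[, 1]) <= dim(atlas$labels)[1] %/% 2)
  }, logical(1))]
  expect_setequal(got_h, brute_h)
})

test_that("single-voxel lesion at a streamline midpoint disconnects it", {
  atlas <- make_atlas(4, c(12, 12, 12))
  pts <- resample_streamline(rbind(c(3, 6, 6), c(30, 6, 6)))
  tpl <- tibble::tibble(id = 1L, roi_a = 1L, roi_b = 3L,
                        length_mm = 27, points = list(pts))
  attr(tpl, "spacing") <- 3
  lesion <- array(FALSE, dim(atlas$labels))
  mid <- mm_to_vox_test(pts[50, ])
  lesion[mid[1], mid[2], mid[3]] <- TRUE
  expect_identical(intersect_lesion(tpl, lesion), 1L)
})

test_that("connectome weights follow the normalization mode", {
  pts1 <- resample_streamline(rbind(c(0, 0, 0), c(2, 0, 0)))
  pts2 <- resample_streamline(rbind(c(0, 0, 0), c(4, 0, 0)))
  tpl <- tibble::tibble(id = 1:2, roi_a = c(1L, 1L), roi_b = c(2L, 2L),
                        length_mm = c(2, 4),
                        points = list(pts1, pts2))
  attr(tpl, "spacing") <- 3
  sc <- build_connectome(tpl, integer(0), 2, "length_inverse")
  expect_equal(sc$weights[1, 2], 0.75)   # 1/2 + 1/4
  expect_equal(sc$weights, t(sc$weights))
  expect_equal(diag(sc$weights), c(0, 0))
  sc2 <- build_connectome(tpl, integer(0), 2, "raw_count")
  expect_equal(sc2$weights[1, 2], 2)
  roi_table <- tibble::tibble(roi = 1:2, n_voxels = c(10, 20))
  sc3 <- build_connectome(tpl, integer(0), 2, "roi_size_normalized",
                          roi_table)
  expect_equal(sc3$weights[1, 2], 2 / 200)
  # all streamlines of the edge disconnected -> zero weight and support
  sc0 <- build_connectome(tpl, 1:2, 2)
  expect_equal(sc0$weights[1, 2], 0)
  expect_equal(sc0$support[1, 2], 0)
})

test_that("per-subject weights never exceed the template and damage is monotone", {
  co <- simulate_cohort(tiny_cohort_config())
  disconnected <- lapply(co$subjects, `[[`, "disconnected_ids")
  tpl_sc <- build_connectome(co$template, integer(0), co$config$n_rois)
  for (mode in c("length_inverse", "raw_count")) {
    tpl_m <- build_connectome(co$template, integer(0), co$config$n_rois, mode)
    for (ids in disconnected) {
      sub_m <- build_connectome(co$template, ids, co$config$n_rois, mode)
      expect_true(all(sub_m$weights <= tpl_m$weights + 1e-12))
      # growing the lesion (superset of ids) never reconnects anything
      more <- union(ids, co$template$id[seq_len(min(5, nrow(co$template)))])
      sub_more <- build_connectome(co$template, more, co$config$n_rois, mode)
      expect_true(all(sub_more$weights <= sub_m$weights + 1e-12))
    }
  }
  # conservation: connected + disconnected = template count
  for (ids in disconnected) {
    expect_equal(length(ids) + sum(!co$template$id %in% ids),
                 nrow(co$template))
  }
})

test_that("damage stratification applies the strict below-median rule", {
  w <- tibble::tibble(roi_i = 1L, roi_j = 2L, subject = 1:5,
                      weight = c(1, 2, 3, 4, 5))
  d <- stratify_damage(w)
  expect_equal(d$high_damage, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # all equal -> nobody below the median
  w2 <- tibble::tibble(roi_i = 1L, roi_j = 2L, subject = 1:4, weight = 2)
  expect_false(any(stratify_damage(w2)$high_damage))
  # exactly at the median -> low damage
  w3 <- tibble::tibble(roi_i = 1L, roi_j = 2L, subject = 1:3,
                       weight = c(1, 3, 3))
  expect_equal(stratify_damage(w3)$high_damage, c(TRUE, FALSE, FALSE))
  expect_error(stratify_damage(dplyr::filter(w, subject == 1)), "two subjects")
})

test_that("edge eligibility thresholds count high-damage subjects monotonically", {
  d <- tibble::tibble(
    roi_i = rep(c(1L, 1L, 2L), each = 8),
    roi_j = rep(c(2L, 3L, 3L), each = 8),
    subject = rep(1:8, 3),
    high_damage = c(rep(TRUE, 4), rep(FALSE, 4),
                    rep(TRUE, 2), rep(FALSE, 6),
                    rep(TRUE, 7), FALSE))
  e3 <- eligible_edges(d, 3)
  expect_equal(nrow(e3), 2)
  expect_setequal(paste(e3$roi_i, e3$roi_j), c("1 2", "2 3"))
  e1 <- eligible_edges(d, 1)
  expect_true(all(paste(e3$roi_i, e3$roi_j) %in% paste(e1$roi_i, e1$roi_j)))
  expect_equal(nrow(eligible_edges(d, 9)), 0)
  expect_error(eligible_edges(d, 0), "min_subjects")
})
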