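test_that("non-touching nuclei are segmented one label each, containing its truth centroid", {
  spec <- sparse_section_spec(seed = 4)
  gen <- generate_section(spec)
  lab <- segment_nuclei(gen$image$channels$hoechst, spec$pixel_size_um)
  expect_identical(max(lab), nrow(gen$truth))
  i <- pmin(pmax(ceiling(gen$truth$x_um / spec$pixel_size_um), 1L), nrow(lab))
  j <- pmin(pmax(ceiling(gen$truth$y_um / spec$pixel_size_um), 1L), ncol(lab))
  hit <- lab[cbind(i, j)]
  expect_true(all(hit > 0L))
  expect_identical(anyDuplicated(hit), 0L)
})

test_that("degenerate rasters yield empty labelings, not errors", {
  z <- matrix(0, 40, 30)
  expect_identical(max(segment_nuclei(z, 0.5)), 0L)
  expect_identical(nrow(measure_nuclei(segment_nuclei(z, 0.5), list(gfp = z), 0.5)), 0L)
  expect_error(segment_nuclei(z, 0.5, threshold_mode = "magic"), "arg")
})

test_that("two moderately overlapping ellipses are split into two labels", {
  # centres 6 um apart along the major axis: overlap well under 30% of minor axis
  m <- matrix(0, 100, 60)
  for (cx in c(20, 26)) {
    idx <- tenomac:::ellipse_pixels(cx, 15, 4, 2, 0, 100, 60, 0.5)
    m[idx] <- 180
  }
  lab <- segment_nuclei(m + 1, 0.5)
  expect_identical(max(lab), 2L)
})

test_that("per-nucleus means equal brute-force pixel iteration", {
  spec <- sparse_section_spec(seed = 6)
  out <- run_section_pipeline(spec)
  lab <- out$labels
  gfp <- out$gen$image$channels$gfp
  recs <- out$records
  expect_identical(nrow(recs), max(lab))
  for (k in sample(recs$label, 5)) {
    acc <- 0; npx <- 0
    for (i in seq_len(nrow(lab))) {
      for (j in seq_len(ncol(lab))) {
        if (lab[i, j] == k) { acc <- acc + gfp[i, j]; npx <- npx + 1 }
      }
    }
    expect_equal(recs$mean_gfp[recs$label == k], acc / npx, tolerance = 1e-12)
  }
})

test_that("uniform-intensity nuclei measure their rendered value exactly", {
  m <- matrix(0, 60, 40)
  idx <- tenomac:::ellipse_pixels(15, 10, 4, 2, 0, 60, 40, 0.5)
  m[idx] <- 150
  v <- matrix(0, 60, 40)
  v[idx] <- 42.5
  lab <- segment_nuclei(m, 0.5, threshold_mode = "fixed", threshold = 10)
  rec <- measure_nuclei(lab, list(gfp = v), 0.5)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$mean_gfp, 42.5)
})

test_that("otsu segmentation is invariant to affine intensity rescaling", {
  spec <- sparse_section_spec(seed = 9)
  h <- generate_section(spec)$image$channels$hoechst
  lab1 <- segment_nuclei(h, 0.5)
  lab2 <- segment_nuclei(3.5 * h + 120, 0.5)
  expect_identical(array(lab1, dim(lab1)), array(lab2, dim(lab2)))
})

test_that("watershed never creates foreground and area bounds are enforced", {
  spec <- small_section_spec(seed = 10)
  h <- generate_section(spec)$image$channels$hoechst
  lab <- segment_nuclei(h, 0.5)
  thr <- attr(lab, "threshold")
  expect_lte(sum(lab > 0), sum(h > thr))
  areas <- table(lab[lab > 0]) * 0.5^2
  expect_true(all(areas >= 8 & areas <= 200))
})

test_that("threshold classification is arithmetic on mean intensities", {
  recs <- data.frame(label = 1:2, mean_gfp = c(10, 200))
  out <- classify_by_threshold(recs, "gfp", 100)
  expect_identical(out$gfp_pos, c(FALSE, TRUE))
  expect_false(any(classify_by_threshold(recs, "gfp", Inf)$gfp_pos))
  expect_error(classify_by_threshold(recs, "edu", 1), "absent")
})

test_that("nucleus detection reaches F1 >= 0.95 and classification accuracy >= 0.98", {
  spec <- small_section_spec(seed = 12)
  out <- run_section_pipeline(spec)
  expect_gte(detection_f1(out$records, out$gen$truth), 0.95)
  # per-truth-cell classification accuracy against generator labels
  truth <- out$gen$truth
  d <- outer(out$records$x_um, truth$x_um, "-")^2 + outer(out$records$y_um, truth$y_um, "-")^2
  nearest <- max.col(-d)
  acc <- mean(out$records$gfp_pos == (truth$class[nearest] == "macrophage"))
  expect_gte(acc, 0.98)
})
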