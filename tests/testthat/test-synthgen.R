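test_that("section generation is bit-reproducible and honours degenerate fractions", {
  spec <- small_section_spec(seed = 42)
  a <- generate_section(spec)
  b <- generate_section(spec)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)

  none <- small_section_spec(seed = 3, macrophage_fraction = 0,
                             peritenon_macrophage_fraction = 0)
  expect_false(any(generate_section(none)$truth$class == "macrophage"))
})

test_that("cell count equals an independent re-run of the documented sampling recipe", {
  # 1 mm^2 fascicle at 200 cells/mm^2; the first seeded draw is the Poisson count
  geo <- fascicle_band_polygon(2000, 500, x0 = 60, y0 = 80, wave_amp_um = 0)
  spec <- section_spec(width_um = 2120, height_um = 660,
                       fascicle_polygon = geo$polygon,
                       anterior_polyline = geo$anterior, posterior_polyline = geo$posterior,
                       cell_density_per_mm2 = 200, seed = 99)
  truth <- sample_cells(spec)
  area_mm2 <- polygon_area(spec$fascicle_polygon) / 1e6
  expect_equal(area_mm2, 1, tolerance = 1e-12)
  n_expected <- local({ set.seed(99L); rpois(1L, 200 * area_mm2) })
  expect_identical(sum(truth$compartment == "fascicle"), n_expected)
})

test_that("ground truth and rendering are mutually consistent", {
  gen <- generate_section(small_section_spec(seed = 5))
  psz <- 0.5
  i <- pmin(pmax(ceiling(gen$truth$x_um / psz), 1L), nrow(gen$truth_labels))
  j <- pmin(pmax(ceiling(gen$truth$y_um / psz), 1L), ncol(gen$truth_labels))
  ids <- gen$truth_labels[cbind(i, j)]
  # every centroid pixel lies inside its own rendered nucleus, and no other's
  expect_identical(ids, gen$truth$cell_id)
  # in-polygon placement of fascicle cells
  fas <- gen$truth[gen$truth$compartment == "fascicle", ]
  expect_true(all(points_in_polygon(fas$x_um, fas$y_um, gen$image$rois$polygons$fascicle)))
})

test_that("realized macrophage fraction is unbiased for the spec fraction", {
  p <- 0.08
  fr <- vapply(1:50, function(s) {
    t <- sample_cells(small_section_spec(seed = s))
    t <- t[t$compartment == "fascicle", ]
    mean(t$class == "macrophage")
  }, 0)
  mc_sem <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - p), 2 * mc_sem + 1e-12)
})

test_that("invalid section specs are rejected", {
  bow <- data.frame(x = c(0, 100, 0, 100), y = c(0, 100, 100, 0))
  line <- data.frame(x = c(0, 100), y = c(0, 0))
  expect_error(section_spec(fascicle_polygon = bow, anterior_polyline = line,
                            posterior_polyline = line), "simple")
  expect_error(small_section_spec(pixel_size_um = 3), "unresolvable")
  expect_error(small_section_spec(macrophage_fraction = 1.2), "\\[0, 1\\]")
})

test_that("packaged presets carry the measured study conditions", {
  expect_equal(preset("P56-patellar")$macrophage_fraction, 0.079)
  expect_equal(preset("P4-patellar")$macrophage_fraction, 0.016)
  expect_equal(preset("P4-achilles")$macrophage_fraction, 0.014)
  expect_equal(preset("P56-achilles")$macrophage_fraction, 0.048)
  p1 <- preset("P1-edu")
  expect_equal(p1$edu_fraction_macrophage / p1$edu_fraction_fibroblast, 2.5)
  expect_equal(preset("ish-uniform")$coloc_kappa, 0)
  expect_equal(preset("explant-dq")$dq_positive_prob[["macrophage"]], 0.754)
  # monotone abundance across the patellar time course
  ages <- c("P4-patellar", "P14-patellar", "P28-patellar", "P56-patellar")
  fr <- vapply(ages, function(n) preset(n)$macrophage_fraction, 0)
  expect_true(all(diff(fr) > 0))
  expect_error(preset("P99-tail"), "unknown preset")
})

test_that("suspension generator honours noise-free and distributional contracts", {
  spec <- suspension_spec(n_cells = 300, seed = 8)
  for (cls in names(spec$marker_models)) {
    for (ch in c("CFP", "CD206", "F480")) spec$marker_models[[cls]][[ch]]["sd"] <- 0
  }
  tab <- generate_suspension(spec)
  for (cls in unique(tab$true_class)) {
    expect_length(unique(tab$CFP[tab$true_class == cls]), 1L)
  }
  # realized class counts within the binomial 99% interval across seeds
  p_mac <- 0.12
  n <- 2000
  counts <- vapply(1:50, function(s) {
    sum(generate_suspension(suspension_spec(n_cells = n, seed = s))$true_class == "macrophage")
  }, 0L)
  lo <- qbinom(0.005, n, p_mac)
  hi <- qbinom(0.995, n, p_mac)
  expect_gt(mean(counts >= lo & counts <= hi), 0.9)
  expect_error(generate_suspension(suspension_spec(n_cells = 0)), ">= 1")
})

test_that("qPCR generator matches the assay design and rejects bad specs", {
  gen <- generate_ct_matrix(preset("qpcr-study", seed = 4))
  expect_identical(ncol(gen$raw_ct), 80L)       # 40 samples in duplicate
  expect_identical(nrow(gen$sample_meta), 40L)
  bad_panel <- default_gene_panel()
  rownames(bad_panel)[1] <- "Abl1"
  expect_error(qpcr_spec(gene_panel = bad_panel), "housekeeping")
  expect_error(qpcr_spec(noise_sd = -1), ">= 0")
})
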