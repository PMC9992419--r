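mini_raw <- function(vals, genes = c("g1", "18s", "Abl1", "Rps17"), n_samples = 2) {
  ids <- paste0("s", seq_len(n_samples))
  raw <- matrix(vals, length(genes), 2 * n_samples,
                dimnames = list(genes, paste(rep(ids, each = 2), 1:2, sep = ".")))
  list(
    raw = raw,
    col_meta = data.frame(column = colnames(raw), sample_id = rep(ids, each = 2),
                          duplicate = rep(1:2, n_samples)),
    smeta = data.frame(sample_id = ids, population = c("macrophage", "fibroblast")[seq_len(n_samples)],
                       tissue = "limb", age = "P14", replicate = 1)
  )
}

test_that("duplicate collapse: means, single-duplicate policy, QC discrepancy flags", {
  d <- mini_raw(c(20.0, 10, 12, 14, 20.4, 10, 12, 14,  30, 10, 12, 14, NA, 10, 12, 14))
  em <- collapse_duplicates(d$raw, d$col_meta, d$smeta)
  expect_equal(em$ct["g1", "s1"], 20.2)
  expect_equal(em$ct["g1", "s2"], 30)  # one duplicate missing: keep the present value
  expect_true(any(em$qc$issue == "single_duplicate" & em$qc$sample_id == "s2"))
  # a > 1 cycle duplicate discrepancy is flagged
  wide <- mini_raw(c(19.0, 10, 12, 14, 20.4, 10, 12, 14, 20, 10, 12, 14, 20, 10, 12, 14))
  em2 <- collapse_duplicates(wide$raw, wide$col_meta, wide$smeta)
  expect_true(any(em2$qc$issue == "duplicate_discrepancy" & em2$qc$gene == "g1"))
  # unpaired duplicate column is an error
  bad <- d$col_meta[-1, ]
  expect_error(collapse_duplicates(d$raw[, -1], bad, d$smeta), "unpaired")
})

test_that("exclusion rule needs undetectables in both populations", {
  genes <- c("gA", "gB", "18s", "Abl1", "Rps17")
  ids <- paste0("s", 1:8)
  ct <- matrix(20, length(genes), 8, dimnames = list(genes, ids))
  smeta <- data.frame(sample_id = ids,
                      population = rep(c("macrophage", "fibroblast"), each = 4),
                      tissue = "limb", age = "P14", replicate = 1:8)
  ct["gA", c(1, 2, 5, 6)] <- NA   # 2 undetectable in each population -> excluded
  ct["gB", c(1, 2)] <- NA         # 2 in macrophages only -> retained
  em <- expression_matrix(ct, smeta)
  em <- apply_exclusions(em)
  expect_identical(em$gene_meta$role[em$gene_meta$gene == "gA"], "excluded")
  expect_identical(em$gene_meta$role[em$gene_meta$gene == "gB"], "panel")
  # manual list is the only route for assay-quality exclusions
  em2 <- apply_exclusions(em, manual = "gB")
  expect_identical(em2$gene_meta$role[em2$gene_meta$gene == "gB"], "excluded")
  expect_identical(em2$gene_meta$exclusion_reason[em2$gene_meta$gene == "gB"], "manual")
})

test_that("delta-CT arithmetic, plate-shift invariance, and exact noise-free recovery", {
  genes <- c("g1", "18s", "Abl1", "Rps17")
  ct <- matrix(c(9, 10, 12, 14, 12, 10, 12, 14), 4, 2, dimnames = list(genes, c("s1", "s2")))
  smeta <- data.frame(sample_id = c("s1", "s2"), population = "macrophage",
                      tissue = "limb", age = "P14", replicate = 1:2)
  em <- delta_ct(expression_matrix(ct, smeta))
  expect_equal(em$dct["g1", "s1"], 3)   # mean(10,12,14) - 9
  expect_equal(em$dct["g1", "s2"], 0)   # gene CT equals the housekeeping mean
  # adding a plate shift to one sample leaves delta-CT unchanged
  ct2 <- ct; ct2[, "s1"] <- ct2[, "s1"] + 5
  em2 <- delta_ct(expression_matrix(ct2, smeta))
  expect_equal(em2$dct, em$dct)
  # missing housekeeping CT voids the sample's delta-CTs with a warning
  ct3 <- ct; ct3["18s", "s1"] <- NA
  expect_warning(em3 <- delta_ct(expression_matrix(ct3, smeta)), "housekeeping")
  expect_true(all(is.na(em3$dct[, "s1"])))

  # noise-free generator: recovered delta-CT equals the specified offsets exactly
  g0 <- generate_ct_matrix(qpcr_spec(noise_sd = 0, duplicate_jitter_sd = 0, seed = 2))
  em0 <- delta_ct(collapse_duplicates(g0$raw_ct, g0$column_meta, g0$sample_meta))
  # undetectable design rows are excluded from the identity
  det <- (g0$truth_offsets > -15)[, em0$sample_meta$group]
  expct <- g0$truth_offsets[, em0$sample_meta$group]
  expect_equal(em0$dct[rownames(g0$truth_offsets), ][det], expct[det], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ddCT contrasts: null, antisymmetry, and the exact Mann-Whitney oracle", {
  g <- generate_ct_matrix(qpcr_spec(seed = 5))
  em <- delta_ct(apply_exclusions(collapse_duplicates(g$raw_ct, g$column_meta, g$sample_meta)))
  a <- list(population = "macrophage", tissue = "limb", age = "P56")
  b <- list(population = "macrophage", tissue = "limb", age = "P14")
  vab <- ddct_contrast(em, a, b)
  vba <- ddct_contrast(em, b, a)
  expect_equal(vab$ddct, -vba$ddct)
  expect_equal(vab$p, vba$p)
  # identical groups: ddCT 0, p 1
  same <- ddct_contrast(em, a, a)
  expect_true(all(same$ddct == 0))
  expect_true(all(same$p == 1))
  # separated groups {1..5} vs {6..10}: U = 0, p from full enumeration (252 splits)
  x <- 1:5; y <- 6:10
  p_pkg <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
  expect_equal(p_pkg, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  expect_equal(p_pkg, 2 / choose(10, 5), tolerance = 1e-12)
  # random draws also agree with the enumeration oracle
  set.seed(13)
  x2 <- rnorm(5); y2 <- rnorm(5) + 1
  expect_equal(suppressWarnings(wilcox.test(x2, y2, exact = TRUE)$p.value),
               oracle_mw_exact_p(x2, y2), tolerance = 1e-12)
})

test_that("a 2-cycle offset at n = 5/5 with 0.3-cycle noise is detected reliably", {
  hits <- vapply(1:40, function(s) {
    set.seed(4000 + s)
    a <- rnorm(5, 2, sqrt(2 * 0.3^2))  # dCT difference carries two noise draws
    b <- rnorm(5, 0, sqrt(2 * 0.3^2))
    suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value) < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("PCA: variance conservation, duplication invariance, orientation, constant genes", {
  g <- generate_ct_matrix(preset("qpcr-study", seed = 6))
  em <- delta_ct(apply_exclusions(collapse_duplicates(g$raw_ct, g$column_meta, g$sample_meta),
                                  manual = "Sema4c"))
  pca <- pca_and_cluster(em)
  expect_equal(sum(pca$var_pct), 100, tolerance = 1e-9)
  # marker orientation: macrophage markers load positively on PC1
  expect_gt(mean(pca$loadings[c("Adgre1", "Csf1r", "Mrc1"), 1]), 0)
  expect_true(all(pca$loadings[pca$gene_subset, 1] > 0))
  # duplicating every sample leaves the loadings unchanged
  em2 <- em
  em2$ct <- cbind(em$ct, em$ct)
  em2$dct <- cbind(em$dct, em$dct)
  colnames(em2$ct) <- colnames(em2$dct) <- paste0("c", seq_len(ncol(em2$ct)))
  em2$sample_meta <- rbind(em$sample_meta, em$sample_meta)
  em2$sample_meta$sample_id <- colnames(em2$ct)
  pca2 <- pca_and_cluster(em2)
  expect_equal(abs(pca2$loadings[, 1]), abs(pca$loadings[rownames(pca2$loadings), 1]),
               tolerance = 1e-8)
  # constant gene is dropped with a warning
  em3 <- em
  em3$dct["Scx", ] <- 1
  expect_warning(pca3 <- pca_and_cluster(em3), "constant gene")
  expect_false("Scx" %in% pca3$genes_used)
})

test_that("PC1 separates macrophage from fibroblast samples", {
  g <- generate_ct_matrix(preset("qpcr-study", seed = 7))
  em <- delta_ct(apply_exclusions(collapse_duplicates(g$raw_ct, g$column_meta, g$sample_meta),
                                  manual = "Sema4c"))
  pca <- pca_and_cluster(em)
  mac <- em$sample_meta$population == "macrophage"
  p <- wilcox.test(pca$scores[mac, 1], pca$scores[!mac, 1])$p.value
  expect_lt(p, 0.001)
  expect_gt(median(pca$scores[mac, 1]), median(pca$scores[!mac, 1]))
})

test_that("ligand-receptor report: age contrast, robustness to missing pairs", {
  g <- generate_ct_matrix(preset("qpcr-study", seed = 8))
  em <- delta_ct(apply_exclusions(collapse_duplicates(g$raw_ct, g$column_meta, g$sample_meta),
                                  manual = "Sema4c"))
  lr <- ligand_receptor_report(em)
  csf1 <- lr[lr$ligand == "Csf1", ]
  # fibroblast Csf1 rises from P14 to P56 (generator offsets 2 -> 4) and tests significant
  expect_gt(csf1$ligand_mean_dct[csf1$age == "P56"], csf1$ligand_mean_dct[csf1$age == "P14"])
  expect_lt(csf1$ligand_age_p[1], 0.05)
  # unknown pair gene: flagged row, no crash
  odd <- rbind(default_lr_pairs(),
               data.frame(ligand = "Nope1", receptor = "Csf1r",
                          sender = "fibroblast", receiver = "macrophage"))
  lr2 <- ligand_receptor_report(em, pairs = odd)
  bad <- lr2[lr2$ligand == "Nope1", ]
  expect_identical(unique(bad$note), "ligand_unavailable")
  expect_true(all(is.na(bad$ligand_mean_dct)))
})

test_that("null generator keeps ligand-receptor age contrasts at the type-I level", {
  panel <- default_gene_panel()
  null_panel <- matrix(rep(panel[, 1], ncol(panel)), nrow(panel),
                       dimnames = dimnames(panel))
  # same offset in every group: no age effect anywhere
  null_panel["Il2", ] <- 0; null_panel["Il2ra", ] <- 0
  hits <- vapply(1:30, function(s) {
    g <- generate_ct_matrix(qpcr_spec(gene_panel = null_panel, seed = 9000 + s))
    em <- delta_ct(collapse_duplicates(g$raw_ct, g$column_meta, g$sample_meta))
    lr <- ligand_receptor_report(em)
    one <- lr[lr$age == "P14", ]
    mean(c(one$ligand_age_p, one$receptor_age_p) < 0.05, na.rm = TRUE)
  }, 0)
  expect_lt(mean(hits), 0.10)  # near the nominal 5% rate
})
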