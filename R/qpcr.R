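# Fluidigm-style qPCR analysis: technical-duplicate collapse, exclusion
# policy, delta-CT against the mean of three housekeeping genes (higher
# delta-CT = higher expression), delta-delta-CT contrasts with exact
# Mann-Whitney tests, PCA with loading-based gene subsetting, hierarchical
# clustering, and the ligand-receptor crosstalk report.

#' Construct an expression matrix container
#' @param ct genes x samples CT matrix (missing allowed)
#' @param sample_meta data.frame with sample_id, population, tissue, age, replicate
#' @param housekeeping exactly three housekeeping gene names present in `ct`
#' @param qc optional QC flag data.frame
#' @return object of class `expression_matrix`
#' @export
expression_matrix <- function(ct, sample_meta, housekeeping = c("18s", "Abl1", "Rps17"),
                              qc = NULL) {
  if (length(housekeeping) != 3L) stopf("exactly 3 housekeeping genes required")
  if (!all(housekeeping %in% rownames(ct))) stopf("housekeeping genes missing from CT matrix")
  if (!identical(colnames(ct), sample_meta$sample_id)) {
    stopf("CT columns must match sample_meta$sample_id in order")
  }
  gene_meta <- data.frame(
    gene = rownames(ct),
    role = ifelse(rownames(ct) %in% housekeeping, "housekeeping", "panel"),
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(
    list(ct = ct, dct = NULL, sample_meta = sample_meta, gene_meta = gene_meta,
         housekeeping = housekeeping,
         qc = qc %||% data.frame(gene = character(0), sample_id = character(0),
                                 issue = character(0))),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes (%d housekeeping, %d excluded) x %d samples; dCT %s\n",
              nrow(x$ct), sum(x$gene_meta$role == "housekeeping"),
              sum(x$gene_meta$role == "excluded"), ncol(x$ct),
              if (is.null(x$dct)) "not yet computed" else "computed"))
  invisible(x)
}

#' Collapse technical duplicates into per-sample CT values
#'
#' Mean of the present duplicate values; one missing duplicate keeps the
#' present value with a QC flag; both missing stays missing. Duplicate pairs
#' whose CT values differ by more than `warn_delta` cycles get a QC warning
#' row. Duplicate pairing comes from `column_meta`; an unpaired column is an
#' error.
#'
#' @param raw_ct genes x duplicate-columns matrix
#' @param column_meta data.frame with `column` and `sample_id`
#' @param sample_meta per-sample metadata (sample_id, population, tissue, age)
#' @param housekeeping three housekeeping gene names
#' @param warn_delta duplicate-discrepancy QC threshold in cycles
#' @return [expression_matrix()]
#' @export
collapse_duplicates <- function(raw_ct, column_meta, sample_meta,
                                housekeeping = c("18s", "Abl1", "Rps17"),
                                warn_delta = 1) {
  if (!all(colnames(raw_ct) %in% column_meta$column)) {
    stopf("duplicate columns missing from column_meta")
  }
  ids <- unique(column_meta$sample_id)
  cnt <- table(column_meta$sample_id)
  if (any(cnt != 2L)) {
    stopf("unpaired duplicate column(s) for sample(s): %s",
          paste(names(cnt)[cnt != 2L], collapse = ", "))
  }
  ct <- matrix(NA_real_, nrow(raw_ct), length(ids),
               dimnames = list(rownames(raw_ct), ids))
  qc <- list()
  for (s in ids) {
    cols <- column_meta$column[column_meta$sample_id == s]
    a <- raw_ct[, cols[1]]; b <- raw_ct[, cols[2]]
    ct[, s] <- rowMeans(cbind(a, b), na.rm = TRUE)
    ct[is.nan(ct[, s]), s] <- NA_real_
    single <- xor(is.na(a), is.na(b))
    if (any(single)) {
      qc[[length(qc) + 1L]] <- data.frame(gene = rownames(raw_ct)[single], sample_id = s,
                                          issue = "single_duplicate", stringsAsFactors = FALSE)
    }
    wide <- !is.na(a) & !is.na(b) & abs(a - b) > warn_delta
    if (any(wide)) {
      qc[[length(qc) + 1L]] <- data.frame(gene = rownames(raw_ct)[wide], sample_id = s,
                                          issue = "duplicate_discrepancy", stringsAsFactors = FALSE)
    }
  }
  sample_meta <- sample_meta[match(ids, sample_meta$sample_id), , drop = FALSE]
  expression_matrix(ct, sample_meta, housekeeping,
                    qc = if (length(qc)) do.call(rbind, qc) else NULL)
}

#' Apply the gene exclusion policy
#'
#' Rule-based: a panel gene is excluded iff more than one sample in the
#' macrophage population AND more than one sample in the fibroblast
#' population are undetectable (missing, or CT at/above `detection_limit`).
#' Genes with known assay problems (e.g. abnormal amplification curves) are
#' excluded only via the `manual` list, never auto-detected.
#'
#' @param em expression_matrix
#' @param manual character vector of manually excluded genes
#' @param detection_limit undetectable threshold (CT)
#' @return em with `gene_meta$role` set to "excluded" where applicable
#' @export
apply_exclusions <- function(em, manual = character(0), detection_limit = 40) {
  undet <- is.na(em$ct) | em$ct >= detection_limit
  mac <- em$sample_meta$population == "macrophage"
  fib <- em$sample_meta$population == "fibroblast"
  panel <- em$gene_meta$role == "panel"
  rule <- panel & rowSums(undet[, mac, drop = FALSE]) > 1L &
    rowSums(undet[, fib, drop = FALSE]) > 1L
  em$gene_meta$role[rule] <- "excluded"
  em$gene_meta$exclusion_reason[rule] <- "undetectable_both_populations"
  man <- em$gene_meta$gene %in% manual
  em$gene_meta$role[man & em$gene_meta$role != "housekeeping"] <- "excluded"
  em$gene_meta$exclusion_reason[man] <- "manual"
  em
}

#' Compute delta-CT against the housekeeping mean
#'
#' `dCT(g, s) = mean(CT of the three housekeeping genes in s) - CT(g, s)`,
#' so higher delta-CT means higher expression. A sample missing any
#' housekeeping CT gets missing delta-CTs (with a warning). By construction,
#' delta-CT is invariant to adding a constant to every CT of a sample.
#'
#' @param em expression_matrix
#' @return em with `$dct` filled (panel + excluded rows; housekeeping rows NA)
#' @export
delta_ct <- function(em) {
  hk <- em$ct[em$housekeeping, , drop = FALSE]
  hk_mean <- colMeans(hk)
  bad <- !is.finite(hk_mean)
  if (any(bad)) {
    warnf("sample(s) missing housekeeping CT; their delta-CTs are missing: %s",
          paste(colnames(em$ct)[bad], collapse = ", "))
    hk_mean[bad] <- NA_real_
  }
  dct <- sweep(-em$ct, 2, hk_mean, "+")
  dct[em$housekeeping, ] <- NA_real_
  em$dct <- dct
  em
}

select_samples <- function(em, population = NULL, tissue = NULL, age = NULL) {
  sel <- rep(TRUE, nrow(em$sample_meta))
  if (!is.null(population)) sel <- sel & em$sample_meta$population %in% population
  if (!is.null(tissue)) sel <- sel & em$sample_meta$tissue %in% tissue
  if (!is.null(age)) sel <- sel & em$sample_meta$age %in% age
  sel
}

mw_p <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
}

#' Delta-delta-CT contrast with Mann-Whitney tests (volcano table)
#'
#' Per gene, `ddCT = mean dCT(group A) - mean dCT(group B)`, read directly
#' as log2 fold change of A over B. Two-sided exact Mann-Whitney U p-values
#' at these sample sizes; no multiple-testing adjustment gates results (a
#' Benjamini-Hochberg column is emitted as supplementary output only).
#' Genes with fewer than `min_n` delta-CT values in either group are
#' skipped with a note.
#'
#' @param em expression_matrix with delta-CT computed
#' @param group_a,group_b filter lists for [select_samples] fields, e.g.
#'   `list(population = "macrophage", tissue = "limb", age = "P56")`
#' @param min_n minimum per-group samples per gene
#' @return data.frame: gene, ddct (log2 fold change), p, p_bh, n_a, n_b, note
#' @export
ddct_contrast <- function(em, group_a, group_b, min_n = 3L) {
  if (is.null(em$dct)) stopf("run delta_ct first")
  sa <- do.call(select_samples, c(list(em), group_a))
  sb <- do.call(select_samples, c(list(em), group_b))
  genes <- em$gene_meta$gene[em$gene_meta$role == "panel"]
  rows <- lapply(genes, function(g) {
    a <- em$dct[g, sa]; a <- a[is.finite(a)]
    b <- em$dct[g, sb]; b <- b[is.finite(b)]
    if (length(a) < min_n || length(b) < min_n) {
      return(data.frame(gene = g, ddct = NA_real_, p = NA_real_, n_a = length(a),
                        n_b = length(b), note = "insufficient_samples",
                        stringsAsFactors = FALSE))
    }
    data.frame(gene = g, ddct = mean(a) - mean(b), p = mw_p(a, b),
               n_a = length(a), n_b = length(b), note = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out[, c("gene", "ddct", "p", "p_bh", "n_a", "n_b", "note")]
}

#' PCA of delta-CT profiles with loading-based gene subsetting
#'
#' Samples are observations, genes variables. Genes are centred and scaled
#' to unit variance before singular value decomposition; housekeeping and
#' excluded genes never enter, genes with any missing value are dropped
#' listwise, and constant genes are dropped with a warning. The PC1 sign is
#' fixed so that the macrophage marker gene set has positive mean loading
#' (PCA signs are otherwise arbitrary and tests need determinism). The gene
#' subset for downstream macrophage-only analyses is every gene with PC1
#' loading > 0. Hierarchical clustering uses correlation distance with
#' average linkage.
#'
#' @param em expression_matrix with delta-CT computed
#' @param marker_genes macrophage marker genes used to orient PC1
#' @param scaling "uv" (unit variance, default), "pareto", or "none"
#' @return list: scores (samples x PC), loadings (genes x PC), var_pct,
#'   gene_subset, hclust_samples, hclust_genes, genes_used
#' @export
pca_and_cluster <- function(em, marker_genes = c("Adgre1", "Cx3cr1", "C1qc", "Csf1r", "Mrc1"),
                            scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  if (is.null(em$dct)) stopf("run delta_ct first")
  genes <- em$gene_meta$gene[em$gene_meta$role == "panel"]
  X <- t(em$dct[genes, , drop = FALSE])  # samples x genes
  keep <- colSums(!is.finite(X)) == 0L
  X <- X[, keep, drop = FALSE]
  v <- apply(X, 2, var)
  if (any(v == 0)) {
    warnf("dropping constant gene(s): %s", paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 2L || nrow(X) < 3L) stopf("need >= 3 samples and >= 2 usable genes")
  Xc <- scale(X, center = TRUE, scale = switch(scaling,
    uv = TRUE, none = FALSE, pareto = sqrt(apply(X, 2, sd))))
  pc <- prcomp(Xc, center = FALSE, scale. = FALSE)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  mk <- intersect(marker_genes, colnames(X))
  if (length(mk) && mean(pc$rotation[mk, 1]) < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  gene_subset <- colnames(X)[pc$rotation[, 1] > 0]
  cor_dist <- function(m) as.dist(1 - cor(m))
  list(
    scores = pc$x,
    loadings = pc$rotation,
    var_pct = var_pct,
    gene_subset = gene_subset,
    hclust_samples = hclust(cor_dist(t(Xc)), method = "average"),
    hclust_genes = hclust(cor_dist(Xc), method = "average"),
    genes_used = colnames(X)
  )
}

#' Default ligand-receptor pair list
#'
#' Fibroblast-to-macrophage: Csf1-Csf1r, Il6-Il6ra, Cx3cl1-Cx3cr1;
#' macrophage-to-fibroblast: Gas6-Axl, Tgfb1-Tgfbr2, Pdgfb-Pdgfra.
#' @return data.frame: ligand, receptor, sender, receiver
#' @export
default_lr_pairs <- function() {
  data.frame(
    ligand = c("Csf1", "Il6", "Cx3cl1", "Gas6", "Tgfb1", "Pdgfb"),
    receptor = c("Csf1r", "Il6ra", "Cx3cr1", "Axl", "Tgfbr2", "Pdgfra"),
    sender = c("fibroblast", "fibroblast", "fibroblast", "macrophage", "macrophage", "macrophage"),
    receiver = c("macrophage", "macrophage", "macrophage", "fibroblast", "fibroblast", "fibroblast"),
    stringsAsFactors = FALSE
  )
}

#' Ligand-receptor crosstalk report
#'
#' One row per pair x age: mean ligand delta-CT in the sender population and
#' mean receptor delta-CT in the receiver population (given tissue), with a
#' per-gene Mann-Whitney contrast across the two ages within its own
#' population. Pairs whose genes are absent or excluded are emitted as
#' flagged rows with missing values, never an error.
#'
#' @param em expression_matrix with delta-CT computed
#' @param pairs pair table as in [default_lr_pairs()]
#' @param tissue tissue to report (default "limb")
#' @param ages the two ages to contrast
#' @return data.frame: ligand, receptor, sender, receiver, age,
#'   ligand_mean_dct, receptor_mean_dct, ligand_age_p, receptor_age_p, note
#' @export
ligand_receptor_report <- function(em, pairs = default_lr_pairs(),
                                   tissue = "limb", ages = c("P14", "P56")) {
  if (is.null(em$dct)) stopf("run delta_ct first")
  usable <- function(g) {
    g %in% em$gene_meta$gene && em$gene_meta$role[match(g, em$gene_meta$gene)] == "panel"
  }
  vals <- function(g, pop, age) {
    v <- em$dct[g, select_samples(em, population = pop, tissue = tissue, age = age)]
    v[is.finite(v)]
  }
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    ok_l <- usable(p$ligand); ok_r <- usable(p$receptor)
    note <- if (!ok_l && !ok_r) "both_genes_unavailable"
            else if (!ok_l) "ligand_unavailable"
            else if (!ok_r) "receptor_unavailable" else NA_character_
    lp <- if (ok_l) mw_p(vals(p$ligand, p$sender, ages[1]), vals(p$ligand, p$sender, ages[2])) else NA_real_
    rp <- if (ok_r) mw_p(vals(p$receptor, p$receiver, ages[1]), vals(p$receptor, p$receiver, ages[2])) else NA_real_
    for (a in ages) {
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = p$ligand, receptor = p$receptor,
        sender = p$sender, receiver = p$receiver, age = a,
        ligand_mean_dct = if (ok_l) mean(vals(p$ligand, p$sender, a)) else NA_real_,
        receptor_mean_dct = if (ok_r) mean(vals(p$receptor, p$receiver, a)) else NA_real_,
        ligand_age_p = lp, receptor_age_p = rp,
        note = note, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
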