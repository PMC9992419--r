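# Synthetic Fluidigm-style CT matrix generator. The design mirrors the
# study's expression assay: sorted macrophage and fibroblast samples from
# limb and tail tendons at P14 and P56, loaded in technical duplicate, with
# three housekeeping genes. Group effects are specified as delta-CT offsets
# (higher offset = higher expression), so the analysis stage can be tested
# by exact parameter recovery.

qpcr_groups <- function() {
  g <- expand.grid(
    population = c("macrophage", "fibroblast"),
    tissue = c("limb", "tail"),
    age = c("P14", "P56"),
    stringsAsFactors = FALSE
  )
  g$group <- paste(g$population, g$tissue, g$age, sep = "_")
  g
}

#' Default synthetic gene panel with per-group expression offsets
#'
#' Offsets are delta-CT units relative to the housekeeping mean (higher =
#' more expressed). The panel contains macrophage markers, tendon fibroblast
#' markers, the ligand-receptor pairs used in the crosstalk report, two
#' cytokines with an age trend in macrophages, Csf1 with an age trend in
#' fibroblasts, two genes rendered undetectable in both populations (the
#' rule-based exclusion case), and one gene meant for manual exclusion.
#'
#' @return matrix of offsets, genes x groups
#' @export
default_gene_panel <- function() {
  # gene, mac base, fib base, age trend in mac (P56 - P14), age trend in fib,
  # tail trend in mac
  tab <- rbind(
    c("Adgre1", 5, -5, 0.5, 0, -0.5),
    c("Cx3cr1", 6, -5, 0, 0, -1),
    c("C1qc", 6, -4, 0.5, 0, 0),
    c("Mrc1", 5, -4, 1, 0, -0.5),
    c("Lyve1", 4, -5, 0.5, 0, -1),
    c("Folr2", 4, -4, 0, 0, 0),
    c("Lair1", 4, -5, 0.5, 0, 0),
    c("Ctss", 5, -3, 0.5, 0, 0),
    c("Mmp13", 2, -2, 1, 0, -1),
    c("Csf1r", 6, -5, 0.5, 0, 0),
    c("Il6ra", 3, -2, 1, 0, 0),
    c("Tnf", 1, -3, 1.5, 0, 0),
    c("Il10", 0, -3, 1.5, 0, 0),
    c("Gas6", 4, -2, 0.5, 0, 0),
    c("Tgfb1", 3, 0, 0.5, 0, 0),
    c("Pdgfb", 2, -1, 0, 0, 0),
    c("Col1a1", -4, 8, 0, -1, 0),
    c("Prg4", -5, 3, 0, 1, 0),
    c("Tnmd", -5, 6, 0, 0, 0),
    c("Scx", -4, 5, 0, 0, 0),
    c("Csf1", -2, 2, 0, 2, 0),
    c("Il6", -1, 2, 0, 1, 0),
    c("Cx3cl1", -2, 2, 0, 0.5, 0),
    c("Axl", 0, 3, 0, 0, 0),
    c("Tgfbr2", 0, 3, 0, 0.5, 0),
    c("Pdgfra", -3, 5, 0, 0, 0),
    c("Sema4c", 1, 1, 0, 0, 0),
    c("Il2", -25, -25, 0, 0, 0),
    c("Il2ra", -25, -25, 0, 0, 0)
  )
  genes <- tab[, 1]
  num <- apply(tab[, -1, drop = FALSE], 2, as.numeric)
  grp <- qpcr_groups()
  off <- matrix(0, length(genes), nrow(grp), dimnames = list(genes, grp$group))
  for (j in seq_len(nrow(grp))) {
    base <- if (grp$population[j] == "macrophage") num[, 1] else num[, 2]
    age <- if (grp$age[j] == "P56") {
      if (grp$population[j] == "macrophage") num[, 3] else num[, 4]
    } else 0
    tail_t <- if (grp$tissue[j] == "tail" && grp$population[j] == "macrophage") num[, 5] else 0
    off[, j] <- base + age + tail_t
  }
  off
}

#' Specification of a synthetic qPCR run
#'
#' @param gene_panel offsets matrix, genes x groups (see [default_gene_panel()];
#'   group columns `population_tissue_age`)
#' @param housekeeping_genes exactly three housekeeping gene names (must not
#'   appear in the panel)
#' @param ct_baseline housekeeping CT centre
#' @param noise_sd per-reaction biological/technical CT noise SD (>= 0)
#' @param n_samples_per_group replicates per population x tissue x age group (>= 2)
#' @param detection_limit_ct CT at or above which a reaction reads as
#'   undetectable (emitted missing)
#' @param duplicate_jitter_sd SD of the technical-duplicate jitter
#' @param seed integer seed
#' @return object of class `qpcr_spec`
#' @export
qpcr_spec <- function(gene_panel = default_gene_panel(),
                      housekeeping_genes = c("18s", "Abl1", "Rps17"),
                      ct_baseline = 22,
                      noise_sd = 0.5,
                      n_samples_per_group = 5,
                      detection_limit_ct = 40,
                      duplicate_jitter_sd = 0.25,
                      seed = 1L) {
  spec <- structure(as.list(environment()), class = "qpcr_spec")
  validate_qpcr_spec(spec)
  spec
}

validate_qpcr_spec <- function(spec) {
  if (length(spec$housekeeping_genes) != 3L) stopf("exactly 3 housekeeping genes required")
  if (spec$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (spec$n_samples_per_group < 2L) stopf("n_samples_per_group must be >= 2")
  hk_in_panel <- intersect(spec$housekeeping_genes, rownames(spec$gene_panel))
  if (length(hk_in_panel) && any(spec$gene_panel[hk_in_panel, ] != 0)) {
    stopf("housekeeping gene(s) listed in the panel with nonzero offsets: %s",
          paste(hk_in_panel, collapse = ", "))
  }
  invisible(spec)
}

#' Generate a synthetic CT matrix with technical duplicates
#'
#' Panel CT = `ct_baseline - group offset + noise`; housekeeping CT =
#' `ct_baseline + noise`. Every sample is emitted as two technical-duplicate
#' columns with independent duplicate jitter; readings at or above the
#' detection limit are emitted as missing.
#'
#' @param spec qpcr_spec
#' @return list: `raw_ct` (genes x duplicate-columns matrix), `column_meta`
#'   (column, sample_id, duplicate), `sample_meta` (sample_id, population,
#'   tissue, age, replicate), `truth_offsets` (the spec's offsets), `spec`
#' @export
generate_ct_matrix <- function(spec) {
  validate_qpcr_spec(spec)
  grp <- qpcr_groups()
  sample_meta <- do.call(rbind, lapply(seq_len(nrow(grp)), function(j) {
    data.frame(
      sample_id = sprintf("%s_r%d", grp$group[j], seq_len(spec$n_samples_per_group)),
      population = grp$population[j], tissue = grp$tissue[j], age = grp$age[j],
      replicate = seq_len(spec$n_samples_per_group),
      group = grp$group[j],
      stringsAsFactors = FALSE
    )
  }))
  genes <- c(rownames(spec$gene_panel), spec$housekeeping_genes)
  ns <- nrow(sample_meta)
  with_seed(spec$seed, {
    ct <- matrix(NA_real_, length(genes), ns, dimnames = list(genes, sample_meta$sample_id))
    for (s in seq_len(ns)) {
      off <- spec$gene_panel[, sample_meta$group[s]]
      ct[seq_len(nrow(spec$gene_panel)), s] <-
        spec$ct_baseline - off + rnorm(nrow(spec$gene_panel), 0, spec$noise_sd)
      ct[spec$housekeeping_genes, s] <- spec$ct_baseline + rnorm(3L, 0, spec$noise_sd)
    }
    raw <- matrix(NA_real_, length(genes), 2L * ns,
                  dimnames = list(genes, paste(rep(sample_meta$sample_id, each = 2L),
                                               rep(1:2, ns), sep = ".")))
    for (s in seq_len(ns)) {
      for (d in 1:2) {
        raw[, 2L * (s - 1L) + d] <- ct[, s] + rnorm(length(genes), 0, spec$duplicate_jitter_sd)
      }
    }
    raw[raw >= spec$detection_limit_ct] <- NA_real_
    column_meta <- data.frame(
      column = colnames(raw),
      sample_id = rep(sample_meta$sample_id, each = 2L),
      duplicate = rep(1:2, ns),
      stringsAsFactors = FALSE
    )
    list(raw_ct = raw, column_meta = column_meta, sample_meta = sample_meta,
         truth_offsets = spec$gene_panel, spec = spec)
  })
}
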