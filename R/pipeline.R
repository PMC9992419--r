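# Pipeline plumbing: YAML configuration, stage dispatch, and versioned
# artifact + report output. Every stage writes its tabular results as CSV
# and a JSON report of all parameters actually used, so any number in any
# report is reproducible from the logged parameter set alone. Output tables
# carry micrometre coordinates only; pixel coordinates never leave the
# image modules.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "tenomac-out",
    synth = list(preset = "P56-patellar", n_sections = 2L),
    segment = list(min_area_um2 = 8, max_area_um2 = 200, threshold_mode = "otsu",
                   gfp_threshold = 60, edu_threshold = 100),
    abundance = list(flag = "gfp_pos"),
    depth = list(normalization = "within_quartile_pct"),
    edu = list(),
    ish = list(preset = "ish-colocalized", n_sections = 2L, unit_um = 50),
    qpcr = list(preset = "qpcr-study", manual_exclusions = "Sema4c",
                contrast = list(population = "macrophage", tissue = "limb",
                                ages = c("P56", "P14"))),
    internalize = list(preset = "explant-dq", n_tables = 2L,
                       thresholds = c(CFP = 100, CD206 = 100, F480 = 100, DQ = 100))
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML file with a `seed`, an `out_dir`, and one parameter block per stage;
#' omitted keys fall back to the packaged defaults. Unknown stage blocks and
#' missing required keys are hard errors listing the offending keys.
#'
#' @param path YAML file path, or `NULL` for the packaged default config
#' @return validated config list
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file does not exist: %s", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stopf("unknown config block(s): %s", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  required <- list(
    synth = c("preset", "n_sections"),
    segment = c("min_area_um2", "max_area_um2", "threshold_mode", "gfp_threshold"),
    ish = c("preset", "n_sections", "unit_um"),
    qpcr = c("preset", "manual_exclusions", "contrast"),
    internalize = c("preset", "n_tables", "thresholds")
  )
  for (blk in names(required)) {
    missing <- setdiff(required[[blk]], names(cfg[[blk]]))
    if (length(missing)) {
      stopf("config block '%s' is missing required key(s): %s",
            blk, paste(missing, collapse = ", "))
    }
  }
  if (is.null(cfg$seed)) stopf("config is missing required key(s): seed")
  invisible(cfg)
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_report <- function(dir, stage, params) {
  jsonlite::write_json(list(stage = stage, parameters = params),
                       file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

write_csv_plain <- function(df, path) write.csv(df, path, row.names = FALSE)

section_seed <- function(base, k) as.integer(base) * 1000L + as.integer(k)

#' Run one pipeline stage (or all of them)
#'
#' Stages: `synth` (generate preset sections + truth), `segment` (nuclear
#' segmentation, measurement, run-level classification), `abundance`
#' (in-ROI quantification + group comparison), `depth` (EDM quartile
#' profiling + uniformity tests), `edu` (per-animal EdU fractions + paired
#' test), `ish` (duplex ISH generation, deconvolution, grid Spearman),
#' `qpcr` (CT matrix generation + full expression analysis), `internalize`
#' (explant suspension classification + DQ summary), `all`. Rerunning a
#' stage with the same config and seed reproduces its CSV reports byte for
#' byte.
#'
#' @param name stage name
#' @param config config list from [read_config()]
#' @return invisible list of the stage's principal result objects
#' @export
run_stage <- function(name, config = read_config()) {
  stages <- c("synth", "segment", "abundance", "depth", "edu", "ish", "qpcr", "internalize")
  if (identical(name, "all")) {
    res <- lapply(stages, run_stage, config = config)
    names(res) <- stages
    return(invisible(res))
  }
  if (!name %in% stages) {
    stopf("unknown stage '%s'; available: %s, all", name, paste(stages, collapse = ", "))
  }
  validate_config(config)
  fn <- switch(name,
    synth = stage_synth, segment = stage_segment, abundance = stage_abundance,
    depth = stage_depth, edu = stage_edu, ish = stage_ish,
    qpcr = stage_qpcr, internalize = stage_internalize
  )
  invisible(fn(config))
}

stage_synth <- function(cfg) {
  d <- stage_dir(cfg, "synth")
  n <- cfg$synth$n_sections
  # paths are stored relative to out_dir so reports are location-independent
  manifest <- data.frame(
    section_id = sprintf("S%02d", seq_len(n)),
    animal_id = sprintf("A%02d", seq_len(n)),
    image = file.path("synth", sprintf("section_%02d.tif", seq_len(n))),
    roi = file.path("synth", sprintf("section_%02d_roi.json", seq_len(n))),
    seed = section_seed(cfg$seed, seq_len(n)),
    preset = cfg$synth$preset,
    stringsAsFactors = FALSE
  )
  truths <- list()
  for (k in seq_len(n)) {
    gen <- generate_section(preset(cfg$synth$preset, seed = manifest$seed[k]))
    write_section(gen$image, file.path(cfg$out_dir, manifest$image[k]),
                  roi_path = file.path(cfg$out_dir, manifest$roi[k]))
    t <- gen$truth
    t$section_id <- manifest$section_id[k]
    truths[[k]] <- t
  }
  write_csv_plain(manifest, file.path(d, "manifest.csv"))
  write_csv_plain(do.call(rbind, truths), file.path(d, "truth.csv"))
  write_report(d, "synth", cfg["synth"])
  list(manifest = manifest)
}

read_manifest <- function(cfg) {
  p <- file.path(cfg$out_dir, "synth", "manifest.csv")
  if (!file.exists(p)) stopf("run the synth stage first (missing %s)", p)
  read.csv(p, stringsAsFactors = FALSE)
}

stage_segment <- function(cfg) {
  d <- stage_dir(cfg, "segment")
  manifest <- read_manifest(cfg)
  sg <- cfg$segment
  recs <- list()
  for (k in seq_len(nrow(manifest))) {
    img <- read_section(file.path(cfg$out_dir, manifest$image[k]),
                        roi_path = file.path(cfg$out_dir, manifest$roi[k]))
    lab <- segment_nuclei(img$channels$hoechst, img$pixel_size_um,
                          min_area_um2 = sg$min_area_um2, max_area_um2 = sg$max_area_um2,
                          threshold_mode = sg$threshold_mode, threshold = sg$threshold)
    r <- measure_nuclei(lab, img$channels, img$pixel_size_um)
    r <- classify_by_threshold(r, "gfp", sg$gfp_threshold)
    if ("edu" %in% names(img$channels)) {
      r <- classify_by_threshold(r, "edu", sg$edu_threshold %||% 100)
    }
    r <- flag_in_roi(r, img$rois$polygons$fascicle)
    r$section_id <- manifest$section_id[k]
    r$animal_id <- manifest$animal_id[k]
    recs[[k]] <- r
    lab_img <- lab
    attributes(lab_img) <- attributes(lab_img)["dim"]
    write_section(section_image(list(labels = lab_img), img$pixel_size_um),
                  file.path(d, sprintf("labels_%02d.tif", k)))
  }
  records <- do.call(rbind, recs)
  write_csv_plain(records, file.path(d, "records.csv"))
  write_report(d, "segment", cfg["segment"])
  list(records = records)
}

read_records <- function(cfg) {
  p <- file.path(cfg$out_dir, "segment", "records.csv")
  if (!file.exists(p)) stopf("run the segment stage first (missing %s)", p)
  read.csv(p, stringsAsFactors = FALSE)
}

stage_abundance <- function(cfg) {
  d <- stage_dir(cfg, "abundance")
  manifest <- read_manifest(cfg)
  records <- read_records(cfg)
  res <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(k) {
    roi <- read_roi_json(file.path(cfg$out_dir, manifest$roi[k]))
    quantify_section(records[records$section_id == manifest$section_id[k], ],
                     roi$polygons$fascicle, flag = cfg$abundance$flag,
                     section_id = manifest$section_id[k])
  }))
  write_csv_plain(res, file.path(d, "abundance.csv"))
  write_report(d, "abundance", cfg["abundance"])
  list(abundance = res)
}

stage_depth <- function(cfg) {
  d <- stage_dir(cfg, "depth")
  manifest <- read_manifest(cfg)
  records <- read_records(cfg)
  profiles <- list()
  for (k in seq_len(nrow(manifest))) {
    img <- read_section(file.path(cfg$out_dir, manifest$image[k]),
                        roi_path = file.path(cfg$out_dir, manifest$roi[k]))
    lab <- read_section(file.path(cfg$out_dir, "segment", sprintf("labels_%02d.tif", k)))
    labm <- lab$channels$labels
    storage.mode(labm) <- "integer"
    edm <- build_edm(nrow(labm), ncol(labm), img$rois$polylines$anterior,
                     img$rois$polylines$posterior, img$pixel_size_um)
    r <- records[records$section_id == manifest$section_id[k], ]
    r <- assign_depth(r, labm, edm, roi_polygon = img$rois$polygons$fascicle,
                      pixel_size_um = img$pixel_size_um)
    pr <- quartile_profile(r[r$in_roi, ], section_id = manifest$section_id[k],
                           normalization = cfg$depth$normalization)
    pr$animal_id <- manifest$animal_id[k]
    profiles[[k]] <- pr
  }
  profiles <- do.call(rbind, profiles)
  write_csv_plain(profiles, file.path(d, "profiles.csv"))
  rep <- if (length(unique(profiles$animal_id)) >= 2L) {
    tryCatch(test_uniformity(profiles), error = function(e) list(error = conditionMessage(e)))
  } else list(note = "uniformity test needs >= 2 animals")
  jsonlite::write_json(list(stage = "depth", parameters = cfg["depth"], uniformity = rep),
                       file.path(d, "report.json"), digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  list(profiles = profiles, uniformity = rep)
}

stage_edu <- function(cfg) {
  d <- stage_dir(cfg, "edu")
  records <- read_records(cfg)
  if (!"edu_pos" %in% names(records)) stopf("records carry no EdU flags; use an EdU preset")
  fr <- edu_fractions(records)
  write_csv_plain(fr, file.path(d, "edu_fractions.csv"))
  test <- tryCatch(compare_proliferation(fr), error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(list(stage = "edu", parameters = cfg["edu"], paired_test = test),
                       file.path(d, "report.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
  list(fractions = fr, test = test)
}

stage_ish <- function(cfg) {
  d <- stage_dir(cfg, "ish")
  n <- cfg$ish$n_sections
  per <- list()
  tables <- list()
  for (k in seq_len(n)) {
    spec <- preset(cfg$ish$preset, seed = section_seed(cfg$seed, k))
    gen <- generate_duplex_ish(spec)
    ctrl <- generate_ish_controls(spec)
    sm <- estimate_stain_vectors(ctrl, spec$background_white)
    dec <- deconvolve(gen$rgb, sm, spec$background_white)
    tab <- grid_intensities(list(csf1r = dec$csf1r, csf1 = dec$csf1,
                                 hoechst = dec$counterstain),
                            spec$fascicle_polygon, spec$pixel_size_um,
                            unit_um = cfg$ish$unit_um)
    tab$section_id <- sprintf("S%02d", k)
    tables[[k]] <- tab
    per[[k]] <- coloc_spearman(tab, "csf1r", "csf1")
  }
  grid <- do.call(rbind, tables)
  write_csv_plain(grid, file.path(d, "grid_intensities.csv"))
  agg <- aggregate_spearman(per)
  jsonlite::write_json(list(stage = "ish", parameters = cfg["ish"],
                            per_section = per, aggregate = agg),
                       file.path(d, "report.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
  list(grid = grid, spearman = agg)
}

stage_qpcr <- function(cfg) {
  d <- stage_dir(cfg, "qpcr")
  gen <- generate_ct_matrix(preset(cfg$qpcr$preset, seed = cfg$seed))
  em <- collapse_duplicates(gen$raw_ct, gen$column_meta, gen$sample_meta,
                            housekeeping = gen$spec$housekeeping_genes)
  em <- apply_exclusions(em, manual = cfg$qpcr$manual_exclusions,
                         detection_limit = gen$spec$detection_limit_ct)
  em <- delta_ct(em)
  ct <- cfg$qpcr$contrast
  volcano <- ddct_contrast(em,
                           list(population = ct$population, tissue = ct$tissue, age = ct$ages[1]),
                           list(population = ct$population, tissue = ct$tissue, age = ct$ages[2]))
  pca <- pca_and_cluster(em)
  lr <- ligand_receptor_report(em)
  dct_df <- data.frame(gene = rownames(em$dct), em$dct, check.names = FALSE)
  write_csv_plain(dct_df, file.path(d, "delta_ct.csv"))
  write_csv_plain(volcano, file.path(d, "volcano.csv"))
  write_csv_plain(data.frame(sample_id = rownames(pca$scores), pca$scores, check.names = FALSE),
                  file.path(d, "pca_scores.csv"))
  write_csv_plain(data.frame(gene = rownames(pca$loadings), pca$loadings, check.names = FALSE),
                  file.path(d, "pca_loadings.csv"))
  write_csv_plain(lr, file.path(d, "ligand_receptor.csv"))
  jsonlite::write_json(list(stage = "qpcr", parameters = cfg["qpcr"],
                            var_pct = pca$var_pct, gene_subset = pca$gene_subset),
                       file.path(d, "report.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
  list(em = em, volcano = volcano, pca = pca, lr = lr)
}

stage_internalize <- function(cfg) {
  d <- stage_dir(cfg, "internalize")
  thr <- unlist(cfg$internalize$thresholds)
  res <- list()
  for (k in seq_len(cfg$internalize$n_tables)) {
    tab <- generate_suspension(preset(cfg$internalize$preset,
                                      seed = section_seed(cfg$seed, k)))
    s <- dq_positivity(classify_markers(tab, thr))
    s$table_id <- sprintf("T%02d", k)
    res[[k]] <- s
  }
  out <- do.call(rbind, res)
  write_csv_plain(out, file.path(d, "dq_summary.csv"))
  write_report(d, "internalize", cfg["internalize"])
  list(summary = out)
}
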