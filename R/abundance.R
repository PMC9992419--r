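# In-fascicle abundance: percentage of reporter-positive nuclei and spatial
# densities, restricted to the manually-outlined fascicle ROI (the peritenon
# is excluded from quantification), plus the ANOVA/Tukey comparison battery.

#' Quantify reporter-positive abundance inside the fascicle ROI
#'
#' Only records whose centroid lies strictly inside the polygon are counted.
#' Densities are cells per mm^2 of ROI area (polygon geometry, um^2 / 1e6).
#' With zero in-ROI cells the percentage is undefined and emitted as `NA`.
#'
#' @param records nucleus records carrying centroids and the positivity flag
#' @param fascicle_polygon simple polygon (data.frame x, y, um)
#' @param flag name of the logical positivity column (default "gfp_pos")
#' @param section_id identifier copied into the result
#' @return one-row data.frame: section_id, n_total, n_pos, pct_pos,
#'   density_total, density_pos, density_neg, roi_area_mm2
#' @export
quantify_section <- function(records, fascicle_polygon, flag = "gfp_pos", section_id = NA_character_) {
  if (!polygon_is_simple(fascicle_polygon)) stopf("fascicle polygon is not simple")
  area_mm2 <- polygon_area(fascicle_polygon) / 1e6
  if (area_mm2 <= 0) stopf("zero-area fascicle polygon")
  if (!flag %in% names(records)) stopf("flag column '%s' absent from records", flag)
  inside <- if (nrow(records)) points_in_polygon(records$x_um, records$y_um, fascicle_polygon) else logical(0)
  n_total <- sum(inside)
  n_pos <- sum(inside & records[[flag]])
  data.frame(
    section_id = section_id,
    n_total = n_total,
    n_pos = n_pos,
    pct_pos = if (n_total > 0) 100 * n_pos / n_total else NA_real_,
    density_total = n_total / area_mm2,
    density_pos = n_pos / area_mm2,
    density_neg = (n_total - n_pos) / area_mm2,
    roi_area_mm2 = area_mm2,
    stringsAsFactors = FALSE
  )
}

#' Flag records by ROI membership
#' @inheritParams quantify_section
#' @return records with a logical `in_roi` column
#' @export
flag_in_roi <- function(records, fascicle_polygon) {
  records$in_roi <- if (nrow(records)) {
    points_in_polygon(records$x_um, records$y_um, fascicle_polygon)
  } else logical(0)
  records
}

#' Compare per-animal means across groups (ANOVA + Tukey battery)
#'
#' Runs the preflight checks (Shapiro-Wilk normality per group, Levene
#' homogeneity of variances) followed by one-way ANOVA with Tukey's post hoc
#' test at alpha = 0.05. A Kruskal-Wallis fallback is available but off by
#' default, matching the parametric analysis used for these endpoints.
#'
#' @param values named list: group -> numeric vector of per-animal means
#'   (>= 2 groups with >= 2 values each)
#' @param nonparametric_fallback if TRUE and any Shapiro-Wilk p < 0.05, a
#'   Kruskal-Wallis p is added to the report (the ANOVA is still reported)
#' @return list: shapiro_p (per group), levene_p, anova (F, df, p), tukey
#'   (data.frame of pairwise adjusted p), optionally kruskal_p
#' @export
compare_groups <- function(values, nonparametric_fallback = FALSE) {
  if (length(values) < 2L) stopf("need at least 2 groups")
  sizes <- vapply(values, length, 0L)
  if (any(sizes < 2L)) stopf("every group needs at least 2 values")
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    group = factor(rep(names(values), sizes))
  )
  shapiro_p <- vapply(values, function(v) {
    if (length(unique(v)) < 3L) return(NA_real_)  # degenerate for Shapiro-Wilk
    tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  # suppress the perfect-fit warning Levene emits on (near-)degenerate groups
  levene_p <- tryCatch(suppressWarnings(car::leveneTest(value ~ group, data = df)[1, "Pr(>F)"]),
                       error = function(e) NA_real_)
  if (var(df$value) == 0) {
    # every observation identical: no between- or within-group variability
    pairs <- utils::combn(names(values), 2, paste, collapse = "-")
    return(list(
      shapiro_p = shapiro_p, levene_p = levene_p,
      anova = list(F = 0, df = c(length(values) - 1L, nrow(df) - length(values)), p = 1),
      tukey = data.frame(contrast = pairs, diff = 0, lwr = 0, upr = 0, p_adj = 1),
      alpha = 0.05
    ))
  }
  fit <- aov(value ~ group, data = df)
  at <- anova(fit)
  tk <- TukeyHSD(fit)$group
  report <- list(
    shapiro_p = shapiro_p,
    levene_p = levene_p,
    anova = list(F = at[1, "F value"], df = unname(at[["Df"]]), p = at[1, "Pr(>F)"]),
    tukey = data.frame(
      contrast = rownames(tk), diff = tk[, "diff"],
      lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
      row.names = NULL
    ),
    alpha = 0.05
  )
  if (nonparametric_fallback && any(shapiro_p < 0.05, na.rm = TRUE)) {
    report$kruskal_p <- stats::kruskal.test(value ~ group, data = df)$p.value
  }
  report
}
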