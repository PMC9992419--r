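# DQ-collagen internalization quantification: run-level marker thresholds
# classify explant-derived cells, then DQ positivity is reported within the
# CD206+, F4/80+, and Col1CFP+ populations (plus the joint-population
# rarity checks).

#' Flag cells by per-channel run-level thresholds
#'
#' `flag = intensity > threshold`, with the same thresholds applied
#' uniformly to every cell; a cell may carry several flags.
#'
#' @param table per-cell intensity table with columns CFP, CD206, F480, DQ
#' @param thresholds named numeric vector of finite thresholds for those
#'   channels
#' @return table with logical columns cfp_pos, cd206_pos, f480_pos, dq_pos
#' @export
classify_markers <- function(table,
                             thresholds = c(CFP = 100, CD206 = 100, F480 = 100, DQ = 100)) {
  for (ch in c("CFP", "CD206", "F480", "DQ")) {
    if (!ch %in% names(table)) stopf("channel '%s' missing from table", ch)
    if (!ch %in% names(thresholds) || is.na(thresholds[[ch]])) {
      stopf("no threshold supplied for channel '%s'", ch)
    }
  }
  table$cfp_pos <- table$CFP > thresholds[["CFP"]]
  table$cd206_pos <- table$CD206 > thresholds[["CD206"]]
  table$f480_pos <- table$F480 > thresholds[["F480"]]
  table$dq_pos <- table$DQ > thresholds[["DQ"]]
  table
}

pct_within <- function(num, den) {
  n <- sum(den)
  if (n == 0L) return(c(pct = NA_real_, n = 0))
  c(pct = 100 * sum(num & den) / n, n = n)
}

#' DQ positivity summary within marker-defined populations
#'
#' Reports the percentage of DQ+ cells within the CD206+, F4/80+, and
#' Col1CFP+ populations, plus the joint-population rarity percentages
#' (%CD206+ and %F4/80+ among CFP+ cells). Empty denominator populations
#' are emitted as `NA` with their size 0.
#'
#' @param table flagged table from [classify_markers()]
#' @return data.frame: measure, pct, n_denominator
#' @export
dq_positivity <- function(table) {
  if (nrow(table) == 0L) stopf("empty cell table")
  need <- c("cfp_pos", "cd206_pos", "f480_pos", "dq_pos")
  if (!all(need %in% names(table))) stopf("run classify_markers first")
  rows <- rbind(
    dq_in_cd206 = pct_within(table$dq_pos, table$cd206_pos),
    dq_in_f480 = pct_within(table$dq_pos, table$f480_pos),
    dq_in_cfp = pct_within(table$dq_pos, table$cfp_pos),
    cd206_in_cfp = pct_within(table$cd206_pos, table$cfp_pos),
    f480_in_cfp = pct_within(table$f480_pos, table$cfp_pos)
  )
  data.frame(
    measure = rownames(rows),
    pct = rows[, "pct"],
    n_denominator = rows[, "n"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
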