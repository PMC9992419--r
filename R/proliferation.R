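# EdU proliferation comparison: labelled fractions within the GFP+
# macrophage and GFP- fibroblast populations, pooled over each animal's
# sections, compared by paired t-test.

#' Per-animal EdU-labelled fractions
#'
#' Counts are pooled over all of an animal's sections before fractions are
#' formed (small per-section counts make per-section fractions unstable at
#' neonatal ages). Only in-ROI records are used when an `in_roi` column is
#' present. A zero-denominator population yields `NA` fractions and excludes
#' the animal from ratio reporting with a warning.
#'
#' @param records nucleus records with `animal_id`, `gfp_pos`, `edu_pos`
#'   columns (and optionally `in_roi`)
#' @return data.frame: animal_id, n_gfp_pos, n_gfp_pos_edu, n_gfp_neg,
#'   n_gfp_neg_edu, frac_edu_mac, frac_edu_fib, ratio
#' @export
edu_fractions <- function(records) {
  need <- c("animal_id", "gfp_pos", "edu_pos")
  if (!all(need %in% names(records))) {
    stopf("records need columns: %s", paste(need, collapse = ", "))
  }
  if ("in_roi" %in% names(records)) records <- records[records$in_roi, , drop = FALSE]
  out <- do.call(rbind, lapply(split(records, records$animal_id), function(r) {
    n_mac <- sum(r$gfp_pos)
    n_fib <- sum(!r$gfp_pos)
    data.frame(
      animal_id = r$animal_id[1],
      n_gfp_pos = n_mac,
      n_gfp_pos_edu = sum(r$gfp_pos & r$edu_pos),
      n_gfp_neg = n_fib,
      n_gfp_neg_edu = sum(!r$gfp_pos & r$edu_pos),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out$frac_edu_mac <- ifelse(out$n_gfp_pos > 0, out$n_gfp_pos_edu / out$n_gfp_pos, NA_real_)
  out$frac_edu_fib <- ifelse(out$n_gfp_neg > 0, out$n_gfp_neg_edu / out$n_gfp_neg, NA_real_)
  out$ratio <- ifelse(is.finite(out$frac_edu_mac) & is.finite(out$frac_edu_fib) & out$frac_edu_fib > 0,
                      out$frac_edu_mac / out$frac_edu_fib, NA_real_)
  if (anyNA(out$frac_edu_mac) || anyNA(out$frac_edu_fib)) {
    warnf("animal(s) with an empty population excluded from ratio reporting")
  }
  out
}

#' Paired comparison of macrophage vs fibroblast EdU fractions
#'
#' Paired t-test on per-animal (macrophage, fibroblast) EdU fractions.
#' Animals missing either fraction are dropped; >= 2 complete pairs required.
#'
#' @param results output of [edu_fractions()]
#' @return list: t, df, p, mean_diff, n_pairs
#' @export
compare_proliferation <- function(results) {
  ok <- is.finite(results$frac_edu_mac) & is.finite(results$frac_edu_fib)
  m <- results$frac_edu_mac[ok]
  f <- results$frac_edu_fib[ok]
  if (length(m) < 2L) stopf("need >= 2 animals with both fractions")
  if (all(m == f)) {
    # degenerate identical pairs: t = 0, p = 1 by convention
    return(list(t = 0, df = length(m) - 1L, p = 1, mean_diff = 0, n_pairs = length(m)))
  }
  tt <- t.test(m, f, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), n_pairs = length(m))
}
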