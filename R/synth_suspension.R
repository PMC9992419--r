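# Synthetic explant cell-suspension generator: per-cell marker intensities
# (CFP, CD206, F4/80, DQ collagen) drawn from class-conditional Gaussian
# models, with a hidden DQ-internalization state per cell. Emulates
# chamber-slide imaging of digested tendon explants.

#' Specification of a synthetic explant cell suspension
#'
#' @param n_cells number of cells (>= 1)
#' @param class_fractions named fractions over fibroblast / macrophage /
#'   other; must sum to 1
#' @param marker_models per class, per channel `c(mean, sd)` intensity model
#'   for channels CFP, CD206, F480
#' @param dq_models intensity models for the DQ channel given the hidden
#'   internalization state (`pos` / `neg`)
#' @param dq_positive_prob named per-class probability of the DQ+ state
#' @param seed integer seed
#' @return object of class `suspension_spec`
#' @export
suspension_spec <- function(n_cells = 5000,
                            class_fractions = c(fibroblast = 0.6, macrophage = 0.12, other = 0.28),
                            marker_models = list(
                              fibroblast = list(CFP = c(mean = 200, sd = 20),
                                                CD206 = c(mean = 40, sd = 20),
                                                F480 = c(mean = 40, sd = 20)),
                              macrophage = list(CFP = c(mean = 20, sd = 15),
                                                CD206 = c(mean = 220, sd = 25),
                                                F480 = c(mean = 220, sd = 25)),
                              other = list(CFP = c(mean = 20, sd = 15),
                                           CD206 = c(mean = 40, sd = 20),
                                           F480 = c(mean = 50, sd = 20))
                            ),
                            dq_models = list(pos = c(mean = 220, sd = 25),
                                             neg = c(mean = 30, sd = 18)),
                            dq_positive_prob = c(fibroblast = 0.005, macrophage = 0.5, other = 0),
                            seed = 1L) {
  spec <- structure(as.list(environment()), class = "suspension_spec")
  validate_suspension_spec(spec)
  spec
}

validate_suspension_spec <- function(spec) {
  if (spec$n_cells < 1L) stopf("n_cells must be >= 1")
  if (abs(sum(spec$class_fractions) - 1) > 1e-8) stopf("class_fractions must sum to 1")
  if (any(spec$dq_positive_prob < 0 | spec$dq_positive_prob > 1)) {
    stopf("dq_positive_prob values must lie in [0, 1]")
  }
  if (!all(names(spec$class_fractions) %in% names(spec$marker_models))) {
    stopf("every class needs a marker model")
  }
  invisible(spec)
}

#' Generate a synthetic explant cell-suspension intensity table
#'
#' One row per cell with four intensity columns (CFP, CD206, F480, DQ) and
#' hidden truth columns (class, DQ internalization state). Class draws are
#' independent Bernoulli/multinomial from the spec fractions; intensities
#' are class-conditional Gaussians truncated at zero.
#'
#' @param spec suspension_spec
#' @return data.frame: cell_id, CFP, CD206, F480, DQ, true_class, true_dq
#' @export
generate_suspension <- function(spec) {
  validate_suspension_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_cells
    cls <- sample(names(spec$class_fractions), n, replace = TRUE, prob = spec$class_fractions)
    dq_state <- rbinom(n, 1L, spec$dq_positive_prob[cls]) == 1L
    draw <- function(models, channel) {
      mu <- vapply(cls, function(cc) models[[cc]][[channel]][["mean"]], numeric(1))
      sg <- vapply(cls, function(cc) models[[cc]][[channel]][["sd"]], numeric(1))
      pmax(rnorm(n, mu, sg), 0)
    }
    dqm <- ifelse(dq_state, spec$dq_models$pos[["mean"]], spec$dq_models$neg[["mean"]])
    dqs <- ifelse(dq_state, spec$dq_models$pos[["sd"]], spec$dq_models$neg[["sd"]])
    data.frame(
      cell_id = seq_len(n),
      CFP = draw(spec$marker_models, "CFP"),
      CD206 = draw(spec$marker_models, "CD206"),
      F480 = draw(spec$marker_models, "F480"),
      DQ = pmax(rnorm(n, dqm, dqs), 0),
      true_class = cls,
      true_dq = dq_state,
      stringsAsFactors = FALSE
    )
  })
}
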