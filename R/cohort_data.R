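# Published molecular-marker counts for a cohort of 168 biliary tract
# cancers (83 intrahepatic CCA, 44 extrahepatic CCA, 41 gallbladder
# adenocarcinoma), shipped so that the cohort statistics can be
# recomputed without access to per-sample data. Rows are the three
# diagnostic groups; columns are present / absent; samples whose status
# could not be determined are excluded from the denominators.

#' Bundled biliary-tract-cancer cohort marker counts
#'
#' Per-marker present/absent counts by diagnostic group (iCCA, eCCA,
#' GBA) for a profiled cohort of 168 biliary tract cancers, plus the
#' gender counts reconstructed from the reported percentages. These are
#' the inputs for the cohort-level contingency statistics and pooled
#' prevalence summaries.
#'
#' @return list with `markers` (named list of 3x2 matrices), `gender`
#'   (3x2 matrix female/male) and `group_n` (enrolled samples per group).
#' @export
btc_cohort_counts <- function() {
  g <- c("iCCA", "eCCA", "GBA")
  m <- function(...) {
    x <- matrix(c(...), nrow = 3, byrow = TRUE,
                dimnames = list(g, c("present", "absent")))
    storage.mode(x) <- "integer"
    x
  }
  list(
    markers = list(
      MSI        = m(2, 76, 0, 41, 1, 38),
      ERBB2_amp  = m(2, 74, 0, 44, 3, 38),
      FGFR2      = m(17, 65, 1, 42, 0, 40),
      IDH1_2     = m(23, 59, 0, 43, 0, 40),
      KRAS       = m(11, 71, 16, 27, 4, 36),
      NRAS       = m(3, 79, 0, 43, 1, 39),
      BRAF       = m(2, 80, 0, 43, 1, 39),
      ERBB2_mut  = m(1, 81, 0, 43, 1, 39),
      PIK3CA     = m(9, 73, 6, 37, 3, 37)),
    gender = matrix(c(50L, 33L, 28L, 16L, 30L, 11L), nrow = 3, byrow = TRUE,
                    dimnames = list(g, c("female", "male"))),
    group_n = c(iCCA = 83L, eCCA = 44L, GBA = 41L))
}

#' Pooled and per-group prevalence summaries of the bundled cohort
#'
#' Computes, from the bundled counts, the pooled PIK3CA mutation
#' prevalence, the pooled BRAF p.V600E prevalence, and the iCCA
#' prevalences of FGFR2 alterations and IDH1/2 mutations, as percentages
#' of the successfully analysed samples.
#'
#' @return named numeric vector of percentages (1 decimal; IDH1/2
#'   reported to the nearest integer as in the source summary).
#' @export
btc_prevalence_summary <- function() {
  ct <- btc_cohort_counts()$markers
  pooled <- function(mm) sum(mm[, "present"]) / sum(mm)
  c(PIK3CA_pooled_pct = round(100 * pooled(ct$PIK3CA), 1),
    BRAF_V600E_pooled_pct = round(100 * pooled(ct$BRAF), 1),
    FGFR2_iCCA_pct = round(100 * ct$FGFR2["iCCA", "present"] /
                             sum(ct$FGFR2["iCCA", ]), 1),
    IDH1_2_iCCA_pct = round(100 * ct$IDH1_2["iCCA", "present"] /
                              sum(ct$IDH1_2["iCCA", ])))
}
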