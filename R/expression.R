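#' qPCR-like normalized expression of one target
#'
#' The target's unique-template count is divided by each of the three
#' referee-gene counts; the reported value is the median of the three
#' ratios, which tolerates aberrant expression of any single referee.
#'
#' @param target_count unique templates on the target's fragment.
#' @param referee_counts named numeric vector of length 3 (DDX23, GOLGA5,
#'   SEL1L fragment counts).
#' @return list with `ratios` (length 3) and `value` (their median).
#' @export
normalized_expression <- function(target_count, referee_counts) {
  if (length(referee_counts) != 3)
    stop("exactly three referee counts are required")
  if (any(referee_counts <= 0))
    stop("referee dropout: expression not evaluable (zero referee count)")
  ratios <- target_count / referee_counts
  list(ratios = ratios, value = median(ratios))
}

#' Sample-level QC verdict from the total template count
#'
#' A sample with fewer than `threshold` unique templates remaining after
#' duplicate removal and off-target filtering is interpreted as an assay
#' failure.
#'
#' @param total_templates unique templates in the sample.
#' @param threshold failure threshold (default 3000).
#' @return "PASS" or "FAIL".
#' @export
qc_sample <- function(total_templates, threshold = 3000L) {
  stopifnot(total_templates >= 0)
  if (total_templates < threshold) "FAIL" else "PASS"
}

#' Expression profile of a deduplicated sample
#'
#' Counts unique templates on the measurement fragment of each target
#' gene (ERBB2, FGFR1-4, CD274) and each referee gene, computes the
#' median-of-three normalized value per target, and attaches the QC
#' verdict. When a cohort median is supplied, targets above
#' `overexpression_factor` times it are flagged as overexpressed
#' (a surrogate marker of gene amplification).
#'
#' @param templates a `race_templates` object.
#' @param panel a `race_panel`.
#' @param qc_threshold total-template failure threshold.
#' @param cohort_median optional named vector of cohort median values.
#' @param overexpression_factor flag factor (default 5).
#' @return object of class `race_expression_profile`: data.frame `table`
#'   (gene, target count, three ratios, value), `referee_counts`,
#'   `total_templates`, `qc`, `evaluable`.
#' @export
profile_sample <- function(templates, panel, qc_threshold = 3000L,
                           cohort_median = NULL,
                           overexpression_factor = 5) {
  targets <- c("ERBB2", "FGFR1", "FGFR2", "FGFR3", "FGFR4", "CD274")
  referees <- c("DDX23", "GOLGA5", "SEL1L")
  ref_counts <- vapply(referees, function(g)
    count_templates(templates, fragment_for(g, panel)), integer(1))
  tgt_counts <- vapply(targets, function(g)
    count_templates(templates, fragment_for(g, panel)), integer(1))
  evaluable <- all(ref_counts > 0)
  tab <- data.frame(gene = targets, templates = tgt_counts,
                    stringsAsFactors = FALSE)
  if (evaluable) {
    vals <- lapply(tgt_counts, normalized_expression, referee_counts = ref_counts)
    rt <- do.call(rbind, lapply(vals, function(v) v$ratios))
    colnames(rt) <- paste0("ratio_", referees)
    tab <- cbind(tab, rt, value = vapply(vals, `[[`, numeric(1), "value"))
    if (!is.null(cohort_median))
      tab$overexpressed <- tab$value >
        overexpression_factor * cohort_median[tab$gene]
  } else {
    tab$value <- NA_real_
  }
  rownames(tab) <- NULL
  structure(list(table = tab, referee_counts = ref_counts,
                 total_templates = templates$total_templates,
                 qc = qc_sample(templates$total_templates, qc_threshold),
                 evaluable = evaluable),
            class = "race_expression_profile")
}

#' @export
print.race_expression_profile <- function(x, ...) {
  cat(sprintf("<expression profile: %d templates, QC %s%s>\n",
              x$total_templates, x$qc,
              if (!x$evaluable) ", NOT EVALUABLE (referee dropout)" else ""))
  print(x$table, digits = 3)
  invisible(x)
}
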