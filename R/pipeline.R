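#' Pipeline configuration
#'
#' One structured object carries every tunable of the per-sample
#' pipeline; the pipeline itself is deterministic (seeds exist only in
#' the simulator).
#'
#' @param align from [align_params()].
#' @param varcall from [varcall_thresholds()].
#' @param fusion_min_support,fusion_min_umis,fusion_min_tail,fusion_boundary_slop
#'   fusion-calling thresholds.
#' @param qc_threshold total-template failure threshold.
#' @return named list.
#' @export
pipeline_config <- function(align = align_params(),
                            varcall = varcall_thresholds(),
                            fusion_min_support = 5L, fusion_min_umis = 2L,
                            fusion_min_tail = 25L,
                            fusion_boundary_slop = 5L,
                            qc_threshold = 3000L) {
  list(align = align, varcall = varcall,
       fusion_min_support = as.integer(fusion_min_support),
       fusion_min_umis = as.integer(fusion_min_umis),
       fusion_min_tail = as.integer(fusion_min_tail),
       fusion_boundary_slop = as.integer(fusion_boundary_slop),
       qc_threshold = as.integer(qc_threshold))
}

#' Run the full per-sample pipeline
#'
#' Preprocess (primer/pseudo-UMI assignment, adapter trimming), align,
#' collapse duplicates, call variants and fusions, and profile
#' expression; every filtering step is counted so reads are fully
#' accounted for. Input is either a FASTQ pair on disk or an in-memory
#' reads table (e.g. `simulate_sample()$reads`).
#'
#' @param fastq_r1,fastq_r2 FASTQ paths (ignored when `reads` given).
#' @param panel a `race_panel`.
#' @param config from [pipeline_config()].
#' @param reads optional in-memory reads table (id, r1, q1, r2, q2).
#' @param sample_id sample label.
#' @param out_dir optional directory for stage artifacts (SAM, TSV, VCF).
#' @return object of class `race_sample_report`.
#' @export
run_pipeline <- function(fastq_r1 = NULL, fastq_r2 = NULL, panel,
                         config = pipeline_config(), reads = NULL,
                         sample_id = "sample", out_dir = NULL) {
  if (is.null(reads)) {
    f1 <- read_fastq(fastq_r1)
    f2 <- read_fastq(fastq_r2)
    if (length(f1$seq) == 0)
      stop("pipeline stage 'preprocess' failed: empty FASTQ input")
    if (!identical(f1$id, f2$id))
      stop("pipeline stage 'preprocess' failed: R1/R2 ids differ")
    reads <- data.table::data.table(id = f1$id, r1 = f1$seq, q1 = f1$qual,
                                    r2 = f2$seq, q2 = f2$qual)
  }
  if (nrow(reads) == 0)
    stop("pipeline stage 'preprocess' failed: empty FASTQ input")
  assigned <- assign_primer_and_umi(reads, panel, config$align$max_mm)
  aln <- align_sample(assigned, panel, config$align)
  tpl <- collapse(aln, panel)
  cols <- pileup(tpl, panel)
  variants <- call_variants(cols, panel, config$varcall)
  fusions <- call_fusions(tpl, aln, panel,
                          min_tail = config$fusion_min_tail,
                          boundary_slop = config$fusion_boundary_slop,
                          min_support = config$fusion_min_support,
                          min_umis = config$fusion_min_umis)
  expr <- profile_sample(tpl, panel, qc_threshold = config$qc_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sam(aln, panel, file.path(out_dir, paste0(sample_id, ".sam")))
    write_vcf(variants, panel, file.path(out_dir, paste0(sample_id, ".vcf")))
    write.table(as.data.frame(tpl$templates),
                file.path(out_dir, paste0(sample_id, ".templates.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log_counts <- c(aln$counts, discarded_offtarget = tpl$discarded,
                  templates = tpl$total_templates)
  structure(list(sample_id = sample_id,
                 qc = expr$qc,
                 total_templates = tpl$total_templates,
                 variants = variants[variants$filter == "PASS", ,
                                     drop = FALSE],
                 variants_all = variants,
                 fusions = fusions,
                 expression = expr,
                 counts = log_counts,
                 metadata = list(panel = panel$name,
                                 panel_version = panel$version,
                                 config = config[setdiff(names(config),
                                                         "align")])),
            class = "race_sample_report")
}

#' Render a sample report as JSON and readable text
#'
#' The JSON is schema-stable and byte-identical for identical inputs;
#' the text lists events in fixed order (fusions, variants, expression,
#' QC).
#'
#' @param report a `race_sample_report`.
#' @return list with `json` (character scalar) and `text` (character
#'   vector of lines).
#' @export
render_report <- function(report) {
  ex <- report$expression
  payload <- list(
    sample = report$sample_id,
    qc = list(verdict = report$qc,
              total_templates = report$total_templates),
    fusions = if (nrow(report$fusions)) report$fusions else list(),
    variants = if (nrow(report$variants))
      report$variants[c("transcript", "pos", "ref", "alt", "alt_templates",
                        "depth", "vaf", "hotspot", "protein")] else list(),
    expression = if (ex$evaluable)
      ex$table[c("gene", "templates", "value")] else "not evaluable",
    counts = as.list(report$counts),
    metadata = report$metadata)
  json <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                        digits = 6, na = "null"))
  txt <- c(sprintf("Sample %s", report$sample_id), "")
  txt <- c(txt, "Fusions:")
  txt <- c(txt, if (nrow(report$fusions))
    sprintf("  %s (support %d)", report$fusions$name,
            report$fusions$supporting_templates)
    else "  no alterations detected")
  txt <- c(txt, "Variants:")
  txt <- c(txt, if (nrow(report$variants))
    sprintf("  %s:%d %s>%s VAF %.3f%s", report$variants$transcript,
            report$variants$pos, report$variants$ref, report$variants$alt,
            report$variants$vaf,
            ifelse(is.na(report$variants$protein), "",
                   paste0(" (", report$variants$protein, ")")))
    else "  no alterations detected")
  txt <- c(txt, "Expression (median of three referee ratios):")
  txt <- c(txt, if (ex$evaluable)
    sprintf("  %s: %.3f", ex$table$gene, ex$table$value)
    else "  not evaluable (referee dropout)")
  txt <- c(txt, sprintf("QC: %s (%d templates)", report$qc,
                        report$total_templates))
  list(json = json, text = txt)
}

#' @export
print.race_sample_report <- function(x, ...) {
  writeLines(render_report(x)$text)
  invisible(x)
}
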