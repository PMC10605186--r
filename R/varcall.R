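#' Default variant-calling thresholds
#'
#' Template-level (post-dedup) calling floors. The hotspot VAF floor is
#' lower than the general floor because prior expectation at annotated
#' hotspot codons justifies higher sensitivity; the defaults keep an
#' activating mutation expressed at ~7% allele fraction comfortably
#' callable while leaving error-only columns silent.
#'
#' @param min_depth minimum unique-template depth.
#' @param min_alt_templates minimum alternate-allele templates.
#' @param min_vaf_hotspot,min_vaf_other VAF floors at hotspot /
#'   non-hotspot positions.
#' @param min_mean_qual minimum mean consensus base quality of the allele.
#' @return named list.
#' @export
varcall_thresholds <- function(min_depth = 50L, min_alt_templates = 3L,
                               min_vaf_hotspot = 0.02, min_vaf_other = 0.05,
                               min_mean_qual = 20) {
  list(min_depth = as.integer(min_depth),
       min_alt_templates = as.integer(min_alt_templates),
       min_vaf_hotspot = min_vaf_hotspot, min_vaf_other = min_vaf_other,
       min_mean_qual = min_mean_qual)
}

#' Template-level pileup over panel target regions
#'
#' One column per covered position inside the panel's fragments and
#' hotspot regions; depth is the number of unique templates whose
#' consensus covers the position and allele counts are template counts
#' (duplicates never inflate support).
#'
#' @param templates a `race_templates` object.
#' @param panel a `race_panel`.
#' @return data.table with columns transcript, pos, allele, count,
#'   mean_qual, depth (long format: one row per observed allele).
#' @export
pileup <- function(templates, panel) {
  cons <- templates$consensus
  if (is.null(cons) || nrow(cons) == 0)
    return(data.table::data.table(transcript = character(0), pos = integer(0),
                                  allele = character(0), count = integer(0),
                                  mean_qual = numeric(0), depth = integer(0)))
  tm <- .target_mask(panel)
  keep <- logical(nrow(cons))
  for (txid in unique(cons$transcript)) {
    sel <- which(cons$transcript == txid)
    m <- tm$mask[[txid]]
    keep[sel] <- !is.null(m) & m[cons$pos[sel] + 1L]
  }
  cons <- cons[keep]
  pc <- cons[, .(count = .N, mean_qual = mean(qual)),
             by = .(transcript, pos, allele)]
  dep <- pc[, .(depth = sum(count)), by = .(transcript, pos)]
  pc <- merge(pc, dep, by = c("transcript", "pos"))
  data.table::setorder(pc, transcript, pos, -count)
  pc
}

.hotspot_lookup <- function(panel, transcript, pos) {
  h <- panel$hotspots
  if (nrow(h) == 0) return(rep(NA_character_, length(pos)))
  vapply(seq_along(pos), function(i) {
    hit <- h[h$transcript == transcript[i] & h$start <= pos[i] &
               h$end > pos[i], , drop = FALSE]
    if (nrow(hit) == 0) NA_character_ else hit$label[1]
  }, character(1))
}

#' Call variants from a template pileup
#'
#' Emits a candidate for every non-reference allele with at least
#' `min_alt_templates` supporting templates and assigns a PASS / reason
#' filter from the threshold set; hotspot annotation is attached from the
#' panel. Calls are sorted by (transcript, position).
#'
#' @param columns pileup table from [pileup()].
#' @param panel a `race_panel`.
#' @param thresholds from [varcall_thresholds()].
#' @return data.frame of variant calls (transcript, pos, ref, alt,
#'   alt_templates, depth, vaf, mean_qual, hotspot, filter, protein).
#' @export
call_variants <- function(columns, panel, thresholds = varcall_thresholds()) {
  empty <- data.frame(transcript = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_templates = integer(0), depth = integer(0),
                      vaf = numeric(0), mean_qual = numeric(0),
                      hotspot = character(0), filter = character(0),
                      protein = character(0))
  if (nrow(columns) == 0) return(empty)
  seqs <- panel$transcriptome$seqs
  ref <- substr(seqs[columns$transcript], columns$pos + 1L, columns$pos + 1L)
  cand <- columns[columns$allele != ref &
                    columns$count >= thresholds$min_alt_templates]
  if (nrow(cand) == 0) return(empty)
  ref <- substr(seqs[cand$transcript], cand$pos + 1L, cand$pos + 1L)
  hot <- .hotspot_lookup(panel, cand$transcript, cand$pos)
  vaf <- cand$count / cand$depth
  floor_vaf <- ifelse(is.na(hot), thresholds$min_vaf_other,
                      thresholds$min_vaf_hotspot)
  filt <- rep("PASS", nrow(cand))
  filt[cand$depth < thresholds$min_depth] <- "LOW_DEPTH"
  filt[cand$mean_qual < thresholds$min_mean_qual] <- "LOW_QUAL"
  filt[vaf < floor_vaf] <- "LOW_VAF"
  out <- data.frame(transcript = cand$transcript, pos = cand$pos,
                    ref = ref, alt = cand$allele,
                    alt_templates = cand$count, depth = cand$depth,
                    vaf = vaf, mean_qual = cand$mean_qual, hotspot = hot,
                    filter = filt, protein = NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  annotate_protein(out, panel)
}

#' Protein-level annotation of hotspot substitutions
#'
#' For substitution calls at hotspot positions the reference codon is
#' read off the panel transcriptome (using the transcript's CDS start),
#' the alternate codon substituted, and both translated; nonsynonymous
#' changes receive an HGVS-style label such as `IDH1 p.R132C`.
#' Synonymous changes and non-hotspot calls are left unlabelled.
#'
#' @param calls data.frame of variant calls.
#' @param panel a `race_panel`.
#' @return the calls with the `protein` column filled in.
#' @export
annotate_protein <- function(calls, panel) {
  if (nrow(calls) == 0) return(calls)
  tx <- panel$transcriptome
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$hotspot[i])) next
    if (nchar(calls$ref[i]) != 1 || !calls$alt[i] %in% c("A", "C", "G", "T"))
      next
    cs <- tx$cds_start[[calls$transcript[i]]]
    off <- calls$pos[i] - cs
    if (off < 0) next
    codon_i <- off %/% 3L
    cstart <- cs + 3L * codon_i
    codon <- substr(tx$seqs[[calls$transcript[i]]], cstart + 1L, cstart + 3L)
    if (nchar(codon) < 3) next
    within <- calls$pos[i] - cstart + 1L
    alt_codon <- codon
    substr(alt_codon, within, within) <- calls$alt[i]
    aa_ref <- unname(gc[codon])
    aa_alt <- unname(gc[alt_codon])
    if (is.na(aa_ref) || is.na(aa_alt) || aa_ref == aa_alt) next
    calls$protein[i] <- sprintf("%s p.%s%d%s",
                                tx$gene[[calls$transcript[i]]],
                                aa_ref, codon_i + 1L, aa_alt)
  }
  calls
}

#' Write variant calls as VCF 4.2
#'
#' CHROM is the transcript id, POS is 1-based; INFO carries DP, AD, VAF
#' (4 decimals), HOTSPOT and PROTEIN (spaces replaced by underscores).
#'
#' @param calls data.frame of variant calls.
#' @param panel a `race_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, panel, path) {
  lens <- transcript_lengths(panel$transcriptome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=raceseq",
               sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Unique template depth\">",
               "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate templates\">",
               "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
               "##INFO=<ID=HOTSPOT,Number=1,Type=String,Description=\"Hotspot label\">",
               "##INFO=<ID=PROTEIN,Number=1,Type=String,Description=\"Protein change\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) == 0) return(invisible(path))
  us <- function(x) gsub(" ", "_", x)
  # represent deletions/insertions with anchored REF/ALT alleles
  ref <- calls$ref; alt <- calls$alt; pos <- calls$pos
  seqs <- panel$transcriptome$seqs
  for (i in seq_len(nrow(calls))) {
    if (alt[i] == "-") {            # deletion of ref base
      anchor <- substr(seqs[[calls$transcript[i]]], pos[i], pos[i])
      ref[i] <- paste0(anchor, ref[i]); alt[i] <- anchor
      pos[i] <- pos[i] - 1L
    } else if (startsWith(alt[i], "+")) {  # insertion before pos
      anchor <- substr(seqs[[calls$transcript[i]]], pos[i], pos[i])
      ref[i] <- anchor; alt[i] <- paste0(anchor, sub("^\\+", "", alt[i]))
      pos[i] <- pos[i] - 1L
    }
  }
  info <- sprintf("DP=%d;AD=%d;VAF=%.4f%s%s", calls$depth,
                  calls$alt_templates, calls$vaf,
                  ifelse(is.na(calls$hotspot), "",
                         paste0(";HOTSPOT=", us(calls$hotspot))),
                  ifelse(is.na(calls$protein), "",
                         paste0(";PROTEIN=", us(calls$protein))))
  writeLines(paste(calls$transcript, pos + 1L, ".", ref, alt, ".",
                   calls$filter, info, sep = "\t"), con)
  invisible(path)
}

#' Read a raceseq VCF back into a calls table
#'
#' Round-trips the fields emitted by [write_vcf()] (SNVs are restored
#' exactly; anchored indels keep their VCF representation).
#'
#' @param path VCF path.
#' @return data.frame of calls.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(transcript = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_templates = integer(0), depth = integer(0),
                      vaf = numeric(0), filter = character(0),
                      hotspot = character(0), protein = character(0)))
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  getinfo <- function(info, key) {
    m <- regmatches(info, regexec(paste0(key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  data.frame(transcript = f[, 1], pos = as.integer(f[, 2]) - 1L,
             ref = f[, 4], alt = f[, 5],
             alt_templates = as.integer(getinfo(f[, 8], "AD")),
             depth = as.integer(getinfo(f[, 8], "DP")),
             vaf = as.numeric(getinfo(f[, 8], "VAF")),
             filter = f[, 7],
             hotspot = gsub("_", " ", getinfo(f[, 8], "HOTSPOT")),
             protein = gsub("_", " ", getinfo(f[, 8], "PROTEIN")),
             stringsAsFactors = FALSE)
}
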