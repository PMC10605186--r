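#' Find chimeric template candidates at the fusion anchors
#'
#' FGFR fusions conserve the 5' gene up to an anchor boundary (for FGFR2,
#' the 3' end of exon 17 or the start of exon 18) while the 3' partner is
#' arbitrary, so a chimeric template shows an R1 alignment that ends at
#' the boundary with a soft-clipped 3' tail. Tails of at least `min_tail`
#' nt are re-aligned to the full panel transcriptome by seed-and-extend;
#' unalignable tails are retained with an unknown partner.
#'
#' @param templates a `race_templates` object.
#' @param aln the `race_alignments` the templates came from.
#' @param panel a `race_panel`.
#' @param min_tail minimum soft-clipped tail length (default 25).
#' @param boundary_slop tolerated distance from the anchor boundary
#'   (default 5).
#' @param params alignment parameters for tail re-alignment.
#' @return data.table of candidates (template_id, anchor gene/exon,
#'   breakpoint, tail sequence, partner transcript/gene/start, umi).
#' @export
find_candidates <- function(templates, aln, panel, min_tail = 25L,
                            boundary_slop = 5L,
                            params = align_params(k = 12L, seed_stride = 3L,
                                                  min_score = 14)) {
  t <- templates$templates
  if (is.null(t) || nrow(t) == 0) return(data.table::data.table())
  anch <- panel$anchors
  # representative R1 record per template: highest score among members
  r1 <- aln$records[aln$records$mate == 1L]
  mem <- merge(templates$members, r1, by.x = "id", by.y = "read_id")
  data.table::setorder(mem, template_id, -score, id)
  rep1 <- unique(mem, by = "template_id")
  cand <- merge(t, rep1[, .(template_id, transcript_r1 = transcript,
                            r_end, clip3, q_end, seq)],
                by = "template_id")
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    arow <- anch[anch$transcript == cand$transcript_r1[i] &
                   abs(anch$boundary - cand$r_end[i]) <= boundary_slop, ,
                 drop = FALSE]
    if (nrow(arow) == 0 || cand$clip3[i] < min_tail) next
    arow <- arow[order(abs(arow$boundary - cand$r_end[i]), arow$exon), ,
                 drop = FALSE]
    tail_seq <- substr(cand$seq[i], cand$q_end[i] + 1L, nchar(cand$seq[i]))
    partner_tx <- NA_character_; partner_gene <- "UNKNOWN"
    partner_start <- NA_integer_
    if (nchar(tail_seq) >= params$k) {
      hits <- seed_and_extend(tail_seq, panel, params)
      hits <- hits[hits$transcript != cand$transcript_r1[i]]
      if (nrow(hits) > 0) {
        partner_tx <- hits$transcript[1]
        partner_gene <- panel$transcriptome$gene[[partner_tx]]
        # project the partner-side junction to the tail's first base
        partner_start <- hits$r_start[1] - hits$q_start[1]
      }
    }
    rows[[length(rows) + 1L]] <- list(
      template_id = cand$template_id[i], anchor_gene = arow$gene[1],
      anchor_exon = arow$exon[1], breakpoint = cand$r_end[i],
      tail_seq = tail_seq, partner_tx = partner_tx,
      partner_gene = partner_gene, partner_start = partner_start,
      umi = cand$umi[i])
  }
  data.table::rbindlist(rows)
}

#' Cluster chimeric candidates into fusion calls
#'
#' Candidates are grouped by (anchor gene, breakpoint, partner gene,
#' partner exon); groups supported by at least `min_support` unique
#' templates carrying at least `min_umis` distinct pseudo-UMIs become
#' calls, named in the conventional notation (see [name_fusion()]).
#' Calls are ordered by support, descending.
#'
#' @param candidates from [find_candidates()].
#' @param panel a `race_panel`.
#' @param min_support minimum unique templates (default 5).
#' @param min_umis minimum distinct pseudo-UMIs (default 2).
#' @return data.frame of fusion calls.
#' @export
cluster_calls <- function(candidates, panel, min_support = 5L,
                          min_umis = 2L) {
  empty <- data.frame(gene5 = character(0), exon5 = integer(0),
                      breakpoint = integer(0), gene3 = character(0),
                      exon3 = integer(0), partner_start = integer(0),
                      supporting_templates = integer(0),
                      n_umis = integer(0), name = character(0))
  if (is.null(candidates) || nrow(candidates) == 0) return(empty)
  ex <- panel$transcriptome$exons
  candidates$partner_exon <- vapply(seq_len(nrow(candidates)), function(i) {
    if (is.na(candidates$partner_tx[i])) return(NA_integer_)
    e <- ex[ex$transcript == candidates$partner_tx[i] &
              ex$start <= candidates$partner_start[i] &
              ex$end > candidates$partner_start[i], , drop = FALSE]
    if (nrow(e) == 0) NA_integer_ else e$exon[1]
  }, integer(1))
  grp <- candidates[, .(supporting_templates = .N,
                        n_umis = length(unique(umi)),
                        partner_start = {
                          ps <- suppressWarnings(min(partner_start,
                                                     na.rm = TRUE))
                          if (is.finite(ps)) as.integer(ps) else NA_integer_
                        }),
                    by = .(anchor_gene, anchor_exon, breakpoint,
                           partner_gene, partner_exon)]
  grp <- grp[grp$supporting_templates >= min_support &
               grp$n_umis >= min_umis]
  if (nrow(grp) == 0) return(empty)
  data.table::setorder(grp, -supporting_templates, anchor_gene,
                       partner_gene)
  data.frame(gene5 = grp$anchor_gene, exon5 = grp$anchor_exon,
             breakpoint = grp$breakpoint, gene3 = grp$partner_gene,
             exon3 = grp$partner_exon, partner_start = grp$partner_start,
             supporting_templates = grp$supporting_templates,
             n_umis = grp$n_umis,
             name = mapply(name_fusion, grp$anchor_gene, grp$anchor_exon,
                           grp$partner_gene, grp$partner_exon),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Canonical fusion name
#'
#' Formats a fusion as `GENE5-GENE3 (X{exon5};Y{exon3})` where X and Y
#' are the first letters of the two gene symbols, e.g.
#' `FGFR2-BICC1 (F17;B3)`. Unknown partners render as
#' `GENE5-UNKNOWN (X{exon5};?)`, and a known partner with no annotated
#' exon gets `?` in place of its exon number.
#'
#' @param gene5,exon5 5' (anchor) gene symbol and exon number.
#' @param gene3,exon3 3' partner gene symbol (or "UNKNOWN") and exon
#'   number (or NA).
#' @return character fusion name.
#' @export
name_fusion <- function(gene5, exon5, gene3, exon3 = NA) {
  stopifnot(exon5 >= 1)
  if (identical(gene3, "UNKNOWN") || is.na(gene3))
    return(sprintf("%s-UNKNOWN (%s%d;?)", gene5, substr(gene5, 1, 1),
                   exon5))
  right <- if (is.na(exon3)) "?" else as.character(as.integer(exon3))
  sprintf("%s-%s (%s%d;%s%s)", gene5, gene3, substr(gene5, 1, 1), exon5,
          substr(gene3, 1, 1), right)
}

#' Detect fusions in a deduplicated sample
#'
#' Composition of [find_candidates()] and [cluster_calls()].
#'
#' @inheritParams find_candidates
#' @inheritParams cluster_calls
#' @return data.frame of fusion calls.
#' @export
call_fusions <- function(templates, aln, panel, min_tail = 25L,
                         boundary_slop = 5L, min_support = 5L,
                         min_umis = 2L) {
  cluster_calls(find_candidates(templates, aln, panel, min_tail,
                                boundary_slop),
                panel, min_support, min_umis)
}
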