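#' Default alignment parameters
#'
#' Seed-and-extend parameters: exact k-mer seeds on a prebuilt
#' transcriptome index, chained by diagonal and extended by local
#' alignment with affine gaps. `min_score` is the minimum accepted local
#' alignment score; `max_mm` the primer-prefix mismatch tolerance;
#' `primer_slop` the tolerated deviation of the R1 alignment start from
#' the assigned primer's 3' end (anchored PCR fixes that end, so larger
#' deviations mark the pair improper).
#'
#' @param k seed length.
#' @param match,mismatch,gap_open,gap_extend local alignment scores.
#' @param min_score minimum alignment score to keep a record.
#' @param max_mm maximum mismatches for primer assignment.
#' @param primer_slop allowed offset (nt) between R1 start and primer 3' end.
#' @param seed_stride spacing between query seed positions.
#' @return named list of parameters.
#' @export
align_params <- function(k = 15L, match = 1, mismatch = -2, gap_open = -4,
                         gap_extend = -1, min_score = 25, max_mm = 2L,
                         primer_slop = 2L, seed_stride = 6L) {
  list(k = as.integer(k), match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend, min_score = min_score,
       max_mm = as.integer(max_mm), primer_slop = as.integer(primer_slop),
       seed_stride = as.integer(seed_stride))
}

# locate the adapter read-through in a read; returns trim length (number
# of leading bases kept) or nchar if absent. The first `probe` nt of the
# adapter are matched with <=1 mismatch.
.trim_adapter <- function(seqs, adapter, probe = 12L) {
  pat <- substr(adapter, 1, probe)
  hits <- Biostrings::vmatchPattern(pat, Biostrings::DNAStringSet(seqs),
                                    max.mismatch = 1)
  st <- Biostrings::startIndex(hits)
  vapply(seq_along(seqs), function(i) {
    s <- st[[i]]
    if (is.null(s) || length(s) == 0) nchar(seqs[i]) else min(s) - 1L
  }, integer(1))
}

#' Assign enrichment primers and pseudo-UMIs to read pairs
#'
#' The chemistry guarantees that R1 begins with one of the panel's
#' gene-specific primers and that R2 begins with the 10-nt random decamer.
#' Each R1 prefix is matched against all panel primers; the unique best
#' match with at most `max_mm` mismatches is assigned (ties and
#' no-matches are marked unassigned and excluded from all downstream
#' counts). The R2 10-nt prefix is recorded as the observed pseudo-UMI.
#' Primer bases, the decamer, and adapter read-through are trimmed before
#' alignment but retained as metadata.
#'
#' @param reads list with `id`, `r1`, `q1`, `r2`, `q2` vectors (a
#'   `race_sim$reads` table works directly).
#' @param panel a `race_panel`.
#' @param max_mm maximum primer-prefix mismatches (default 2).
#' @return data.table with assignment columns (`primer`, `primer_mm`,
#'   `umi`, trimmed sequences/qualities, `assigned`).
#' @export
assign_primer_and_umi <- function(reads, panel, max_mm = 2L) {
  reads <- data.table::as.data.table(reads)
  if (is.null(reads$q1)) reads$q1 <- strrep("?", nchar(reads$r1))
  if (is.null(reads$q2)) reads$q2 <- strrep("?", nchar(reads$r2))
  mm <- primer_prefix_mm_cpp(reads$r1, panel$primers$sequence, max_mm)
  assigned <- mm[, 1] > 0 & mm[, 3] == 1
  pidx <- ifelse(assigned, mm[, 1], NA_integer_)
  plen <- panel$primers$length[pidx]
  ad <- .adapter_readthrough()
  keep1 <- .trim_adapter(reads$r1, ad$r1)
  keep2 <- .trim_adapter(reads$r2, ad$r2)
  out <- data.table::data.table(
    id = reads$id,
    assigned = assigned,
    primer = panel$primers$name[pidx],
    primer_mm = mm[, 2],
    umi = substr(reads$r2, 1, 10),
    r1_trim = substr(reads$r1, ifelse(is.na(plen), 1L, plen + 1L), keep1),
    q1_trim = substr(reads$q1, ifelse(is.na(plen), 1L, plen + 1L), keep1),
    r2_trim = substr(reads$r2, 11L, keep2),
    q2_trim = substr(reads$q2, 11L, keep2))
  out
}

# align one sequence against a reference window; returns a record row or NULL
.align_window <- function(seq, qual, txid, w_start, ref, params) {
  al <- sw_align_cpp(seq, ref, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
  # short trimmed reads cannot reach the absolute floor; scale it down
  thr <- min(params$min_score,
             max(10, floor(0.8 * nchar(seq) * params$match)))
  if (al$score < thr) return(NULL)
  list(transcript = txid, r_start = w_start + al$r_start,
       r_end = w_start + al$r_end, q_start = al$q_start, q_end = al$q_end,
       clip5 = al$q_start, clip3 = nchar(seq) - al$q_end,
       cigar = al$cigar, nm = al$nm, score = al$score, seq = seq,
       qual = qual)
}

#' Seed-and-extend local alignment against the panel transcriptome
#'
#' Exact k-mer seeds are looked up in a prebuilt index, grouped by
#' (transcript, diagonal), and the best diagonals extended with a local
#' affine-gap alignment. Unaligned terminal stretches are reported as soft
#' clips. Records are sorted by score (descending) with deterministic
#' tie-breaking by transcript id, then start.
#'
#' @param seq nucleotide string (length >= k).
#' @param panel a `race_panel` (its transcriptome is searched).
#' @param params from [align_params()].
#' @param qual optional quality string.
#' @param max_candidates number of candidate diagonals to extend.
#' @return data.table of alignment records (possibly empty).
#' @export
seed_and_extend <- function(seq, panel, params = align_params(),
                            qual = NULL, max_candidates = 4L) {
  if (nchar(seq) < params$k)
    stop("sequence shorter than the seed length k")
  if (is.null(qual)) qual <- strrep("?", nchar(seq))
  idx <- .kmer_index(panel, params$k)
  L <- nchar(seq)
  starts <- unique(c(seq(1L, L - params$k + 1L, by = params$seed_stride),
                     L - params$k + 1L))
  kms <- substring(seq, starts, starts + params$k - 1L)
  hit_tx <- integer(0); hit_diag <- integer(0)
  for (j in seq_along(kms)) {
    h <- idx$env[[kms[j]]]
    if (is.null(h)) next
    hit_tx <- c(hit_tx, h[, 1])
    hit_diag <- c(hit_diag, h[, 2] - (starts[j] - 1L))
  }
  if (!length(hit_tx)) return(.empty_records())
  # bucket diagonals within +/-8 nt
  key <- paste(hit_tx, hit_diag %/% 8L)
  cnt <- sort(table(key), decreasing = TRUE)
  cand <- names(cnt)[seq_len(min(max_candidates, length(cnt)))]
  seqs <- panel$transcriptome$seqs
  rows <- list()
  for (cc in cand) {
    sel <- which(key == cc)
    ti <- hit_tx[sel[1]]
    d0 <- min(hit_diag[sel])
    txid <- idx$tx[ti]
    w_start <- max(0L, d0 - 20L)
    w_end <- min(nchar(seqs[[txid]]), max(hit_diag[sel]) + L + 20L)
    ref <- substr(seqs[[txid]], w_start + 1L, w_end)
    r <- .align_window(seq, qual, txid, w_start, ref, params)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) return(.empty_records())
  rec <- data.table::rbindlist(rows)
  rec <- unique(rec, by = c("transcript", "r_start", "cigar"))
  data.table::setorder(rec, -score, transcript, r_start)
  rec
}

.empty_records <- function() {
  data.table::data.table(transcript = character(0), r_start = integer(0),
                         r_end = integer(0), q_start = integer(0),
                         q_end = integer(0), clip5 = integer(0),
                         clip3 = integer(0), cigar = character(0),
                         nm = integer(0), score = numeric(0),
                         seq = character(0), qual = character(0))
}

#' Align assigned read pairs to the panel transcriptome
#'
#' R1 (primer and adapter trimmed) is aligned sense starting at the
#' assigned primer's 3' end; R2 (decamer and adapter trimmed) is
#' reverse-complemented and aligned near the primer first, with a full
#' seed-and-extend fallback for sequences that do not fit there (fusion
#' partners in particular). Pairs whose R1 start deviates from the primer
#' 3' end by more than `primer_slop` are flagged improper.
#'
#' @param assigned output of [assign_primer_and_umi()].
#' @param panel a `race_panel`.
#' @param params from [align_params()].
#' @return list of class `race_alignments`: `records` (one row per aligned
#'   mate), `pairs` (per-pair status), `counts` (read accounting).
#' @export
align_sample <- function(assigned, panel, params = align_params()) {
  prm <- panel$primers
  seqs <- panel$transcriptome$seqs
  keep <- which(assigned[["assigned"]])
  a <- assigned[keep]
  n_a <- nrow(a)
  ids <- a[["id"]]; r1s <- a[["r1_trim"]]; q1s <- a[["q1_trim"]]
  q2s <- .revstr(a[["q2_trim"]])
  r2rc <- revcomp(a[["r2_trim"]])
  pidx <- match(a[["primer"]], prm$name)
  p3v <- prm$end[pidx]; txv <- prm$transcript[pidx]
  p5v <- prm$start[pidx]
  txlens <- nchar(seqs)[txv]
  len1 <- nchar(r1s); len2 <- nchar(r2rc)
  eff_thr <- function(len) pmin(params$min_score,
                                pmax(10, floor(0.8 * len * params$match)))
  # R1: one window per read, anchored at the primer 3' end
  w1s <- pmax(0L, p3v - 10L)
  w1e <- pmin(txlens, p3v + len1 + 30L)
  b1 <- sw_align_batch_cpp(r1s, substring(seqs[txv], w1s + 1L, w1e),
                           params$match, params$mismatch, params$gap_open,
                           params$gap_extend)
  r1_rs <- w1s + b1$r_start; r1_re <- w1s + b1$r_end
  r1ok <- len1 >= params$k & b1$score >= eff_thr(len1)
  proper1 <- r1ok & abs((r1_rs - b1$q_start) - p3v) <= params$primer_slop
  # R2: window near the primer first
  w2s <- pmax(0L, p5v - 5L)
  w2e <- pmin(txlens, p3v + 330L)
  b2 <- sw_align_batch_cpp(r2rc, substring(seqs[txv], w2s + 1L, w2e),
                           params$match, params$mismatch, params$gap_open,
                           params$gap_extend)
  r2_tx <- txv
  r2_rs <- w2s + b2$r_start; r2_re <- w2s + b2$r_end
  r2_qs <- b2$q_start; r2_qe <- b2$q_end
  r2_cig <- b2$cigar; r2_nm <- b2$nm; r2_score <- b2$score
  r2ok <- len2 >= params$k & r2_score >= eff_thr(len2)
  # full seed-and-extend fallback for R2s that do not fit near the primer
  # (fusion partner sequence in particular)
  retry <- which(r1ok & proper1 & len2 >= params$k &
                   r2_score < 0.8 * len2 * params$match)
  for (i in retry) {
    alt <- seed_and_extend(r2rc[i], panel, params, qual = q2s[i])
    if (nrow(alt) > 0 && alt$score[1] > r2_score[i]) {
      r2_tx[i] <- alt$transcript[1]
      r2_rs[i] <- alt$r_start[1]; r2_re[i] <- alt$r_end[1]
      r2_qs[i] <- alt$q_start[1]; r2_qe[i] <- alt$q_end[1]
      r2_cig[i] <- alt$cigar[1]; r2_nm[i] <- alt$nm[1]
      r2_score[i] <- alt$score[1]
      r2ok[i] <- r2_score[i] >= eff_thr(len2[i])
    }
  }
  stat <- rep("half-mapped", n_a)
  stat[r1ok & !proper1] <- "improper"
  good <- proper1 & r2ok
  stat[good] <- "proper"
  gi <- which(good)
  records <- data.table::rbindlist(list(
    data.table::data.table(
      transcript = txv[gi], r_start = r1_rs[gi], r_end = r1_re[gi],
      q_start = b1$q_start[gi], q_end = b1$q_end[gi],
      clip5 = b1$q_start[gi], clip3 = len1[gi] - b1$q_end[gi],
      cigar = b1$cigar[gi], nm = b1$nm[gi], score = b1$score[gi],
      seq = r1s[gi], qual = q1s[gi], read_id = ids[gi], mate = 1L),
    data.table::data.table(
      transcript = r2_tx[gi], r_start = r2_rs[gi], r_end = r2_re[gi],
      q_start = r2_qs[gi], q_end = r2_qe[gi],
      clip5 = r2_qs[gi], clip3 = len2[gi] - r2_qe[gi],
      cigar = r2_cig[gi], nm = r2_nm[gi], score = r2_score[gi],
      seq = r2rc[gi], qual = q2s[gi], read_id = ids[gi], mate = 2L)))
  data.table::setorder(records, read_id, mate)
  pairs <- data.table::data.table(id = a$id, primer = a$primer,
                                  umi = a$umi, status = stat)
  counts <- c(input = nrow(assigned),
              unassigned = sum(!assigned$assigned),
              assigned = nrow(a),
              proper = sum(stat == "proper"),
              improper = sum(stat == "improper"),
              half_mapped = sum(stat == "half-mapped"))
  structure(list(records = records, pairs = pairs, counts = counts),
            class = "race_alignments")
}

.revstr <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Align one read pair
#'
#' Convenience wrapper over [assign_primer_and_umi()] and [align_sample()]
#' for a single pair.
#'
#' @param r1,r2 read sequences.
#' @param panel a `race_panel`.
#' @param params from [align_params()].
#' @return a `race_alignments` object for the single pair.
#' @export
align_pair <- function(r1, r2, panel, params = align_params()) {
  reads <- data.table::data.table(id = "pair1", r1 = r1,
                                  q1 = strrep("?", nchar(r1)), r2 = r2,
                                  q2 = strrep("?", nchar(r2)))
  align_sample(assign_primer_and_umi(reads, panel, params$max_mm), panel,
               params)
}

#' @export
print.race_alignments <- function(x, ...) {
  cat("<race_alignments>\n")
  print(x$counts)
  invisible(x)
}
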