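#' Group aligned pairs by the single informative coordinate
#'
#' Enrichment by a gene-specific primer fixes one end of every molecule,
#' so PCR duplicates can only be discriminated by the RT-priming
#' coordinate (the R2 alignment start) plus the pseudo-UMI. Pairs are
#' grouped exactly on the key (primer, R2 transcript, RT coordinate);
#' pairs lying outside every panel fragment and hotspot region are
#' discarded and counted.
#'
#' @param aln a `race_alignments` object (proper pairs are used).
#' @param panel a `race_panel`.
#' @return list with `groups` (data.table: one row per pair with its key)
#'   and `discarded` (off-target pair count).
#' @export
group_by_coordinate <- function(aln, panel) {
  rec <- aln$records
  pairs <- aln$pairs[aln$pairs$status == "proper"]
  r1 <- rec[rec$mate == 1L][, .(read_id, transcript, r_start, r_end)]
  r2 <- rec[rec$mate == 2L][, .(read_id, r2_tx = transcript,
                                rt_coord = r_end)]
  g <- merge(merge(pairs, r1, by.x = "id", by.y = "read_id"),
             r2, by.x = "id", by.y = "read_id")
  # on-target: the template span [primer start, rt) must touch a fragment
  # or hotspot interval on the R1 transcript
  tm <- .target_mask(panel)
  p5 <- panel$primers$start[match(g$primer, panel$primers$name)]
  span_start <- pmin(p5, g$r_start)
  n_target <- vapply(seq_len(nrow(g)), function(i) {
    cum <- tm$cum[[g$transcript[i]]]
    lo <- min(span_start[i], length(cum) - 1L)
    hi <- min(g$rt_coord[i], length(cum) - 1L)
    if (hi <= lo) 0L else cum[hi + 1L] - cum[lo + 1L]
  }, integer(1))
  # chimeric pairs (R2 on another transcript) are kept for the fusion stage
  ontarget <- n_target > 0L | g$r2_tx != g$transcript
  list(groups = g[ontarget], discarded = sum(!ontarget))
}

#' Directional clustering of pseudo-UMIs
#'
#' Re-implementation of the directional adjacency method: a directed edge
#' u -> v exists when the Hamming distance between the two 10-mers is 1
#' and count(u) >= 2 * count(v) - 1. Unvisited nodes are processed in
#' decreasing count order (ties broken lexicographically) and each seed
#' collects every unvisited node reachable along directed edges; the seed
#' UMI is the cluster consensus.
#'
#' @param umi_counts named integer vector: observed 10-mer -> read count.
#' @return list of clusters, each a list with `consensus`, `members`,
#'   `count` (total reads).
#' @export
cluster_umis_directional <- function(umi_counts) {
  if (length(umi_counts) == 0) return(list())
  if (any(nchar(names(umi_counts)) != 10))
    stop("pseudo-UMI length must be 10")
  if (any(umi_counts < 1)) stop("UMI counts must be >= 1")
  umis <- names(umi_counts)
  n <- length(umis)
  ord <- order(-umi_counts, umis)
  if (n == 1)
    return(list(list(consensus = umis, members = umis,
                     count = unname(umi_counts))))
  chm <- do.call(rbind, strsplit(umis, ""))
  visited <- rep(FALSE, n)
  clusters <- list()
  for (s in ord) {
    if (visited[s]) next
    members <- s
    visited[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        cand <- which(!visited)
        if (!length(cand)) break
        hd <- colSums(t(chm[cand, , drop = FALSE]) != chm[u, ])
        take <- cand[hd == 1 & umi_counts[u] >= 2 * umi_counts[cand] - 1]
        if (length(take)) {
          visited[take] <- TRUE
          members <- c(members, take)
          nxt <- c(nxt, take)
        }
      }
      frontier <- nxt
    }
    clusters[[length(clusters) + 1L]] <-
      list(consensus = umis[s], members = umis[members],
           count = sum(umi_counts[members]))
  }
  clusters
}

#' Collapse PCR duplicates into template clusters
#'
#' Applies [group_by_coordinate()] and, within each coordinate key,
#' [cluster_umis_directional()]; every cluster is one unique template.
#' Per-template consensus bases over the insert are taken by majority
#' vote across member reads (ties resolved by higher mean base quality,
#' then the reference base), with the decamer-written positions masked
#' (their mismatches are the UMI signal, not the template sequence).
#'
#' @param aln a `race_alignments` object.
#' @param panel a `race_panel`.
#' @return list of class `race_templates`: `templates` (one row each:
#'   template_id, primer, transcript, start, rt_coord, umi, read_count),
#'   `consensus` (long table template_id/transcript/pos/base/qual),
#'   `total_templates`, `discarded`, `members`.
#' @export
collapse <- function(aln, panel) {
  gb <- group_by_coordinate(aln, panel)
  g <- gb$groups
  if (nrow(g) == 0) {
    return(structure(list(
      templates = data.table::data.table(), consensus = data.table::data.table(),
      total_templates = 0L, discarded = gb$discarded,
      members = data.table::data.table()), class = "race_templates"))
  }
  g$key <- paste(g$primer, g$r2_tx, g$rt_coord, sep = "|")
  # sort-canonicalised processing: order independent of input order
  data.table::setorder(g, key, umi, id)
  keyv <- g[["key"]]; umiv <- g[["umi"]]; idv <- g[["id"]]
  primv <- g[["primer"]]; txv <- g[["transcript"]]
  r2txv <- g[["r2_tx"]]; rtv <- g[["rt_coord"]]
  starts <- which(!duplicated(keyv))
  ends <- c(starts[-1] - 1L, length(keyv))
  t_primer <- character(0); t_tx <- character(0); t_r2tx <- character(0)
  t_rt <- integer(0); t_umi <- character(0); t_n <- integer(0)
  m_tid <- list(); m_ids <- list()
  tid <- 0L
  for (gi in seq_along(starts)) {
    sel <- starts[gi]:ends[gi]
    r <- rle(umiv[sel])  # already sorted within key
    cl <- cluster_umis_directional(setNames(r$lengths, r$values))
    for (c1 in cl) {
      tid <- tid + 1L
      ids <- idv[sel][umiv[sel] %in% c1$members]
      t_primer[tid] <- primv[sel[1]]; t_tx[tid] <- txv[sel[1]]
      t_r2tx[tid] <- r2txv[sel[1]]; t_rt[tid] <- rtv[sel[1]]
      t_umi[tid] <- c1$consensus; t_n[tid] <- length(ids)
      m_tid[[tid]] <- rep.int(tid, length(ids)); m_ids[[tid]] <- ids
    }
  }
  tids <- sprintf("C%06d", seq_len(tid))
  templates <- data.table::data.table(
    template_id = tids, primer = t_primer, transcript = t_tx,
    r2_tx = t_r2tx, rt_coord = t_rt, umi = t_umi, read_count = t_n)
  members <- data.table::data.table(
    template_id = tids[unlist(m_tid)], id = unlist(m_ids))
  p5 <- panel$primers$start[match(templates$primer, panel$primers$name)]
  templates$start <- p5
  cons <- .template_consensus(aln, panel, templates, members)
  structure(list(templates = templates, consensus = cons,
                 total_templates = nrow(templates),
                 discarded = gb$discarded, members = members),
            class = "race_templates")
}

# majority-vote consensus bases per template over both mates, with the
# decamer region (>= rt_coord on the R2 transcript) masked
.template_consensus <- function(aln, panel, templates, members) {
  rec <- aln$records[aln$records$read_id %in% members$id]
  if (nrow(rec) == 0) return(data.table::data.table())
  ev <- aligned_events_cpp(rec$seq, rec$qual, rec$q_start, rec$r_start,
                           rec$cigar)
  read_ids <- rec$read_id[ev$rec]
  tid <- members$template_id[match(read_ids, members$id)]
  tmi <- match(tid, templates$template_id)
  txs <- rec$transcript[ev$rec]
  # mask the decamer-written region of each template
  keep <- !(txs == templates$r2_tx[tmi] &
              ev$pos >= templates$rt_coord[tmi])
  evt <- data.table::data.table(template_id = tid[keep],
                                transcript = txs[keep],
                                pos = ev$pos[keep],
                                allele = ev$allele[keep],
                                qual = ev$qual[keep])
  agg <- evt[, .(n = .N, qual = mean(qual)),
             by = .(template_id, transcript, pos, allele)]
  seqs <- panel$transcriptome$seqs
  agg$ref <- substr(seqs[agg$transcript],
                    agg$pos + 1L, agg$pos + 1L) == agg$allele
  data.table::setorder(agg, template_id, transcript, pos, -n, -qual, -ref,
                       allele)
  cons <- unique(agg, by = c("template_id", "transcript", "pos"))
  cons[, c("template_id", "transcript", "pos", "allele", "qual", "n"),
       with = FALSE]
}

#' Count templates overlapping a target fragment
#'
#' A template counts for a fragment when its consensus insert (primer
#' start to RT coordinate, half-open) overlaps the fragment interval by
#' at least one nucleotide.
#'
#' @param templates a `race_templates` object.
#' @param fragment one-row fragment data.frame (e.g. from
#'   [fragment_for()]).
#' @return integer count.
#' @export
count_templates <- function(templates, fragment) {
  t <- templates$templates
  if (is.null(t) || nrow(t) == 0) return(0L)
  sum(t$transcript == fragment$transcript[1] &
        t$r2_tx == t$transcript &           # non-chimeric span
        t$start < fragment$end[1] &
        t$rt_coord > fragment$start[1])
}

#' @export
print.race_templates <- function(x, ...) {
  cat(sprintf("<race_templates: %d templates, %d off-target pairs discarded>\n",
              x$total_templates, x$discarded))
  invisible(x)
}
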