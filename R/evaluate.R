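# Benchmark / validation utilities: independent oracles and seeded
# end-to-end evaluations used by the test-suite and the acceptance
# script. The oracles are deliberately separate implementations from the
# production code paths they check.

#' Full dynamic-programming local alignment score (oracle)
#'
#' Plain-R affine-gap Smith-Waterman score, independent of the compiled
#' aligner; used to validate seed-and-extend scores.
#'
#' @param q,r query and reference strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return best local alignment score.
#' @export
sw_score_oracle <- function(q, r, match = 1, mismatch = -2, gap_open = -4,
                            gap_extend = -1) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    sub <- ifelse(rc == qc[i] & qc[i] != "N", match, mismatch)
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open, E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open, F[i, j + 1] + gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + sub[j], E[i + 1, j + 1],
                             F[i + 1, j + 1])
    }
    best <- max(best, max(H[i + 1, ]))
  }
  best
}

#' Directional UMI clustering partition (oracle)
#'
#' Independent re-derivation of the directional clustering partition via
#' an explicit adjacency matrix and repeated transitive closure, rather
#' than the breadth-first traversal of the production implementation.
#'
#' @param umi_counts named integer vector.
#' @return list of character vectors (cluster member sets), in seed
#'   processing order.
#' @export
directional_partition_oracle <- function(umi_counts) {
  umis <- names(umi_counts)
  n <- length(umis)
  if (n == 0) return(list())
  chm <- do.call(rbind, strsplit(umis, ""))
  hd <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    hd[i, j] <- sum(chm[i, ] != chm[j, ])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- i != j && hd[i, j] == 1L &&
      umi_counts[i] >= 2L * umi_counts[j] - 1L
  ord <- order(-umi_counts, umis)
  assigned <- rep(FALSE, n)
  out <- list()
  for (s in ord) {
    if (assigned[s]) next
    # members: unassigned nodes reachable from s through unassigned nodes
    # (recompute closure on the unassigned subgraph)
    free <- which(!assigned)
    sub <- adj[free, free, drop = FALSE] | diag(TRUE, length(free))
    repeat {
      nxt <- (sub %*% sub) > 0
      if (identical(nxt, sub)) break
      sub <- nxt
    }
    mem <- free[sub[match(s, free), ] > 0]
    assigned[mem] <- TRUE
    out[[length(out) + 1L]] <- sort(umis[mem])
  }
  out
}

#' Fusion detection benchmark over seeded simulations
#'
#' Simulates fusion-positive samples (an FGFR2-BICC1 fusion at the given
#' fraction on an FGFR2-overexpressing background, as fusion-positive
#' tumours show) and fusion-negative samples, runs the full pipeline, and
#' reports recall and false calls.
#'
#' @param panel a `race_panel`.
#' @param seeds_pos,seeds_neg integer seed vectors.
#' @param n_templates templates per sample (default 3500).
#' @param fusion_fraction fraction of FGFR2 templates carrying the fusion.
#' @return list with `recall`, `false_calls`, `n_pos`, `n_neg`, and the
#'   per-seed call tables.
#' @export
eval_fusion_detection <- function(panel, seeds_pos, seeds_neg,
                                  n_templates = 3500L,
                                  fusion_fraction = 0.25) {
  w <- .full_panel_weights(fgfr2 = 3)
  fus <- list(list(anchor_gene = "FGFR2", anchor_exon = 17L,
                   partner_transcript = "BICC1_tx",
                   partner_breakpoint = 400L,
                   fraction = fusion_fraction))
  run1 <- function(seed, fusions) {
    tm <- truth_model(w, fusions = fusions, n_templates = n_templates,
                      seed = seed)
    sim <- simulate_sample(panel, tm)
    rep <- run_pipeline(panel = panel, reads = sim$reads,
                        sample_id = sprintf("s%d", seed))
    rep$fusions
  }
  pos <- lapply(seeds_pos, run1, fusions = fus)
  neg <- lapply(seeds_neg, run1, fusions = list())
  hit <- vapply(pos, function(f)
    nrow(f) > 0 && any(f$gene5 == "FGFR2" & f$gene3 == "BICC1"),
    logical(1))
  list(recall = mean(hit),
       false_calls = sum(vapply(neg, nrow, integer(1))),
       n_pos = length(seeds_pos), n_neg = length(seeds_neg),
       pos_calls = pos, neg_calls = neg)
}

#' Variant spike-in recovery benchmark
#'
#' Spikes BRAF p.V600E (25%), IDH2 p.R172K (10%) and IDH1 p.R132C (5%)
#' into seeded simulations at >= 200-template depth, runs the pipeline,
#' and reports per-variant recovery, the VAF errors, and any PASS calls
#' at non-spiked positions.
#'
#' @param panel a `race_panel`.
#' @param seeds integer seed vector.
#' @param n_templates templates per sample (default 2500).
#' @return data.frame with one row per (seed, variant): detected, true
#'   and estimated VAF, depth; attribute `false_pass` counts unexpected
#'   PASS calls.
#' @export
eval_variant_recovery <- function(panel, seeds, n_templates = 2500L) {
  tx <- panel$transcriptome
  spec <- list(
    list(gene = "BRAF", codon = 600L, alt_offset = 1L, alt = "A", af = 0.25),
    list(gene = "IDH2", codon = 172L, alt_offset = 1L, alt = "A", af = 0.10),
    list(gene = "IDH1", codon = 132L, alt_offset = 0L, alt = "T", af = 0.05))
  vars <- lapply(spec, function(s) {
    txid <- paste0(s$gene, "_tx")
    pos <- tx$cds_start[[txid]] + 3L * (s$codon - 1L) + s$alt_offset
    list(transcript = txid, pos = pos,
         ref = substr(tx$seqs[[txid]], pos + 1L, pos + 1L), alt = s$alt,
         af = s$af)
  })
  w <- .full_panel_weights(list(BRAF = 25, IDH1 = 25, IDH2 = 15))
  rows <- list()
  false_pass <- 0L
  for (seed in seeds) {
    tm <- truth_model(w, variants = vars, n_templates = n_templates,
                      seed = seed)
    sim <- simulate_sample(panel, tm)
    rep <- run_pipeline(panel = panel, reads = sim$reads,
                        sample_id = sprintf("v%d", seed))
    calls <- rep$variants
    for (v in vars) {
      hit <- calls[calls$transcript == v$transcript & calls$pos == v$pos &
                     calls$alt == v$alt, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, transcript = v$transcript, pos = v$pos,
        true_vaf = v$af, detected = nrow(hit) > 0,
        est_vaf = if (nrow(hit)) hit$vaf[1] else NA_real_,
        depth = if (nrow(hit)) hit$depth[1] else NA_integer_)
    }
    spiked <- paste(vapply(vars, `[[`, character(1), "transcript"),
                    vapply(vars, function(v) v$pos, numeric(1)))
    false_pass <- false_pass +
      sum(!paste(calls$transcript, calls$pos) %in% spiked)
  }
  out <- do.call(rbind, rows)
  attr(out, "false_pass") <- false_pass
  out
}

#' Expression fold-change recovery benchmark
#'
#' Simulates an ERBB2 spike-in at a known fold change over the referees
#' and reports the log2 ratio of recovered to true fold change per seed.
#'
#' @param panel a `race_panel`.
#' @param seeds integer seed vector.
#' @param fold true fold change (default 4).
#' @param n_templates templates per sample (default 10000).
#' @return numeric vector of per-seed log2(recovered / true).
#' @export
eval_expression_recovery <- function(panel, seeds, fold = 4,
                                     n_templates = 10000L) {
  w <- c(ERBB2 = fold, DDX23 = 1, GOLGA5 = 1, SEL1L = 1)
  vapply(seeds, function(seed) {
    tm <- truth_model(w, n_templates = n_templates, seed = seed)
    sim <- simulate_sample(panel, tm)
    as <- assign_primer_and_umi(sim$reads, panel)
    tpl <- collapse(align_sample(as, panel), panel)
    pr <- profile_sample(tpl, panel)
    log2(pr$table$value[pr$table$gene == "ERBB2"] / fold)
  }, numeric(1))
}

# full-panel gene weights, optionally overriding individual genes
.full_panel_weights <- function(overrides = list(), fgfr2 = NULL) {
  genes <- c("FGFR1", "FGFR2", "FGFR3", "FGFR4", "IDH1", "IDH2", "ERBB2",
             "KRAS", "NRAS", "BRAF", "PIK3CA", "CD274", "DDX23", "GOLGA5",
             "SEL1L")
  w <- setNames(rep(1, length(genes)), genes)
  if (!is.null(fgfr2)) w[["FGFR2"]] <- fgfr2
  for (g in names(overrides)) w[[g]] <- overrides[[g]]
  w
}
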