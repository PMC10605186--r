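A10 <- strrep("A", 10)
mut_at <- function(s, i, b) { substr(s, i, i) <- b; s }

test_that("directional clustering follows the adjacency rule", {
  # high-count node absorbs a distance-1 neighbour (10 >= 2*1 - 1)
  cl <- cluster_umis_directional(setNames(c(10L, 1L),
                                          c(A10, mut_at(A10, 10, "T"))))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$consensus, A10)
  expect_equal(cl[[1]]$count, 11L)
  # distance-10 pair stays separate
  cl <- cluster_umis_directional(setNames(c(5L, 5L),
                                          c(A10, strrep("T", 10))))
  expect_length(cl, 2L)
  # boundary of the count condition: 3 >= 2*2 - 1 merges
  cl <- cluster_umis_directional(setNames(c(3L, 2L),
                                          c(A10, mut_at(A10, 10, "T"))))
  expect_length(cl, 1L)
  # just over the boundary: 3 >= 2*3 - 1 fails, two clusters
  cl <- cluster_umis_directional(setNames(c(3L, 3L),
                                          c(A10, mut_at(A10, 10, "T"))))
  expect_length(cl, 2L)
  expect_error(cluster_umis_directional(setNames(1L, "ACGT")), "length")
})

test_that("clustering equals the transitive-closure oracle on random instances", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(1:8, 1)
    base <- random_dna(10)
    umis <- unique(c(base, vapply(seq_len(n - 1), function(i)
      mutate_string(base, sample(1:2, 1)), character(1))))
    counts <- setNames(sample(1:12, length(umis), replace = TRUE), umis)
    got <- partition_of(cluster_umis_directional(counts))
    want <- partition_of(directional_partition_oracle(counts))
    expect_identical(got, want)
  }
})

test_that("collapse conserves reads and is invariant to input order", {
  p <- test_panel()
  sim <- ref_sim()
  aln <- ref_aln()
  tpl <- ref_templates()
  n_proper <- sum(aln$pairs$status == "proper")
  expect_equal(sum(tpl$templates$read_count) + tpl$discarded, n_proper)
  # permuted input reads give the identical template table
  set.seed(11)
  reads2 <- sim$reads[sample(nrow(sim$reads))]
  aln2 <- align_sample(assign_primer_and_umi(reads2, p), p)
  tpl2 <- collapse(aln2, p)
  key <- function(t) {
    k <- t$templates[, c("primer", "r2_tx", "rt_coord", "umi",
                         "read_count")]
    k[order(k$primer, k$r2_tx, k$rt_coord, k$umi), ]
  }
  expect_equal(as.data.frame(key(tpl2)), as.data.frame(key(tpl)),
               ignore_attr = TRUE)
  expect_equal(tpl2$total_templates, tpl$total_templates)
})

test_that("recovered templates match the ledger's information limit", {
  # applying the directional rule directly to the true ledger keys and
  # decamers gives the number of templates that remain distinguishable;
  # the pipeline recovers exactly that at zero sequencing error
  p <- test_panel()
  sim <- ref_sim()
  aln <- ref_aln()
  lg <- sim$ledger
  # restrict to reads that survived alignment (a handful of very short
  # inserts legitimately fail the score floor)
  proper_tid <- sub(":D.*$", "", aln$pairs$id[aln$pairs$status == "proper"])
  n_proper <- table(proper_tid)
  lg <- lg[lg$template_id %in% names(n_proper)]
  lg$duplicate_count <- as.integer(n_proper[lg$template_id])
  keyv <- paste(lg$primer, lg$transcript, lg$rt_coordinate)
  truth_clusters <- 0L
  for (kk in unique(keyv)) {
    sel <- keyv == kk
    cnt <- tapply(lg$duplicate_count[sel], lg$umi_obs[sel], sum)
    truth_clusters <- truth_clusters +
      length(cluster_umis_directional(setNames(as.integer(cnt),
                                               names(cnt))))
  }
  tpl <- ref_templates()
  expect_equal(tpl$total_templates, truth_clusters)
  # and the residual undercount versus the true template count is small
  expect_gt(tpl$total_templates / nrow(lg), 0.95)
})

test_that("template counting respects half-open fragment intervals", {
  p <- test_panel()
  frag <- fragment_for("DDX23", p)
  mk <- function(start, rt) {
    structure(list(templates = data.table::data.table(
      template_id = "C1", primer = "DDX23_e8_9_F",
      transcript = frag$transcript, r2_tx = frag$transcript,
      rt_coord = rt, umi = A10, read_count = 1L, start = start)),
      class = "race_templates")
  }
  # abutting the fragment start (half-open) does not count
  expect_equal(count_templates(mk(1000L, frag$start), frag), 0L)
  # one nucleotide of overlap counts
  expect_equal(count_templates(mk(1000L, frag$start + 1L), frag), 1L)
  # abutting the fragment end does not count
  expect_equal(count_templates(mk(frag$end, frag$end + 50L), frag), 0L)
  expect_equal(count_templates(mk(frag$end - 1L, frag$end + 50L), frag), 1L)
})

test_that("off-target pairs are discarded and counted", {
  p <- test_panel()
  # craft a pair from a region with no fragment or hotspot: deep inside
  # BICC1 (a partner transcript carries no panel intervals), using a
  # synthetic primer-like read that still matches a real primer prefix
  prim <- p$primers[p$primers$name == "IDH1_R132_F", ]
  body <- substr(p$transcriptome$seqs[["IDH1_tx"]], prim$end + 1,
                 prim$end + 100)
  reads <- data.table::data.table(
    id = "x", r1 = paste0(prim$sequence, body),
    q1 = strrep("?", nchar(prim$sequence) + 100),
    r2 = paste0(strrep("A", 10),
                revcomp(substr(body, 60, 100))),
    q2 = strrep("?", 51))
  aln <- align_sample(assign_primer_and_umi(reads, p), p)
  tpl <- collapse(aln, p)
  # this pair IS on-target (IDH1 amplicon); now shrink the panel so the
  # same region has no interval and verify the discard counter
  p2 <- p
  p2$fragments <- p$fragments[p$fragments$gene != "IDH1", ]
  p2$hotspots <- p$hotspots[p$hotspots$gene != "IDH1", ]
  p2$.cache <- new.env(parent = emptyenv())
  tpl2 <- collapse(aln, p2)
  expect_equal(tpl$discarded, 0L)
  expect_equal(tpl$total_templates, 1L)
  expect_equal(tpl2$discarded, 1L)
  expect_equal(tpl2$total_templates, 0L)
})

test_that("single reads collapse to themselves", {
  tpl <- ref_templates()
  singles <- tpl$templates[tpl$templates$read_count == 1L]
  expect_gt(nrow(singles), 0L)
  # a template with one member read has that read's consensus
  one <- singles$template_id[1]
  mem <- tpl$members[tpl$members$template_id == one]
  expect_equal(nrow(mem), 1L)
})
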