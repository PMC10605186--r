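test_that("an exact substring aligns full-length with nm = 0", {
  p <- test_panel()
  s <- substr(p$transcriptome$seqs[["FGFR2_tx"]], 501, 600)
  rec <- seed_and_extend(s, p)
  expect_gte(nrow(rec), 1L)
  expect_equal(rec$transcript[1], "FGFR2_tx")
  expect_equal(rec$r_start[1], 500L)
  expect_equal(rec$nm[1], 0L)
  expect_equal(rec$score[1], 100)
  expect_equal(rec$clip5[1] + rec$clip3[1], 0L)
})

test_that("a random 100-mer absent from the panel aligns nowhere", {
  set.seed(123)
  p <- test_panel()
  expect_equal(nrow(seed_and_extend(random_dna(100), p)), 0L)
  expect_error(seed_and_extend("ACGT", p), "seed length")
})

test_that("a chimeric read soft-clips exactly at the anchor boundary", {
  p <- test_panel()
  b <- p$anchors$boundary[p$anchors$gene == "FGFR2" &
                            p$anchors$exon == 17][1]
  left <- substr(p$transcriptome$seqs[["FGFR2_tx"]], b - 59, b)
  right <- substr(p$transcriptome$seqs[["BICC1_tx"]], 401, 460)
  rec <- seed_and_extend(paste0(left, right), p)
  top <- rec[rec$transcript == "FGFR2_tx"][1]
  expect_equal(top$r_end, b)
  expect_equal(top$clip3, 60L)
  bic <- rec[rec$transcript == "BICC1_tx"][1]
  expect_equal(bic$r_start - bic$q_start, 400L - 60L)
})

test_that("seed-and-extend scores equal a full DP oracle", {
  set.seed(77)
  ref <- random_dna(500)
  exons <- data.frame(transcript = "T1", exon = 1L, start = 0L, end = 500L)
  tx <- race_transcriptome(c(T1 = ref), exons, gene = c(T1 = "G"))
  toy <- suppressWarnings(structure(
    list(transcriptome = tx, primers = data.frame(),
         fragments = data.frame(), hotspots = data.frame(),
         anchors = data.frame(), name = "toy", version = "0",
         .cache = new.env()), class = "race_panel"))
  n_agree <- 0L
  for (i in 1:50) {
    st <- sample(1:300, 1)
    len <- sample(60:200, 1)
    read <- mutate_string(substr(ref, st, min(st + len, 500)),
                          n_mut = rbinom(1, len, 0.04))
    rec <- seed_and_extend(read, toy, align_params(seed_stride = 2L))
    oracle <- sw_score_oracle(read, ref)
    if (nrow(rec) > 0 && isTRUE(all.equal(rec$score[1], oracle)))
      n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 50L)
})

test_that("primer assignment matches the simulation ledger exactly", {
  sim <- ref_sim()
  p <- test_panel()
  as <- assign_primer_and_umi(sim$reads, p)
  expect_true(all(as$assigned))
  lg <- sim$ledger
  truth_primer <- lg$primer[match(sub(":D.*$", "", as$id), lg$template_id)]
  expect_equal(as$primer, truth_primer)
  expect_equal(as$primer_mm, rep(0L, nrow(as)))
  # observed pseudo-UMI is the R2 prefix
  truth_umi <- lg$umi_obs[match(sub(":D.*$", "", as$id), lg$template_id)]
  expect_equal(as$umi, truth_umi)
})

test_that("mismatched prefixes beyond the threshold are unassigned", {
  p <- test_panel()
  prim <- p$primers$sequence[1]
  body <- substr(p$transcriptome$seqs[[p$primers$transcript[1]]],
                 p$primers$end[1] + 1, p$primers$end[1] + 120)
  ok <- paste0(prim, body)
  set.seed(5)
  bad <- paste0(mutate_string(substr(prim, 1, 10), 3), substr(prim, 11, 22),
                body)
  reads <- data.table::data.table(
    id = c("a", "b"), r1 = c(ok, bad),
    q1 = strrep("?", nchar(ok)),
    r2 = strrep("A", 40), q2 = strrep("?", 40))
  as <- assign_primer_and_umi(reads, p)
  expect_true(as$assigned[1])
  expect_equal(as$primer_mm[1], 0L)
  expect_false(as$assigned[2])
})

test_that("error-free pairs align at their ledger coordinates", {
  sim <- ref_sim()
  p <- test_panel()
  aln <- ref_aln()
  expect_equal(unname(aln$counts["improper"]), 0L)
  lg <- sim$ledger
  rec1 <- aln$records[aln$records$mate == 1L]
  m <- match(sub(":D.*$", "", rec1$read_id), lg$template_id)
  pidx <- match(lg$primer[m], p$primers$name)
  # R1 (primer-trimmed) starts at the primer 3' end on the true transcript
  expect_true(all(rec1$transcript == lg$transcript[m]))
  expect_true(all(rec1$r_start - rec1$q_start == p$primers$end[pidx]))
  rec2 <- aln$records[aln$records$mate == 2L]
  m2 <- match(sub(":D.*$", "", rec2$read_id), lg$template_id)
  # R2 alignment ends at the RT-priming coordinate
  expect_true(mean(rec2$r_end == lg$rt_coordinate[m2]) > 0.995)
})

test_that("soft clips and aligned length always sum to the read length", {
  aln <- ref_aln()
  rec <- aln$records
  ops <- regmatches(rec$cigar, gregexpr("[0-9]+[MI]", rec$cigar))
  consumed <- vapply(ops, function(o)
    sum(as.integer(sub("[MI]", "", o))), numeric(1))
  expect_true(all(rec$clip5 + consumed + rec$clip3 == nchar(rec$seq)))
})

test_that("R2 reads too short to seed leave the pair half-mapped", {
  p <- test_panel()
  prim <- p$primers$sequence[1]
  body <- substr(p$transcriptome$seqs[[p$primers$transcript[1]]],
                 p$primers$end[1] + 1, p$primers$end[1] + 120)
  reads <- data.table::data.table(
    id = "a", r1 = paste0(prim, body), q1 = strrep("?", 142),
    r2 = strrep("A", 14), q2 = strrep("?", 14))  # 10 UMI + 4 nt
  as <- assign_primer_and_umi(reads, p)
  aln <- align_sample(as, p)
  expect_equal(unname(aln$counts["half_mapped"]), 1L)
  expect_equal(nrow(aln$records), 0L)
})
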