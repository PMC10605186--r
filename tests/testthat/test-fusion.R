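test_that("fusion naming reproduces the conventional notation", {
  expect_equal(name_fusion("FGFR2", 17, "AHCYL1", 2), "FGFR2-AHCYL1 (F17;A2)")
  expect_equal(name_fusion("FGFR2", 17, "BICC1", 3), "FGFR2-BICC1 (F17;B3)")
  expect_equal(name_fusion("FGFR2", 17, "VCL", 2), "FGFR2-VCL (F17;V2)")
  expect_equal(name_fusion("FGFR2", 17, "BICC1", 16), "FGFR2-BICC1 (F17;B16)")
  expect_equal(name_fusion("FGFR2", 17, "CCDC6", 2), "FGFR2-CCDC6 (F17;C2)")
  expect_equal(name_fusion("FGFR2", 17, "CFAP57", 12), "FGFR2-CFAP57 (F17;C12)")
  expect_equal(name_fusion("FGFR2", 17, "LRBA", 48), "FGFR2-LRBA (F17;L48)")
  expect_equal(name_fusion("FGFR2", 17, "LRRFIP2", 3), "FGFR2-LRRFIP2 (F17;L3)")
  expect_equal(name_fusion("FGFR2", 17, "SLMAP", 3), "FGFR2-SLMAP (F17;S3)")
  expect_equal(name_fusion("FGFR2", 17, "SORBS1", 3), "FGFR2-SORBS1 (F17;S3)")
  expect_equal(name_fusion("FGFR2", 17, "ZMYM4", 2), "FGFR2-ZMYM4 (F17;Z2)")
  expect_equal(name_fusion("FGFR2", 17, "UNKNOWN"), "FGFR2-UNKNOWN (F17;?)")
  expect_equal(name_fusion("FGFR2", 18, "BICC1", NA), "FGFR2-BICC1 (F18;B?)")
})

test_that("candidate clustering applies support and UMI thresholds", {
  p <- test_panel()
  b <- p$anchors$boundary[p$anchors$gene == "FGFR2" &
                            p$anchors$exon == 17][1]
  mk_cand <- function(n, partner_tx, partner_gene, ps, umis = NULL) {
    data.table::data.table(
      template_id = sprintf("C%03d", seq_len(n)), anchor_gene = "FGFR2",
      anchor_exon = 17L, breakpoint = b, tail_seq = strrep("A", 30),
      partner_tx = partner_tx, partner_gene = partner_gene,
      partner_start = ps,
      umi = if (is.null(umis)) replicate(n, random_dna(10)) else umis)
  }
  set.seed(12)
  # six concordant candidates -> one call with support 6
  calls <- cluster_calls(mk_cand(6, "BICC1_tx", "BICC1", 400L), p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$supporting_templates, 6L)
  expect_equal(calls$name, "FGFR2-BICC1 (F17;B3)")
  # four candidates at min_support 5 -> no call
  expect_equal(nrow(cluster_calls(mk_cand(4, "BICC1_tx", "BICC1", 400L),
                                  p)), 0L)
  # clonal artifact guard: 6 templates but a single pseudo-UMI
  expect_equal(nrow(cluster_calls(
    mk_cand(6, "BICC1_tx", "BICC1", 400L, umis = rep(strrep("A", 10), 6)),
    p)), 0L)
  # two partner genes -> two calls
  both <- rbind(mk_cand(6, "BICC1_tx", "BICC1", 400L),
                mk_cand(5, "VCL_tx", "VCL", 200L))
  calls <- cluster_calls(both, p)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$supporting_templates, c(6L, 5L))  # support-descending
  # unknown partner keeps its own call with '?' exon
  unk <- mk_cand(5, NA_character_, "UNKNOWN", NA_integer_)
  expect_equal(cluster_calls(unk, p)$name, "FGFR2-UNKNOWN (F17;?)")
})

test_that("simulated fusion templates yield candidates with aligned tails", {
  p <- test_panel()
  fus <- list(list(anchor_gene = "FGFR2", anchor_exon = 17L,
                   partner_transcript = "BICC1_tx",
                   partner_breakpoint = 400L, fraction = 0.5))
  tm <- truth_model(c(FGFR2 = 1, DDX23 = 1, GOLGA5 = 1, SEL1L = 1),
                    fusions = fus, n_templates = 600L,
                    seq_error_rate = 0, seed = 19L)
  sim <- simulate_sample(p, tm)
  aln <- align_sample(assign_primer_and_umi(sim$reads, p), p)
  tpl <- collapse(aln, p)
  cand <- find_candidates(tpl, aln, p)
  expect_gt(nrow(cand), 5L)
  expect_true(all(cand$anchor_gene == "FGFR2"))
  expect_true(all(cand$breakpoint == p$anchors$boundary[
    p$anchors$gene == "FGFR2" & p$anchors$exon == 17][1]))
  expect_true(all(cand$partner_gene == "BICC1"))
  expect_true(all(nchar(cand$tail_seq) >= 25))
  # wild-type-only sample yields no candidates at all
  tm0 <- truth_model(c(FGFR2 = 1, DDX23 = 1, GOLGA5 = 1, SEL1L = 1),
                     n_templates = 600L, seq_error_rate = 0, seed = 20L)
  sim0 <- simulate_sample(p, tm0)
  aln0 <- align_sample(assign_primer_and_umi(sim0$reads, p), p)
  cand0 <- find_candidates(collapse(aln0, p), aln0, p)
  expect_equal(nrow(cand0), 0L)
})

test_that("breakpoints are exact to the nucleotide without sequencing error", {
  p <- test_panel()
  fus <- list(list(anchor_gene = "FGFR2", anchor_exon = 17L,
                   partner_transcript = "CCDC6_tx",
                   partner_breakpoint = 200L, fraction = 0.5))
  tm <- truth_model(c(FGFR2 = 1, DDX23 = 1, GOLGA5 = 1, SEL1L = 1),
                    fusions = fus, n_templates = 500L,
                    seq_error_rate = 0, seed = 23L)
  sim <- simulate_sample(p, tm)
  aln <- align_sample(assign_primer_and_umi(sim$reads, p), p)
  tpl <- collapse(aln, p)
  calls <- call_fusions(tpl, aln, p)
  expect_equal(nrow(calls), 1L)
  b <- p$anchors$boundary[p$anchors$gene == "FGFR2" &
                            p$anchors$exon == 17][1]
  expect_equal(calls$breakpoint, b)
  expect_equal(calls$partner_start, 200L)
  expect_equal(calls$name, "FGFR2-CCDC6 (F17;C2)")
})

test_that("unknown partners outside the transcriptome are reported as such", {
  p <- test_panel()
  set.seed(55)
  novel <- random_dna(600)
  fus <- list(list(anchor_gene = "FGFR2", anchor_exon = 17L,
                   partner_sequence = novel, fraction = 0.5))
  tm <- truth_model(c(FGFR2 = 1, DDX23 = 1, GOLGA5 = 1, SEL1L = 1),
                    fusions = fus, n_templates = 500L,
                    seq_error_rate = 0, seed = 29L)
  sim <- simulate_sample(p, tm)
  aln <- align_sample(assign_primer_and_umi(sim$reads, p), p)
  calls <- call_fusions(collapse(aln, p), aln, p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene3, "UNKNOWN")
  expect_equal(calls$name, "FGFR2-UNKNOWN (F17;?)")
})
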