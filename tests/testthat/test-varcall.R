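mk_pileup <- function(rows) {
  pc <- data.table::rbindlist(rows)
  dep <- pc[, .(depth = sum(count)), by = .(transcript, pos)]
  merge(pc, dep, by = c("transcript", "pos"))
}

test_that("pileup columns cover exactly the consensus positions", {
  p <- test_panel()
  tpl <- ref_templates()
  pc <- pileup(tpl, p)
  expect_true(all(pc$depth >= pc$count))
  # depth equals the number of distinct templates at each position
  chk <- pc[, .(s = sum(count), d = depth[1]), by = .(transcript, pos)]
  expect_true(all(chk$s == chk$d))
  # error-free uniform simulation: no non-reference allele reaches 3
  ref <- substr(p$transcriptome$seqs[pc$transcript], pc$pos + 1,
                pc$pos + 1)
  expect_true(all(pc$count[pc$allele != ref] < 3))
})

test_that("calling thresholds gate candidates as specified", {
  p <- test_panel()
  idh1_pos <- p$hotspots$start[p$hotspots$label == "IDH1 p.R132"]
  other_pos <- 50L  # inside the IDH1 amplicon fragment, not a hotspot
  mk <- function(pos, alt_n, depth, qual = 35) {
    ref <- substr(p$transcriptome$seqs[["IDH1_tx"]], pos + 1, pos + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    list(data.table::data.table(transcript = "IDH1_tx", pos = pos,
                                allele = ref, count = depth - alt_n,
                                mean_qual = qual),
         data.table::data.table(transcript = "IDH1_tx", pos = pos,
                                allele = alt, count = alt_n,
                                mean_qual = qual))
  }
  # depth 100, 7 alt templates at a hotspot -> PASS with VAF 0.07
  calls <- call_variants(mk_pileup(mk(idh1_pos, 7L, 100L)), p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$filter, "PASS")
  expect_equal(calls$vaf, 0.07)
  expect_equal(calls$hotspot, "IDH1 p.R132")
  # a single alt template is never a candidate
  expect_equal(nrow(call_variants(mk_pileup(mk(idh1_pos, 1L, 100L)), p)),
               0L)
  # non-hotspot position needs 5% VAF
  c2 <- call_variants(mk_pileup(mk(other_pos, 4L, 100L)), p)
  expect_equal(c2$filter, "LOW_VAF")
  c3 <- call_variants(mk_pileup(mk(other_pos, 6L, 100L)), p)
  expect_equal(c3$filter, "PASS")
  # hotspot floor keeps 3% calls at hotspots
  c4 <- call_variants(mk_pileup(mk(idh1_pos, 3L, 100L)), p)
  expect_equal(c4$filter, "PASS")
  # depth floor
  c5 <- call_variants(mk_pileup(mk(idh1_pos, 3L, 40L)), p)
  expect_equal(c5$filter, "LOW_DEPTH")
  # quality floor
  c6 <- call_variants(mk_pileup(mk(idh1_pos, 7L, 100L, qual = 10)), p)
  expect_equal(c6$filter, "LOW_QUAL")
})

test_that("raising the VAF floor never enlarges the call set", {
  p <- test_panel()
  set.seed(808)
  for (rep in 1:20) {
    pos <- sample(30:120, 1)
    alt_n <- sample(3:30, 1)
    pu <- mk_pileup(list(
      data.table::data.table(transcript = "IDH1_tx", pos = pos,
                             allele = substr(p$transcriptome$seqs[["IDH1_tx"]],
                                             pos + 1, pos + 1),
                             count = 100L - alt_n, mean_qual = 35),
      data.table::data.table(transcript = "IDH1_tx", pos = pos,
                             allele = "A", count = alt_n, mean_qual = 35)))
    floors <- sort(runif(3, 0.01, 0.4))
    sets <- lapply(floors, function(f) {
      cc <- call_variants(pu, p, varcall_thresholds(min_vaf_other = f,
                                                    min_vaf_hotspot = f))
      paste(cc$transcript[cc$filter == "PASS"], cc$pos[cc$filter == "PASS"],
            cc$alt[cc$filter == "PASS"])
    })
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
})

test_that("hotspot substitutions get protein-level annotation", {
  p <- test_panel()
  cs <- p$transcriptome$cds_start[["IDH1_tx"]]
  pos <- cs + 3L * 131L  # first base of codon 132 (CGT)
  mkcall <- function(pos, alt) data.frame(
    transcript = "IDH1_tx", pos = pos, ref = substr(
      p$transcriptome$seqs[["IDH1_tx"]], pos + 1, pos + 1), alt = alt,
    alt_templates = 10L, depth = 100L, vaf = 0.1, mean_qual = 35,
    hotspot = "IDH1 p.R132", filter = "PASS", protein = NA_character_,
    stringsAsFactors = FALSE)
  # CGT -> TGT is p.R132C
  out <- annotate_protein(mkcall(pos, "T"), p)
  expect_equal(out$protein, "IDH1 p.R132C")
  # CGT -> CTT is p.R132L
  out <- annotate_protein(mkcall(pos + 1L, "T"), p)
  expect_equal(out$protein, "IDH1 p.R132L")
  # synonymous CGT -> CGC gets no label
  out <- annotate_protein(mkcall(pos + 2L, "C"), p)
  expect_true(is.na(out$protein))
  # non-hotspot calls are untouched
  nh <- mkcall(pos, "T"); nh$hotspot <- NA_character_
  expect_true(is.na(annotate_protein(nh, p)$protein))
})

test_that("a 7% IDH1 hotspot spike-in is called with accurate VAF", {
  p <- test_panel()
  cs <- p$transcriptome$cds_start[["IDH1_tx"]]
  pos <- cs + 3L * 131L
  vars <- list(list(transcript = "IDH1_tx", pos = pos, ref = "C",
                    alt = "T", af = 0.07))
  tm <- truth_model(full_weights(list(IDH1 = 30)), variants = vars,
                    n_templates = 2000L, seed = 77L)
  sim <- simulate_sample(p, tm)
  rep <- run_pipeline(panel = p, reads = sim$reads)
  hit <- rep$variants[rep$variants$pos == pos, , drop = FALSE]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$protein, "IDH1 p.R132C")
  expect_gt(hit$depth, 200L)
  # estimated VAF tracks the realised simulation fraction
  lg <- sim$ledger[sim$ledger$transcript == "IDH1_tx" &
                     sim$ledger$primer == "IDH1_R132_F", ]
  realised <- mean(lg$variants != "")
  expect_lt(abs(hit$vaf - realised), 0.03)
})

test_that("VCF emission round-trips and formats VAF to 4 decimals", {
  p <- test_panel()
  calls <- data.frame(
    transcript = c("IDH1_tx", "KRAS_tx"), pos = c(396L, 225L),
    ref = c("C", "G"), alt = c("T", "A"), alt_templates = c(7L, 12L),
    depth = c(100L, 180L), vaf = c(0.07, 0.0666667), mean_qual = 35,
    hotspot = c("IDH1 p.R132", NA), filter = "PASS",
    protein = c("IDH1 p.R132C", NA), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, p, f)
  txt <- readLines(f)
  expect_true(any(grepl("VAF=0.0700", txt, fixed = TRUE)))
  expect_true(any(grepl("VAF=0.0667", txt, fixed = TRUE)))
  back <- read_vcf(f)
  expect_equal(back$transcript, calls$transcript)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$protein[1], "IDH1 p.R132C")
  # an established VCF parser reads the same records
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(nrow(v@fix), 2L)
  expect_equal(unname(v@fix[, "POS"]), as.character(calls$pos + 1L))
  # empty call set -> header-only VCF
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], p, f2)
  expect_true(all(startsWith(readLines(f2), "#")))
})
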