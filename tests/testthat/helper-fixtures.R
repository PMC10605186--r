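# Shared fixtures and independent oracles for the test suite.
# Heavy objects (the built-in panel, reference simulations) are memoised
# so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

test_panel <- function() {
  if (is.null(.fixture_env$panel)) .fixture_env$panel <- builtin_panel()
  .fixture_env$panel
}

full_weights <- function(overrides = list()) {
  genes <- c("FGFR1", "FGFR2", "FGFR3", "FGFR4", "IDH1", "IDH2", "ERBB2",
             "KRAS", "NRAS", "BRAF", "PIK3CA", "CD274", "DDX23", "GOLGA5",
             "SEL1L")
  w <- setNames(rep(1, length(genes)), genes)
  for (g in names(overrides)) w[[g]] <- overrides[[g]]
  w
}

# error-free reference simulation shared across align / dedup / sam tests
ref_sim <- function() {
  if (is.null(.fixture_env$ref_sim)) {
    tm <- truth_model(full_weights(), n_templates = 800L,
                      seq_error_rate = 0, seed = 42L)
    .fixture_env$ref_sim <- simulate_sample(test_panel(), tm)
  }
  .fixture_env$ref_sim
}

ref_aln <- function() {
  if (is.null(.fixture_env$ref_aln)) {
    sim <- ref_sim()
    as <- assign_primer_and_umi(sim$reads, test_panel())
    .fixture_env$ref_aln <- align_sample(as, test_panel())
  }
  .fixture_env$ref_aln
}

ref_templates <- function() {
  if (is.null(.fixture_env$ref_tpl))
    .fixture_env$ref_tpl <- collapse(ref_aln(), test_panel())
  .fixture_env$ref_tpl
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_string <- function(s, n_mut) {
  ch <- strsplit(s, "")[[1]]
  at <- sample(length(ch), n_mut)
  for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# exhaustive 3'-seed scan: every transcript position compared by Hamming
brute_force_seed_scan <- function(seed, transcriptome, max_mm = 1L) {
  hits <- list()
  k <- nchar(seed)
  sc <- strsplit(seed, "")[[1]]
  for (txid in names(transcriptome$seqs)) {
    s <- transcriptome$seqs[[txid]]
    L <- nchar(s)
    if (L < k) next
    for (st in 0:(L - k)) {
      wc <- strsplit(substr(s, st + 1, st + k), "")[[1]]
      if (sum(wc != sc) <= max_mm)
        hits[[length(hits) + 1L]] <- data.frame(transcript = txid,
                                                start = st)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(transcript = character(0), start = integer(0))
}

# small three-gene toy transcriptome for panel validation tests
toy_transcriptome <- function(seed = 99L) {
  set.seed(seed)
  seqs <- c(G1_tx = random_dna(600), G2_tx = random_dna(600),
            DDX23_tx = random_dna(600))
  exons <- do.call(rbind, lapply(names(seqs), function(tx)
    data.frame(transcript = tx, exon = 1:3, start = c(0L, 200L, 400L),
               end = c(200L, 400L, 600L))))
  race_transcriptome(seqs, exons,
                     gene = c(G1_tx = "G1", G2_tx = "G2",
                              DDX23_tx = "DDX23"))
}

# partition comparison helper: clusters as canonical sorted member sets
partition_of <- function(clusters) {
  sets <- lapply(clusters, function(cl)
    sort(if (is.list(cl)) cl$members else cl))
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}
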