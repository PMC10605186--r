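# Built-in synthetic panel fixture.
#
# The real enrichment primer sequences of the assay are not public, so the
# package ships a fully synthetic panel: random transcript sequences with
# planted canonical hotspot codons, plausible exon structures, and primers
# that are exact substrings of those transcripts. The gene set, the
# primer-category census (29 + 3 + 9 + 7 + 1 + 17 + 1 + 3), the referee
# trio, the expression fragments, and the FGFR fusion anchor boundaries
# all mirror the published panel design; the nucleotide sequences do not
# correspond to any real gene.

.with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.plant <- function(seq, at, piece) {  # at: 0-based
  paste0(substr(seq, 1, at), piece, substr(seq, at + 1 + nchar(piece),
                                           nchar(seq)))
}

#' The built-in synthetic biliary-tract-cancer panel
#'
#' Deterministically generates the synthetic panel bundled with the
#' package: 70 enrichment primers over FGFR1-4, IDH1/2, ERBB2, KRAS/NRAS,
#' BRAF, PIK3CA and PD-L1 (CD274) plus the three referee genes DDX23,
#' GOLGA5 and SEL1L, together with expression fragments at the annotated
#' exon junctions, hotspot codons planted with their canonical reference
#' codons, FGFR fusion anchor boundaries, and four fusion partner
#' transcripts (BICC1, AHCYL1, VCL, CCDC6) that carry no primers.
#' Sequences are synthetic; coordinates and structure are the panel's.
#'
#' @return a validated `race_panel`.
#' @export
builtin_panel <- function() {
  .with_preserved_rng({
    set.seed(20231010L)
    EX <- 160L
    genes <- list(
      # gene, n_exons, exon_len, cds_start, category
      FGFR1  = list(nex = 18L, category = "FGFR1-4"),
      FGFR2  = list(nex = 19L, category = "FGFR1-4"),
      FGFR3  = list(nex = 16L, category = "FGFR1-4"),
      FGFR4  = list(nex = 16L, category = "FGFR1-4"),
      IDH1   = list(nex = 6L,  category = "IDH1/2"),
      IDH2   = list(nex = 8L,  category = "IDH1/2"),
      ERBB2  = list(nex = 22L, category = "ERBB2"),
      KRAS   = list(nex = 5L,  category = "KRAS/NRAS", cds = 190L),
      NRAS   = list(nex = 4L,  category = "KRAS/NRAS", cds = 190L),
      BRAF   = list(nex = 18L, category = "BRAF", cds = 500L),
      PIK3CA = list(nex = 22L, category = "PIK3CA"),
      CD274  = list(nex = 7L,  category = "PD-L1"),
      DDX23  = list(nex = 10L, category = "referee"),
      GOLGA5 = list(nex = 7L,  category = "referee"),
      SEL1L  = list(nex = 15L, category = "referee"),
      BICC1  = list(nex = 6L, exlen = 200L, category = NA),
      AHCYL1 = list(nex = 5L, exlen = 200L, category = NA),
      VCL    = list(nex = 4L, exlen = 200L, category = NA),
      CCDC6  = list(nex = 4L, exlen = 200L, category = NA)
    )
    seqs <- character(0); gmap <- character(0); cds <- integer(0)
    exons <- list()
    for (g in names(genes)) {
      sp <- genes[[g]]
      el <- if (is.null(sp$exlen)) EX else sp$exlen
      L <- sp$nex * el
      tx <- paste0(g, "_tx")
      seqs[[tx]] <- .rand_seq(L)
      gmap[[tx]] <- g
      cds[[tx]] <- if (is.null(sp$cds)) 0L else sp$cds
      exons[[tx]] <- data.frame(transcript = tx, exon = seq_len(sp$nex),
                                start = (seq_len(sp$nex) - 1L) * el,
                                end = seq_len(sp$nex) * el)
    }
    # canonical hotspot codons planted at their protein coordinates
    codon_pos <- function(tx, codon) cds[[tx]] + 3L * (codon - 1L)
    hs_codons <- list(
      list("FGFR2", 203L, "CGT", "FGFR2 p.R203"),
      list("FGFR2", 276L, "TTC", "FGFR2 p.F276"),
      list("FGFR2", 382L, "TGC", "FGFR2 p.C382"),
      list("FGFR2", 547L, "ATC", "FGFR2 p.I547"),
      list("FGFR2", 659L, "AAA", "FGFR2 p.K659"),
      list("IDH1",  132L, "CGT", "IDH1 p.R132"),
      list("IDH2",  140L, "CGG", "IDH2 p.R140"),
      list("IDH2",  172L, "AGG", "IDH2 p.R172"),
      list("ERBB2", 310L, "TCC", "ERBB2 p.S310"),
      list("ERBB2", 678L, "CGG", "ERBB2 p.R678"),
      list("KRAS",  12L,  "GGT", "KRAS p.G12"),
      list("KRAS",  13L,  "GGC", "KRAS p.G13"),
      list("KRAS",  61L,  "CAA", "KRAS p.Q61"),
      list("KRAS",  146L, "GCA", "KRAS p.A146"),
      list("NRAS",  12L,  "GGT", "NRAS p.G12"),
      list("NRAS",  61L,  "CAA", "NRAS p.Q61"),
      list("BRAF",  600L, "GTG", "BRAF p.V600"),
      list("PIK3CA", 542L, "GAA", "PIK3CA p.E542"),
      list("PIK3CA", 545L, "GAG", "PIK3CA p.E545"),
      list("PIK3CA", 1047L, "CAT", "PIK3CA p.H1047")
    )
    for (h in hs_codons) {
      tx <- paste0(h[[1]], "_tx")
      seqs[[tx]] <- .plant(seqs[[tx]], codon_pos(tx, h[[2]]), h[[3]])
    }
    hotspots <- do.call(rbind, lapply(hs_codons, function(h)
      data.frame(type = "codon", gene = h[[1]],
                 transcript = paste0(h[[1]], "_tx"), codon = h[[2]],
                 start = NA_integer_, end = NA_integer_, label = h[[4]])))
    hs_regions <- data.frame(
      type = "region",
      gene = c("KRAS", "NRAS", "BRAF", "FGFR2", "PIK3CA", "PIK3CA"),
      transcript = paste0(c("KRAS", "NRAS", "BRAF", "FGFR2", "PIK3CA",
                            "PIK3CA"), "_tx"),
      codon = NA_integer_,
      start = c(160L, 160L, 2240L, 1550L, 1600L, 3100L),
      end = c(640L, 480L, 2400L, 1700L, 1700L, 3180L),
      label = c("KRAS exons 2-4", "NRAS exons 2-3", "BRAF exon 15",
                "FGFR2 kinase", "PIK3CA helical", "PIK3CA kinase"))
    hotspots <- rbind(hotspots, hs_regions)

    # measurement fragments at the annotated exon junctions
    junction_frag <- function(g, e1, role) {
      tx <- paste0(g, "_tx")
      ex <- exons[[tx]]
      j <- ex$end[ex$exon == e1]
      data.frame(label = sprintf("%s_e%d_%d", g, e1, e1 + 1L), gene = g,
                 transcript = tx, start = j - 60L, end = j + 60L,
                 role = role)
    }
    fragments <- rbind(
      junction_frag("FGFR1", 17L, "expression-target"),
      junction_frag("FGFR2", 16L, "expression-target"),
      junction_frag("FGFR3", 14L, "expression-target"),
      junction_frag("FGFR4", 14L, "expression-target"),
      junction_frag("ERBB2", 19L, "expression-target"),
      junction_frag("CD274", 5L,  "expression-target"),
      junction_frag("DDX23", 8L,  "referee"),
      junction_frag("GOLGA5", 5L, "referee"),
      junction_frag("SEL1L", 13L, "referee"))

    anchors <- data.frame(
      gene = c("FGFR1", "FGFR2", "FGFR2", "FGFR3", "FGFR4"),
      transcript = paste0(c("FGFR1", "FGFR2", "FGFR2", "FGFR3", "FGFR4"),
                          "_tx"),
      exon = c(17L, 17L, 18L, 15L, 15L),
      boundary = c(17L * EX, 17L * EX, 17L * EX, 15L * EX, 15L * EX))

    # primers: 3' end placed `p3` on the transcript, all 22-mers
    PL <- 22L
    prim <- function(g, nm, p3) {
      tx <- paste0(g, "_tx")
      start <- p3 - PL
      data.frame(name = nm, gene = g, transcript = tx, start = start,
                 sequence = substr(seqs[[tx]], start + 1L, p3),
                 category = genes[[g]]$category)
    }
    expr_primer <- function(g, e1) {
      j <- exons[[paste0(g, "_tx")]]$end[exons[[paste0(g, "_tx")]]$exon == e1]
      prim(g, sprintf("%s_e%d_%d_F", g, e1, e1 + 1L), j - 70L)
    }
    anchor_primer <- function(g, exon, off = 70L) {
      b <- anchors$boundary[anchors$gene == g & anchors$exon == exon][1]
      prim(g, sprintf("%s_anch_e%d_F", g, exon), b - off)
    }
    generic <- function(g, k, p3s) {
      do.call(rbind, lapply(seq_len(k), function(i)
        prim(g, sprintf("%s_p%02d", g, i), p3s[i])))
    }
    primers <- rbind(
      expr_primer("FGFR1", 17L), anchor_primer("FGFR1", 17L, off = 40L),
      generic("FGFR1", 5L, c(400L, 800L, 1200L, 1600L, 2000L)),
      expr_primer("FGFR2", 16L), anchor_primer("FGFR2", 17L),
      prim("FGFR2", "FGFR2_e16_anch_F", 16L * EX - 40L),
      prim("FGFR2", "FGFR2_R203_F", codon_pos("FGFR2_tx", 203L) - 35L),
      prim("FGFR2", "FGFR2_F276_F", codon_pos("FGFR2_tx", 276L) - 35L),
      prim("FGFR2", "FGFR2_C382_F", codon_pos("FGFR2_tx", 382L) - 35L),
      prim("FGFR2", "FGFR2_kin1_F", codon_pos("FGFR2_tx", 547L) - 35L),
      prim("FGFR2", "FGFR2_kin2_F", codon_pos("FGFR2_tx", 659L) - 35L),
      expr_primer("FGFR3", 14L), anchor_primer("FGFR3", 15L),
      generic("FGFR3", 5L, c(400L, 800L, 1100L, 1500L, 1900L)),
      expr_primer("FGFR4", 14L), anchor_primer("FGFR4", 15L),
      generic("FGFR4", 5L, c(400L, 800L, 1100L, 1500L, 1900L)),
      prim("IDH1", "IDH1_R132_F", codon_pos("IDH1_tx", 132L) - 35L),
      prim("IDH2", "IDH2_R140_F", codon_pos("IDH2_tx", 140L) - 35L),
      prim("IDH2", "IDH2_R172_F", codon_pos("IDH2_tx", 172L) - 35L),
      expr_primer("ERBB2", 19L),
      prim("ERBB2", "ERBB2_S310_F", codon_pos("ERBB2_tx", 310L) - 35L),
      prim("ERBB2", "ERBB2_R678_F", codon_pos("ERBB2_tx", 678L) - 35L),
      generic("ERBB2", 6L, c(400L, 800L, 1200L, 1600L, 2400L, 2700L)),
      prim("KRAS", "KRAS_ex2_F", 200L), prim("KRAS", "KRAS_ex2b_F", 260L),
      prim("KRAS", "KRAS_ex3_F", 340L), prim("KRAS", "KRAS_ex4_F", 600L),
      prim("NRAS", "NRAS_ex2_F", 200L), prim("NRAS", "NRAS_ex2b_F", 250L),
      prim("NRAS", "NRAS_ex3_F", 340L),
      prim("BRAF", "BRAF_ex15_F", 2270L),
      prim("PIK3CA", "PIK3CA_hel_F", codon_pos("PIK3CA_tx", 542L) - 35L),
      prim("PIK3CA", "PIK3CA_kin_F", codon_pos("PIK3CA_tx", 1047L) - 35L),
      generic("PIK3CA", 15L, seq(200L, 3000L, by = 200L)),
      expr_primer("CD274", 5L),
      expr_primer("DDX23", 8L), expr_primer("GOLGA5", 5L),
      expr_primer("SEL1L", 13L))

    # every primer amplicon is on-target: add a covering hotspot-region
    # style fragment per primer (insert span is at most ~250 nt)
    amp <- data.frame(label = paste0("amp_", primers$name),
                      gene = primers$gene, transcript = primers$transcript,
                      start = primers$start,
                      end = pmin(primers$start + 280L,
                                 nchar(seqs[primers$transcript])),
                      role = "hotspot-region")
    frag_all <- rbind(fragments, amp,
                      data.frame(label = "FGFR2_anchor_region",
                                 gene = "FGFR2", transcript = "FGFR2_tx",
                                 start = 17L * EX - 170L,
                                 end = 17L * EX + 60L,
                                 role = "fusion-anchor"))
    exon_df <- do.call(rbind, exons)
    rownames(exon_df) <- NULL
    tx <- race_transcriptome(seqs, exon_df, gmap, cds)
    race_panel(tx, primers, frag_all, hotspots, anchors,
               name = "btc-race-panel-synthetic", version = "1.0")
  })
}
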