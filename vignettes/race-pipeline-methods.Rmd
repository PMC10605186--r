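---
title: "Methods: 3' RACE targeted RNA-seq analysis"
author: "raceseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3' RACE targeted RNA-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The assay and its analysis problem

A 3' RACE anchored multiplex PCR library fixes one end of every sequenced
molecule at a gene-specific enrichment primer and lets the other end be
set by a tailed random decamer that primes reverse transcription wherever
it happens to anneal. Two consequences drive the entire analysis design:

* **Fusions with unknown 3' partners are visible.** Any sequence
  downstream of the primer is captured, so a chimeric transcript that
  conserves the 5' gene up to a known anchor boundary (FGFR2 after exon
  17, or at the start of exon 18) carries its partner sequence into the
  read, whatever that partner is.
* **PCR duplicates are poorly discriminated.** Because the primer end is
  identical for all molecules of an amplicon, only a *single* coordinate
  — the RT-priming site, observed as the R2 alignment boundary — varies
  between molecules. Two distinct cDNA templates frequently share it.

The package resolves the second problem the way the assay itself
suggests: the decamer anneals permissively (the RT protocol includes a
25 °C step), so the ten bases *written into the molecule* frequently
mismatch the true mRNA sequence. Those written bases replace the template
bases in both reads, and the mismatch pattern is a molecular barcode — a
*pseudo-UMI* — that distinguishes co-coordinate templates.

# Pipeline model

Per sample, `run_pipeline()` composes:

1. **Preprocess** (`assign_primer_and_umi`): R1 must begin with a panel
   primer (the chemistry guarantees it); the unique best prefix match
   with at most 2 mismatches is assigned, ties or misses are dropped and
   counted. The R2 10-nt prefix is recorded as the observed pseudo-UMI.
   Primer, decamer and adapter read-through are trimmed; adapter
   trimming matters because a read that runs off the insert into the
   adapter would otherwise present a soft-clipped tail that mimics a
   fusion junction.
2. **Align** (`align_sample`): transcriptome-space only. R1 is aligned
   in a window anchored at the primer 3' end; a pair whose R1 start
   deviates from that coordinate by more than 2 nt is flagged improper —
   anchored PCR fixes this end, so deviation signals mispriming. R2 is
   reverse-complemented and aligned near the primer first, with a full
   seed-and-extend search as fallback (that fallback is what maps fusion
   partner sequence). The local aligner is an affine-gap Smith-Waterman
   (match 1, mismatch −2, gap open −4, extend −1) over exact 15-mer
   seeds grouped by diagonal; scores are validated against a plain-R
   dynamic-programming oracle in the test-suite.
3. **Collapse** (`collapse`): pairs are grouped exactly on (primer, R2
   transcript, RT coordinate); within each key, observed decamers are
   clustered with the *directional* adjacency rule — an edge u → v when
   Hamming distance is 1 and count(u) ≥ 2·count(v) − 1, clusters grown
   from unvisited highest-count seeds. Every cluster is one unique
   template; consensus bases are majority-vote with quality then
   reference tie-breaks, and the decamer-written positions are masked
   (their mismatches are the barcode, not the template).
4. **Variants** (`call_variants`): template-level pileup over panel
   fragments and hotspot regions. Defaults: depth ≥ 50 templates, ≥ 3
   alternate templates, mean allele quality ≥ Q20, VAF ≥ 2% at annotated
   hotspots and ≥ 5% elsewhere. Calling on templates rather than reads
   is essential — duplicates would otherwise inflate support and defeat
   the pseudo-UMI design. Hotspot substitutions are annotated at protein
   level from the transcript CDS.
5. **Fusions** (`call_fusions`): a template is a chimeric candidate if
   its R1 alignment ends within ±5 nt of an anchor boundary with a
   soft-clipped 3' tail of ≥ 25 nt; tails are re-aligned to the full
   bundled transcriptome and unalignable tails are kept with an UNKNOWN
   partner (3' RACE can recover partners absent from any annotation).
   Calls need ≥ 5 supporting templates carrying ≥ 2 distinct pseudo-UMIs
   — the UMI requirement guards against a clonal artifact amplified into
   apparent support. Names follow the conventional notation, e.g.
   `FGFR2-BICC1 (F17;B3)`.
6. **Expression** (`profile_sample`): unique-template counts on one
   measurement fragment per gene, divided by each of the three referee
   genes (DDX23, GOLGA5, SEL1L); the reported value is the median of the
   three ratios, which survives aberrant expression of any single
   referee. A sample with fewer than 3000 total templates is a QC
   failure (strictly less than; 3000 passes).

Reads are fully accounted: assigned + unassigned = input, and kept +
improper + half-mapped + off-target = assigned.

# The simulator and what it emulates

`simulate_sample()` is first-class, tested code that generates the exact
library architecture: R1 starts at the enrichment primer 5' end reading
sense; R2 starts at the decamer reading antisense; both reads run into
the verbatim adapter oligos when the insert is shorter than 150 nt, and
the decamer bases written into the molecule replace the template bases.
A `TruthLedger` records, per unique template, the primer, RT coordinate,
observed decamer and its mismatch positions, duplicate count, and
carried variants/fusions, which is what makes every downstream stage
testable without clinical data.

Choices a user should know, with rationale:

* **Template allocation.** Each enrichment primer samples the mRNA pool
  independently (one transcript molecule can serve several nested
  primers), so templates are allocated across primers proportionally to
  the *gene's* abundance weight. This is what makes per-fragment counts
  comparable between genes with different primer numbers, and it is the
  reading under which a 10× abundance spike recovers a 10× normalized
  value.
* **Insert length**: truncated normal, mean 120, sd 30, minimum 50 nt.
  The final libraries are about 250 bp including roughly 130 bp of
  adapter and index sequence, and the 80–150 bp RNA template range seen
  for FFPE-compatible kits matches this choice.
* **Duplicate counts**: 1 + Geometric(p), default p = 0.5. Exponential
  amplification with stochastic efficiency; nothing published constrains
  the true distribution, so the parameter is exposed.
* **RT decamer mismatch rate**: default 0.30 per base. The
  reverse-transcription program starts with 10 min at 25 °C, where a
  random decamer anneals highly permissively; a rate this high is what
  gives the written decamer enough diversity to act as a barcode. At
  0.30, two templates sharing coordinates present identical decamers
  only ~0.1% of the time, so the recovered template count tracks the
  truth closely (the duplicate-collapse tests check recovery above 95%
  and exact agreement with the information-limit oracle); at rates as
  low as 0.1 the same arithmetic merges several percent of
  co-coordinate templates, the regime in which single-coordinate
  deduplication is known to undercount coverage. The rate is a
  `truth_model()` field.
* **Qualities**: constant Q30 with uniformly placed substitution errors
  (default 0.001/base). Quality-aware error placement keeps the Q20
  allele-quality threshold meaningful without modelling instrument
  profiles.

What the simulator does **not** emulate: RNA degradation and FFPE
fragment-length bias, index hopping, DNase pretreatment, polymerase
error accumulation over cycles (duplicates of a template are sequenced
independently but share no PCR-era errors), and transcript-level
splicing variation. Passing tests therefore demonstrate correctness of
the *analysis* under the stated generative model, not performance on
clinical FFPE material.

# The bundled synthetic panel

The real enrichment primer sequences are not public, so the bundled
panel (`builtin_panel()`) is synthetic: random transcript sequences with
the canonical hotspot codons planted at their protein coordinates (IDH1
R132, IDH2 R140/R172, KRAS G12/G13/Q61/A146, BRAF V600, PIK3CA
E542/E545/H1047, ERBB2 S310/R678, FGFR2 R203/F276/C382/I547/K659),
primers that are exact 22-mer substrings at plausible positions, the
published primer-category census (29 FGFR1–4, 3 IDH1/2, 9 ERBB2, 7
KRAS/NRAS, 1 BRAF, 17 PIK3CA, 1 PD-L1, 3 referees; 70 total), referee
fragments at the annotated exon junctions (DDX23 e8–9, GOLGA5 e5–6,
SEL1L e13–14), FGFR anchor boundaries (FGFR2 at the 3' end of exon 17,
with the start-of-exon-18 class carried as a second anchor record), and
four partner transcripts (BICC1, AHCYL1, VCL, CCDC6) that carry no
primers. Everything is generated deterministically in code; sequences
correspond to no real gene.

# Numerical and design choices

* **Coordinates** are 0-based half-open internally; 1-based only in SAM
  and VCF output.
* **Alignment determinism**: the first maximal cell in row-major order
  wins; traceback prefers diagonal, then deletion, then insertion;
  candidate records sort by score, then transcript id, then start.
* **Score floor**: absolute minimum 25, scaled down to 80% of read
  length for short trimmed reads (a 28-nt trimmed R1 from a minimal
  insert cannot reach 25 even when perfect).
* **Directional threshold** count(u) ≥ 2·count(v) − 1 is the adjacency
  heuristic of the established UMI package; clustering is performed
  within coordinate keys, the only reading consistent with
  distinguishing "templates with the same coordinates".
* **Consensus ties** resolve by higher mean base quality, then the
  reference base.
* **Two-sided Fisher test**: probability-mass definition (total
  probability of margin-fixed tables no more probable than the observed
  one, relative tolerance 1e-7), computed by complete enumeration; this
  matches the convention of mainstream statistical environments and is
  cross-checked exhaustively against `stats::fisher.test`. Group order
  never changes a p-value.
* **`nd` handling** in marker tables: excluded listwise per marker, as
  the published denominators imply (82/43/40 for the mutation rows).
* **Expression ratios are linear**, not log; fragment-length
  normalization is not applied since all measurement fragments are of
  comparable designed length (120 nt).
* **Overexpression flag**: value > 5× the cohort median when a cohort
  median is supplied; the factor is configurable since no published
  cutoff exists.
* **Kruskal–Wallis** uses the chi-squared approximation (tie-corrected);
  for the age comparison no raw data exist to prefer an exact variant.
* **Indels** are limited to ≤ 10 nt within fragments; the panel targets
  substitution hotspots.

# Problem sizes used by the test-suite

Simulation-backed tests use 400–4000 templates per sample; the
fusion-detection property runs 10 fusion-positive plus 10
fusion-negative samples of 3200 templates at fusion fraction 0.25 on an
FGFR2-overexpressing background (fusion-positive tumours show elevated
FGFR2 expression, so the 3× weight is the realistic condition); variant
recovery runs 20 seeded samples of 2500 templates with spikes at 5, 10
and 25% VAF plus a 6.7% IDH1 p.R132L case at 3000 templates; expression
recovery uses a 4× ERBB2 spike at 10,000 templates. Oracle equivalence
checks run exhaustively on instances of ≤ 8 distinct UMIs and on 50
random read/reference pairs against a full dynamic-programming score.

# Known limitations

* 5'-unknown-partner fusions (the ALK/ROS1/RET/NTRK class) are
  undetectable by construction of the chemistry, and reciprocal
  breakpoints are out of scope.
* Tumor-only calling cannot separate germline from somatic variants;
  the panel's hotspot focus is the mitigation.
* Expression values are relative to the referees; low tumor purity or
  aberrant referee expression flags the sample rather than being
  corrected.
* Breakpoint microhomology between the anchor gene and the partner
  shifts the reported breakpoint by the homology length — consistently
  across templates, so clustering is unaffected.
* Recovered template counts are a lower bound: templates that share all
  coordinates *and* present identical written decamers are inherently
  indistinguishable.
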