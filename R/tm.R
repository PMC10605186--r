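# Nearest-neighbor melting temperature (unified NN parameters of
# SantaLucia 1998) for a perfect DNA duplex. dH in kcal/mol, dS in
# cal/(mol K); monovalent-salt correction 16.6 log10([Na+]).

.nn_dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

.iupac_expand <- c(A = "A", C = "C", G = "G", T = "T",
                   R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT",
                   M = "AC", B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                   N = "ACGT")

.expand_degenerate <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  opts <- .iupac_expand[ch]
  if (any(is.na(opts))) stop("non-IUPAC base in primer sequence")
  combos <- Reduce(function(acc, o) {
    unlist(lapply(acc, function(a) paste0(a, strsplit(o, "")[[1]])))
  }, opts, accumulate = FALSE, init = "")
  combos
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Computes the duplex melting temperature by the unified nearest-neighbor
#' model assuming a perfect duplex, with the standard entropic initiation
#' terms for terminal A/T and G/C pairs and a 16.6 log10(Na) monovalent
#' salt correction. Degenerate positions (at most two) are averaged over
#' their expansions.
#'
#' @param seq primer sequence, 5'->3' (IUPAC; at most 2 degenerate bases).
#' @param primer_conc total strand concentration in M (default 0.5e-6,
#'   the enrichment-mix concentration of each primer).
#' @param na_conc monovalent cation concentration in M (default 0.05).
#' @return melting temperature in Celsius, reported to 0.1 degree.
#' @export
primer_tm <- function(seq, primer_conc = 0.5e-6, na_conc = 0.05) {
  n_degen <- sum(!strsplit(toupper(seq), "")[[1]] %in% c("A", "C", "G", "T"))
  if (n_degen > 2)
    stop("primer has more than 2 degenerate IUPAC bases: unsupported")
  seqs <- .expand_degenerate(seq)
  tm1 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) < 2) stop("primer too short for a nearest-neighbor Tm")
    nn <- paste0(ch[-length(ch)], ch[-1])
    dH <- sum(.nn_dH[nn])
    dS <- sum(.nn_dS[nn])
    for (term in ch[c(1, length(ch))]) {
      if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
      else { dH <- dH + 2.3; dS <- dS + 4.1 }
    }
    tm <- 1000 * dH / (dS + 1.987 * log(primer_conc / 4)) - 273.15
    tm + 16.6 * log10(na_conc)
  }
  round(mean(vapply(seqs, tm1, numeric(1))), 1)
}

#' Screen a primer for anchored-PCR specificity
#'
#' In anchored multiplex PCR each gene-specific primer must on its own
#' hybridise to a single locus. The screen reports every transcriptome
#' site whose sequence matches the primer's 3'-terminal seed (default the
#' last 12 nt) with at most `max_offtarget_mismatches` mismatches, plus
#' the nearest-neighbor melting temperature of the full primer. A primer
#' with more than one site is flagged non-specific.
#'
#' @param primer one-row data.frame with at least `sequence`, and
#'   optionally `name`, `transcript`, `start` (annotated site), or a plain
#'   character sequence.
#' @param transcriptome a `race_transcriptome`.
#' @param seed_len length of the 3'-terminal seed (default 12).
#' @param max_offtarget_mismatches mismatches tolerated at off-target
#'   sites (default 1).
#' @param primer_conc,na_conc passed to [primer_tm()].
#' @return a list of class `race_specificity_report` with elements
#'   `primer`, `on_target_site`, `offtarget_sites` (data.frame
#'   transcript/start of the seed match), `tm_celsius`, `non_specific`.
#' @export
screen_primer_specificity <- function(primer, transcriptome, seed_len = 12L,
                                      max_offtarget_mismatches = 1L,
                                      primer_conc = 0.5e-6, na_conc = 0.05) {
  if (is.character(primer)) primer <- data.frame(sequence = primer)
  seq <- toupper(primer$sequence[1])
  n_degen <- sum(strsplit(seq, "")[[1]] %in%
                   setdiff(names(.iupac_expand), c("A", "C", "G", "T")))
  if (n_degen > 2)
    stop("primer has more than 2 degenerate IUPAC bases: unsupported")
  if (nchar(seq) < seed_len)
    stop("primer shorter than the specificity seed length")
  seed <- substr(seq, nchar(seq) - seed_len + 1L, nchar(seq))
  subject <- Biostrings::DNAStringSet(transcriptome$seqs)
  hits <- Biostrings::vmatchPattern(seed, subject,
                                    max.mismatch = max_offtarget_mismatches,
                                    fixed = "subject")
  sites <- do.call(rbind, lapply(seq_along(hits), function(i) {
    st <- Biostrings::startIndex(hits)[[i]]
    if (is.null(st) || length(st) == 0) return(NULL)
    # drop out-of-limit overhang matches
    L <- nchar(transcriptome$seqs[[i]])
    st <- st[st >= 1L & st + seed_len - 1L <= L]
    if (length(st) == 0) return(NULL)
    data.frame(transcript = names(transcriptome$seqs)[i], start = st - 1L)
  }))
  if (is.null(sites))
    sites <- data.frame(transcript = character(0), start = integer(0))
  on_target <- NULL
  if (!is.null(primer$transcript) && !is.null(primer$start)) {
    seed_start <- primer$start[1] + nchar(seq) - seed_len
    is_on <- sites$transcript == primer$transcript[1] &
      abs(sites$start - seed_start) <= 2L
    on_target <- sites[is_on, , drop = FALSE]
    sites <- sites[!is_on, , drop = FALSE]
  } else if (nrow(sites) >= 1) {
    # unannotated primer: call the best (first exact) site on-target
    exact <- which(vapply(seq_len(nrow(sites)), function(i) {
      s <- transcriptome$seqs[[sites$transcript[i]]]
      substr(s, sites$start[i] + 1L, sites$start[i] + seed_len) == seed
    }, logical(1)))
    pick <- if (length(exact)) exact[1] else 1L
    on_target <- sites[pick, , drop = FALSE]
    sites <- sites[-pick, , drop = FALSE]
  }
  structure(list(primer = seq,
                 name = if (!is.null(primer$name)) primer$name[1] else NA,
                 on_target_site = on_target,
                 offtarget_sites = sites,
                 tm_celsius = primer_tm(seq, primer_conc, na_conc),
                 non_specific = nrow(sites) > 0),
            class = "race_specificity_report")
}

#' @export
print.race_specificity_report <- function(x, ...) {
  cat(sprintf("<specificity report%s>\n",
              if (!is.na(x$name)) paste0(" ", x$name) else ""))
  cat(sprintf("  primer: %s (Tm %.1f C)\n", x$primer, x$tm_celsius))
  cat(sprintf("  off-target seed sites: %d%s\n", nrow(x$offtarget_sites),
              if (x$non_specific) "  ** non-specific **" else ""))
  invisible(x)
}
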