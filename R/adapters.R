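#' Library oligonucleotides of the 3' RACE design
#'
#' Named constants for the fixed oligos of the library architecture. The
#' reverse-transcription primer `R10_AD2` carries the 10-nt random decamer
#' (`N10`) that becomes the pseudo-UMI; `I_AD7` and `I_AD5` are the indexed
#' adapter primers (their 8-nt index stretch is marked `XXXXXXXX` and is
#' fixed per sample at simulation time); `AMP_PCR2S` is the universal
#' amplification primer.
#'
#' @format A named character vector.
#' @export
race_oligos <- c(
  R10_AD2  = "GTTCAGACGTGTGCTCTTCCGATCTNNNNNNNNNN",
  I_AD7    = "CAAGCAGAAGACGGCATACGAGATXXXXXXXXGTGACTGGAGTTCAGACGTGTGCTCTTCC",
  AMP_PCR2S = "CAAGCAGAAGACGGCATACG",
  I_AD5    = "AATGATACGGCGACCACCGAGATCTACACXXXXXXXXACACTCTTTCCCTACACGACGCTCTTCC"
)

# default per-sample index sequences used by the simulator
.default_index7 <- "TAGGCATG"
.default_index5 <- "CTCTCTAT"

#' Reverse complement of plain nucleotide strings
#'
#' Vectorised reverse complement; accepts IUPAC codes.
#'
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Read-through sequences seen when the insert is shorter than the read.
# R1 runs off the decamer end into the reverse complement of the
# R10_AD2 stem and then of the I(N)-AD7 adapter; R2 runs off the primer
# end into the reverse complement of the I(N)-AD5 3' segment.
.adapter_readthrough <- function(index7 = .default_index7,
                                 index5 = .default_index5) {
  ad2_stem <- sub("N+$", "", race_oligos[["R10_AD2"]])
  i_ad7 <- sub("XXXXXXXX", index7, race_oligos[["I_AD7"]], fixed = TRUE)
  # I-AD7 anneals to the last 20 nt of the AD2 stem, so the sense strand
  # past the decamer is revcomp(stem) followed by revcomp(I-AD7) beyond
  # that 20-nt overlap
  r1 <- paste0(revcomp(ad2_stem), substring(revcomp(i_ad7), 21))
  i_ad5 <- sub("XXXXXXXX", index5, race_oligos[["I_AD5"]], fixed = TRUE)
  r2 <- revcomp(i_ad5)
  list(r1 = r1, r2 = r2)
}
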