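#' Write alignment records as SAM
#'
#' Emits a valid SAM file (one @SQ line per panel transcript, 1-based
#' POS, soft clips for unaligned terminal stretches). Mate 2 records are
#' stored in aligned (reverse-complemented) orientation with the reverse
#' flag set. Primer and pseudo-UMI metadata travel in `pr`/`um` tags;
#' alignment score in `AS`, edit distance in `NM`.
#'
#' @param aln a `race_alignments` object (or a compatible records table).
#' @param panel a `race_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, panel, path) {
  rec <- if (inherits(aln, "race_alignments")) aln$records else
    data.table::as.data.table(aln)
  pairs <- if (inherits(aln, "race_alignments")) aln$pairs else NULL
  con <- file(path, "w")
  on.exit(close(con))
  lens <- transcript_lengths(panel$transcriptome)
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens),
               paste0("@PG\tID:raceseq\tPN:raceseq\tVN:",
                      as.character(utils::packageVersion("raceseq")))), con)
  if (nrow(rec) == 0) return(invisible(path))
  flag <- 1L + 64L * (rec$mate == 1L) + 128L * (rec$mate == 2L) +
    16L * (rec$mate == 2L)
  cig <- paste0(ifelse(rec$clip5 > 0, paste0(rec$clip5, "S"), ""),
                rec$cigar,
                ifelse(rec$clip3 > 0, paste0(rec$clip3, "S"), ""))
  tags <- sprintf("NM:i:%d\tAS:i:%g", rec$nm, rec$score)
  if (!is.null(pairs)) {
    m <- match(rec$read_id, pairs$id)
    tags <- paste0(tags, sprintf("\tpr:Z:%s\tum:Z:%s", pairs$primer[m],
                                 pairs$umi[m]))
  }
  writeLines(paste(rec$read_id, flag, rec$transcript, rec$r_start + 1L,
                   60L, cig, "*", 0L, 0L, rec$seq, rec$qual, tags,
                   sep = "\t"), con)
  invisible(path)
}

#' Read a SAM file back into alignment records
#'
#' Parses the fields the downstream stages use and enforces CIGAR /
#' sequence length consistency; malformed lines are fatal with their line
#' number.
#'
#' @param path SAM path.
#' @return list with `records` (data.table) and `pairs` metadata
#'   recovered from tags, of class `race_alignments`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  rows <- vector("list", length(body))
  prm <- character(length(body)); um <- character(length(body))
  for (j in seq_along(body)) {
    ln <- body[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop(sprintf("malformed SAM line %d: fewer than 11 fields", ln))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos))
      stop(sprintf("malformed SAM line %d: bad FLAG/POS", ln))
    cig <- f[6]
    ops <- .parse_cigar(cig)
    if (is.null(ops)) stop(sprintf("malformed SAM line %d: bad CIGAR", ln))
    qlen <- sum(ops$len[ops$op %in% c("M", "I", "S")])
    if (qlen != nchar(f[10]))
      stop(sprintf("malformed SAM line %d: CIGAR consumes %d, SEQ has %d",
                   ln, qlen, nchar(f[10])))
    clip5 <- if (ops$op[1] == "S") ops$len[1] else 0L
    clip3 <- if (ops$op[length(ops$op)] == "S") ops$len[length(ops$op)] else 0L
    core <- ops[ops$op != "S", , drop = FALSE]
    nm <- sub(".*NM:i:([0-9]+).*", "\\1", lines[ln])
    as_ <- sub(".*AS:i:([0-9.eE+-]+).*", "\\1", lines[ln])
    prm[j] <- if (grepl("pr:Z:", lines[ln]))
      sub(".*pr:Z:([^\t]+).*", "\\1", lines[ln]) else NA_character_
    um[j] <- if (grepl("um:Z:", lines[ln]))
      sub(".*um:Z:([^\t]+).*", "\\1", lines[ln]) else NA_character_
    rows[[j]] <- list(
      read_id = f[1], mate = if (bitwAnd(flag, 64L) > 0) 1L else 2L,
      transcript = f[3], r_start = pos - 1L,
      r_end = pos - 1L + sum(core$len[core$op %in% c("M", "D")]),
      q_start = clip5,
      q_end = clip5 + sum(core$len[core$op %in% c("M", "I")]),
      clip5 = clip5, clip3 = clip3,
      cigar = paste0(core$len, core$op, collapse = ""),
      nm = as.integer(nm), score = as.numeric(as_),
      seq = f[10], qual = f[11])
  }
  records <- data.table::rbindlist(rows)
  pairs <- NULL
  if (length(body) && !all(is.na(prm))) {
    pairs <- unique(data.table::data.table(
      id = records$read_id, primer = prm, umi = um,
      status = "proper"))
  }
  structure(list(records = records, pairs = pairs,
                 counts = c(input = NA)), class = "race_alignments")
}

.parse_cigar <- function(cig) {
  if (cig == "*" || !grepl("^([0-9]+[MIDS])+$", cig)) return(NULL)
  len <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  op <- regmatches(cig, gregexpr("[MIDS]", cig))[[1]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}
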