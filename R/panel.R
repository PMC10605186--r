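#' Construct a panel transcriptome
#'
#' The panel transcriptome holds the spliced mRNA sequence of every
#' transcript the panel can see, the exon structure in transcript
#' coordinates (0-based, half-open, contiguously tiling each transcript),
#' the transcript-to-gene map, and the CDS start used for protein-level
#' annotation of hotspot variants.
#'
#' @param seqs named character vector of transcript sequences.
#' @param exons data.frame with columns `transcript`, `exon`, `start`,
#'   `end` (0-based half-open transcript coordinates).
#' @param gene named character vector mapping transcript id to gene symbol.
#' @param cds_start named integer vector of CDS start offsets (0-based);
#'   transcripts absent from it default to 0.
#' @return an object of class `race_transcriptome`.
#' @export
race_transcriptome <- function(seqs, exons, gene, cds_start = integer(0)) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  exons <- as.data.frame(exons)
  need <- c("transcript", "exon", "start", "end")
  if (!all(need %in% names(exons)))
    stop("exon table must have columns transcript, exon, start, end")
  cds <- setNames(integer(length(seqs)), names(seqs))
  cds[names(cds_start)] <- as.integer(cds_start)
  obj <- structure(list(seqs = seqs, exons = exons, gene = gene,
                        cds_start = cds),
                   class = "race_transcriptome")
  .validate_transcriptome(obj)
  obj
}

.validate_transcriptome <- function(tx) {
  for (id in names(tx$seqs)) {
    ex <- tx$exons[tx$exons$transcript == id, , drop = FALSE]
    if (nrow(ex) == 0) stop(sprintf("transcript '%s' has no exon records", id))
    ex <- ex[order(ex$start), , drop = FALSE]
    L <- nchar(tx$seqs[[id]])
    if (ex$start[1] != 0 || ex$end[nrow(ex)] != L ||
        (nrow(ex) > 1 && any(ex$start[-1] != ex$end[-nrow(ex)])))
      stop(sprintf(
        "exons of transcript '%s' must contiguously tile [0, %d)", id, L))
    if (any(diff(ex$exon) != 1))
      stop(sprintf("exon numbers of '%s' must be consecutive", id))
  }
  miss <- setdiff(names(tx$seqs), names(tx$gene))
  if (length(miss))
    stop("transcripts without gene symbol: ", paste(miss, collapse = ", "))
  invisible(tx)
}

#' Length of each transcript
#' @param tx a `race_transcriptome`.
#' @return named integer vector.
#' @export
transcript_lengths <- function(tx) {
  vapply(tx$seqs, nchar, integer(1))
}

#' Assemble and validate a panel design
#'
#' Binds the transcriptome to the enrichment primers, target fragments
#' (expression targets, referee fragments, hotspot regions, fusion
#' anchors), the hotspot set, and the fusion anchor boundaries, and checks
#' every structural invariant of the design. All validation failures are
#' fatal and name the offending record.
#'
#' @param transcriptome a `race_transcriptome`.
#' @param primers data.frame with columns `name`, `gene`, `transcript`,
#'   `start` (0-based coordinate of the primer 5' end), `sequence`, and
#'   optionally `category`.
#' @param fragments data.frame with columns `label`, `gene`, `transcript`,
#'   `start`, `end`, `role`; role is one of `expression-target`,
#'   `referee`, `hotspot-region`, `fusion-anchor`.
#' @param hotspots data.frame with columns `type` (`codon` or `region`),
#'   `gene`, `transcript`, `codon` (codon rows), `start`, `end` (region
#'   rows) and `label`.
#' @param anchors data.frame with columns `gene`, `transcript`, `exon`,
#'   `boundary` (transcript coordinate of the breakpoint boundary).
#' @param name,version panel identification strings.
#' @return an object of class `race_panel`.
#' @export
race_panel <- function(transcriptome, primers, fragments, hotspots, anchors,
                       name = "panel", version = "0") {
  primers <- as.data.frame(primers)
  fragments <- as.data.frame(fragments)
  hotspots <- as.data.frame(hotspots)
  anchors <- as.data.frame(anchors)
  if (is.null(primers$category)) primers$category <- primers$gene
  primers$length <- nchar(primers$sequence)
  primers$end <- primers$start + primers$length
  # resolve codon hotspot coordinates from the CDS start
  if (nrow(hotspots)) {
    if (is.null(hotspots$start)) hotspots$start <- NA_integer_
    if (is.null(hotspots$end)) hotspots$end <- NA_integer_
    cod <- hotspots$type == "codon"
    cs <- transcriptome$cds_start[hotspots$transcript[cod]]
    hotspots$start[cod] <- cs + 3L * (hotspots$codon[cod] - 1L)
    hotspots$end[cod] <- hotspots$start[cod] + 3L
  }
  panel <- structure(list(transcriptome = transcriptome, primers = primers,
                          fragments = fragments, hotspots = hotspots,
                          anchors = anchors, name = name, version = version,
                          .cache = new.env(parent = emptyenv())),
                     class = "race_panel")
  validate_panel(panel)
  panel
}

#' Validate every invariant of a panel design
#'
#' @param panel a `race_panel`.
#' @return the panel, invisibly; fatal error on the first violation.
#' @export
validate_panel <- function(panel) {
  tx <- panel$transcriptome
  lens <- transcript_lengths(tx)
  refd <- unique(c(panel$primers$transcript, panel$fragments$transcript,
                   panel$hotspots$transcript, panel$anchors$transcript))
  miss <- setdiff(refd, names(tx$seqs))
  if (length(miss))
    stop("missing transcript(s) in transcriptome: ",
         paste(miss, collapse = ", "))
  p <- panel$primers
  bad_len <- p$length < 18 | p$length > 35
  if (any(bad_len))
    stop("primer length outside 18-35 nt: ",
         paste(p$name[bad_len], collapse = ", "))
  if (anyDuplicated(p$sequence))
    stop("duplicated primer sequence (ambiguous assignment): ",
         paste(p$name[duplicated(p$sequence)], collapse = ", "))
  for (i in seq_len(nrow(p))) {
    obs <- substr(tx$seqs[[p$transcript[i]]], p$start[i] + 1, p$end[i])
    if (!identical(obs, p$sequence[i]) && !grepl("[^ACGT]", p$sequence[i]))
      stop(sprintf(
        "primer '%s' does not match the transcriptome at %s:%d (expected '%s', observed '%s')",
        p$name[i], p$transcript[i], p$start[i], obs, p$sequence[i]))
  }
  f <- panel$fragments
  if (any(f$start < 0 | f$end > lens[f$transcript] | f$start >= f$end))
    stop("fragment interval outside transcript bounds: ",
         paste(f$label[f$start < 0 | f$end > lens[f$transcript] |
                         f$start >= f$end], collapse = ", "))
  ref_genes <- c("DDX23", "GOLGA5", "SEL1L")
  have <- f$gene[f$role == "referee"]
  if (!setequal(have, ref_genes) || length(have) != 3) {
    missing_ref <- setdiff(ref_genes, have)
    stop("panel must contain exactly the three referee fragments; missing: ",
         if (length(missing_ref)) paste(missing_ref, collapse = ", ")
         else paste("duplicated", paste(have[duplicated(have)], collapse = ", ")))
  }
  et <- f[f$role == "expression-target", , drop = FALSE]
  dup <- unique(et$gene[duplicated(et$gene)])
  if (length(dup))
    stop("more than one expression fragment for gene(s): ",
         paste(dup, collapse = ", "))
  frag_genes <- unique(f$gene)
  orphan <- setdiff(unique(p$gene), frag_genes)
  if (length(orphan))
    stop("primer gene(s) with no fragment: ", paste(orphan, collapse = ", "))
  h <- panel$hotspots
  if (nrow(h)) {
    if (any(h$start < 0 | h$end > lens[h$transcript]))
      stop("hotspot coordinates not resolvable on the transcriptome: ",
           paste(h$label[h$start < 0 | h$end > lens[h$transcript]],
                 collapse = ", "))
    if (anyDuplicated(h$label))
      stop("duplicated hotspot labels: ",
           paste(unique(h$label[duplicated(h$label)]), collapse = ", "))
  }
  a <- panel$anchors
  fg2 <- a[a$gene == "FGFR2" & a$exon == 17, , drop = FALSE]
  if (nrow(fg2)) {
    ex <- tx$exons
    e17 <- ex[ex$transcript == fg2$transcript[1] & ex$exon == 17, , drop = FALSE]
    if (nrow(e17) == 0 || any(fg2$boundary != e17$end[1]))
      stop("FGFR2 anchor boundary must equal the 3' end of exon 17")
  }
  invisible(panel)
}

#' @export
print.race_panel <- function(x, ...) {
  cat(sprintf("<race_panel '%s' v%s>\n", x$name, x$version))
  cat(sprintf("  transcripts: %d (%s kb)\n", length(x$transcriptome$seqs),
              round(sum(transcript_lengths(x$transcriptome)) / 1000, 1)))
  cat(sprintf("  primers: %d  fragments: %d  hotspots: %d  anchors: %d\n",
              nrow(x$primers), nrow(x$fragments), nrow(x$hotspots),
              nrow(x$anchors)))
  invisible(x)
}

#' Load a panel definition from disk
#'
#' Reads a panel directory (or a `panel.yaml` file) containing the
#' transcriptome FASTA, the exon table, and the primer / fragment /
#' hotspot / anchor tables, then validates the assembled design.
#' Expected files: `panel.yaml`, `transcripts.fa`, `transcripts.tsv`
#' (transcript, gene, cds_start), `exons.tsv`, `primers.tsv`,
#' `fragments.tsv`, `hotspots.tsv`, `anchors.tsv`.
#'
#' @param config path to a panel directory or to its `panel.yaml`.
#' @param fasta,exon_table optional overriding paths for the transcriptome
#'   FASTA and the exon table.
#' @return a validated `race_panel`.
#' @export
load_panel <- function(config, fasta = NULL, exon_table = NULL) {
  if (dir.exists(config)) config <- file.path(config, "panel.yaml")
  if (!file.exists(config)) stop("panel config not found: ", config)
  dir <- dirname(config)
  meta <- yaml::read_yaml(config)
  pth <- function(nm, default) {
    f <- if (!is.null(meta$files[[nm]])) meta$files[[nm]] else default
    if (!grepl("^/", f)) f <- file.path(dir, f)
    f
  }
  fasta <- if (is.null(fasta)) pth("fasta", "transcripts.fa") else fasta
  exon_table <- if (is.null(exon_table)) pth("exons", "exons.tsv") else exon_table
  for (f in c(fasta, exon_table))
    if (!file.exists(f)) stop("panel file not found: ", f)
  dss <- Biostrings::readDNAStringSet(fasta)
  seqs <- setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
  rd <- function(f) read.table(f, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, quote = "")
  txmeta <- rd(pth("transcripts", "transcripts.tsv"))
  exons <- rd(exon_table)
  tx <- race_transcriptome(
    seqs, exons,
    gene = setNames(txmeta$gene, txmeta$transcript),
    cds_start = setNames(txmeta$cds_start, txmeta$transcript))
  race_panel(tx,
             primers = rd(pth("primers", "primers.tsv")),
             fragments = rd(pth("fragments", "fragments.tsv")),
             hotspots = rd(pth("hotspots", "hotspots.tsv")),
             anchors = rd(pth("anchors", "anchors.tsv")),
             name = if (is.null(meta$name)) "panel" else meta$name,
             version = if (is.null(meta$version)) "0" else meta$version)
}

#' Serialize a panel design to a directory
#'
#' Writes the file set understood by [load_panel()]; loading the result
#' reproduces the panel exactly.
#'
#' @param panel a `race_panel`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- panel$transcriptome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx$seqs),
                              file.path(dir, "transcripts.fa"), width = 80)
  wr <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wr(data.frame(transcript = names(tx$seqs),
                gene = unname(tx$gene[names(tx$seqs)]),
                cds_start = unname(tx$cds_start[names(tx$seqs)])),
     "transcripts.tsv")
  wr(tx$exons, "exons.tsv")
  wr(panel$primers[c("name", "gene", "transcript", "start", "sequence",
                     "category")], "primers.tsv")
  wr(panel$fragments, "fragments.tsv")
  hs <- panel$hotspots
  wr(hs[setdiff(names(hs), character(0))], "hotspots.tsv")
  wr(panel$anchors, "anchors.tsv")
  yaml::write_yaml(list(name = panel$name, version = panel$version),
                   file.path(dir, "panel.yaml"))
  invisible(dir)
}

#' Retrieve the measurement fragment of a gene
#'
#' Returns the unique expression-target or referee fragment of a gene;
#' these are the fragments whose template counts enter the qPCR-like
#' expression values.
#'
#' @param gene gene symbol.
#' @param panel a `race_panel`.
#' @return one-row data.frame describing the fragment.
#' @export
fragment_for <- function(gene, panel) {
  f <- panel$fragments
  hit <- f[f$gene == gene & f$role %in% c("expression-target", "referee"), ,
           drop = FALSE]
  if (nrow(hit) == 0)
    stop(sprintf("gene '%s' has no expression or referee fragment in the panel",
                 gene))
  if (nrow(hit) > 1)
    stop(sprintf("gene '%s' has %d measurement fragments (ambiguous)",
                 gene, nrow(hit)))
  hit
}

#' Primer counts per panel category
#'
#' @param panel a `race_panel`.
#' @return named integer vector of primer counts by category, in panel
#'   definition order.
#' @export
panel_primer_census <- function(panel) {
  cats <- unique(panel$primers$category)
  setNames(vapply(cats, function(cc) sum(panel$primers$category == cc),
                  integer(1)), cats)
}

# union of genomic intervals relevant to on-target filtering:
# all fragments plus hotspot regions; returns data.table keyed by transcript
.panel_target_intervals <- function(panel) {
  f <- panel$fragments[c("transcript", "start", "end")]
  h <- panel$hotspots
  if (nrow(h)) f <- rbind(f, h[c("transcript", "start", "end")])
  data.table::as.data.table(f)
}

# per-transcript logical mask of target positions (fragments + hotspot
# regions) and its cumulative sum, cached inside the panel
.target_mask <- function(panel) {
  hit <- panel$.cache[["target_mask"]]
  if (!is.null(hit)) return(hit)
  lens <- transcript_lengths(panel$transcriptome)
  iv <- .panel_target_intervals(panel)
  masks <- lapply(names(lens), function(txid) {
    m <- logical(lens[[txid]])
    sub <- iv[iv$transcript == txid]
    for (i in seq_len(nrow(sub)))
      m[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    m
  })
  names(masks) <- names(lens)
  res <- list(mask = masks,
              cum = lapply(masks, function(m) c(0L, cumsum(m))))
  panel$.cache[["target_mask"]] <- res
  res
}

# k-mer index of the transcriptome, cached inside the panel
.kmer_index <- function(panel, k = 15L) {
  key <- paste0("idx", k)
  if (!is.null(panel$.cache[[key]])) return(panel$.cache[[key]])
  env <- new.env(parent = emptyenv(), size = 65536L)
  seqs <- panel$transcriptome$seqs
  for (ti in seq_along(seqs)) {
    s <- seqs[[ti]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    sp <- split(starts - 1L, kms)  # 0-based positions
    for (km in names(sp)) {
      env[[km]] <- rbind(env[[km]],
                         cbind(rep.int(ti, length(sp[[km]])), sp[[km]]))
    }
  }
  res <- list(env = env, k = k, tx = names(seqs))
  panel$.cache[[key]] <- res
  res
}
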