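#' Describe the ground truth of a simulated sample
#'
#' A truth model fixes everything the simulator needs: relative transcript
#' abundances, spiked-in variants and fusions, the number of unique cDNA
#' templates, the PCR duplication and sequencing error parameters, the
#' insert length distribution, the per-base probability that the annealed
#' RT decamer mismatches the template (the source of the pseudo-UMI
#' signal), and the seed.
#'
#' Each enrichment primer samples the mRNA pool independently, so template
#' counts are allocated across primers proportionally to the abundance of
#' the primer's gene (a transcript molecule can serve several nested
#' primers, which is what makes per-fragment counts comparable across
#' genes with different primer numbers).
#'
#' @param expression_weights named numeric vector of relative transcript
#'   abundance per gene; genes absent from the vector get weight 0.
#' @param variants optional list of lists with fields `transcript`, `pos`
#'   (0-based), `ref`, `alt`, `af` (allele fraction).
#' @param fusions optional list of lists with fields `anchor_gene`,
#'   `anchor_exon`, `fraction`, and either `partner_transcript` +
#'   `partner_breakpoint` (0-based) or a literal `partner_sequence`.
#' @param n_templates number of unique templates to emit.
#' @param dup_geometric_p geometric parameter; each template is sequenced
#'   `1 + rgeom(p)` times.
#' @param seq_error_rate per-base sequencing error probability.
#' @param rt_mismatch_rate per-base probability that a decamer base
#'   mismatches the template. The default 0.3 reflects the permissive
#'   low-temperature annealing step of the RT reaction and gives the
#'   decamer enough diversity to discriminate templates that share
#'   coordinates.
#' @param insert_mean,insert_sd,insert_min truncated-normal insert length
#'   (primer 5' end to decamer end), in nt.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return an object of class `race_truth_model`.
#' @export
truth_model <- function(expression_weights, variants = list(),
                        fusions = list(), n_templates = 10000L,
                        dup_geometric_p = 0.5, seq_error_rate = 0.001,
                        rt_mismatch_rate = 0.3, insert_mean = 120,
                        insert_sd = 30, insert_min = 50, seed = 1L) {
  stopifnot(is.numeric(expression_weights), !is.null(names(expression_weights)),
            all(expression_weights >= 0), any(expression_weights > 0),
            n_templates >= 1)
  for (v in variants)
    if (v$af < 0 || v$af > 1) stop("variant allele fraction outside [0,1]")
  for (f in fusions)
    if (f$fraction < 0 || f$fraction > 1)
      stop("fusion fraction outside [0,1]")
  structure(list(expression_weights = expression_weights,
                 variants = variants, fusions = fusions,
                 n_templates = as.integer(n_templates),
                 dup_geometric_p = dup_geometric_p,
                 seq_error_rate = seq_error_rate,
                 rt_mismatch_rate = rt_mismatch_rate,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 insert_min = insert_min, seed = as.integer(seed)),
            class = "race_truth_model")
}

.trunc_norm <- function(n, mean, sd, minv) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < minv)
  while (length(bad)) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < minv]
  }
  out
}

.mutate_bases <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate a 3' RACE library as paired FASTQ plus a truth ledger
#'
#' For each unique template a source transcript copy is drawn by
#' expression weight (with spiked variants/fusions applied), an enrichment
#' primer compatible with that transcript is chosen, an RT priming site is
#' drawn downstream from the insert-length distribution, and the 10-nt
#' decamer written into the molecule is the template 10-mer mutated at
#' `rt_mismatch_rate` (the written bases replace the template bases, which
#' is what creates the pseudo-UMI signal). The molecule is then replicated
#' `1 + Geometric(p)` times and each replicate sequenced 2 x 150 with the
#' given error rate: R1 starts at the enrichment primer 5' end reading
#' sense, R2 starts at the decamer reading antisense, and both reads run
#' into the library adapters when the insert is shorter than 150 nt.
#'
#' @param panel a `race_panel`.
#' @param truth a `race_truth_model`.
#' @param out_dir optional directory; when given, gzipped FASTQ files and
#'   the truth TSV are written there.
#' @return list of class `race_sim` with `reads` (data.table: id, r1, q1,
#'   r2, q2), `ledger` (one row per unique template) and, when `out_dir`
#'   is used, the file paths.
#' @export
simulate_sample <- function(panel, truth, out_dir = NULL) {
  stopifnot(inherits(panel, "race_panel"), inherits(truth, "race_truth_model"))
  set.seed(truth$seed)
  tx <- panel$transcriptome
  prm <- panel$primers
  w <- truth$expression_weights[prm$gene]
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("no panel primer has positive expression weight")
  n <- truth$n_templates

  # resolve fusions against the panel
  fus <- lapply(truth$fusions, function(f) {
    a <- panel$anchors[panel$anchors$gene == f$anchor_gene &
                         panel$anchors$exon == f$anchor_exon, , drop = FALSE]
    if (nrow(a) == 0)
      stop(sprintf("no fusion anchor for %s exon %d", f$anchor_gene,
                   f$anchor_exon))
    if (!is.null(f$partner_sequence)) {
      part <- toupper(f$partner_sequence)
      pname <- if (is.null(f$partner_name)) "UNKNOWN" else f$partner_name
    } else {
      part <- substr(tx$seqs[[f$partner_transcript]],
                     f$partner_breakpoint + 1L,
                     nchar(tx$seqs[[f$partner_transcript]]))
      pname <- tx$gene[[f$partner_transcript]]
    }
    if (nchar(part) < 25)
      stop("fusion partner sequence shorter than 25 nt is undetectable by design")
    f$anchor_transcript <- a$transcript[1]
    f$boundary <- a$boundary[1]
    f$partner_tail <- part
    f$id <- sprintf("%s-%s", f$anchor_gene, pname)
    f
  })
  fus_by_tx <- split(fus, vapply(fus, function(f) f$anchor_transcript,
                                 character(1)))
  var_by_tx <- split(truth$variants,
                     vapply(truth$variants, function(v) v$transcript,
                            character(1)))

  p_idx <- sample.int(nrow(prm), n, replace = TRUE, prob = w)
  base_tx <- prm$transcript[p_idx]

  # per-template event draws
  fus_flag <- character(n)
  for (txid in names(fus_by_tx)) {
    on <- which(base_tx == txid)
    for (f in fus_by_tx[[txid]]) {
      take <- on[runif(length(on)) < f$fraction & fus_flag[on] == ""]
      fus_flag[take] <- f$id
    }
  }
  var_flag <- vector("list", n)
  var_str <- character(n)
  for (txid in names(var_by_tx)) {
    on <- which(base_tx == txid)
    vs <- var_by_tx[[txid]]
    for (vi in seq_along(vs)) {
      v <- vs[[vi]]
      take <- on[runif(length(on)) < v$af]
      for (t in take) var_flag[[t]] <- c(var_flag[[t]], vi)
      var_str[take] <- vapply(var_flag[take], function(ii)
        paste(vapply(vs[ii], function(v2)
          sprintf("%s:%d:%s>%s", v2$transcript, v2$pos, v2$ref, v2$alt),
          character(1)), collapse = ";"), character(1))
    }
  }

  # allele sequence cache keyed by (transcript, variant set, fusion id)
  allele_cache <- new.env(parent = emptyenv())
  allele_seq <- function(txid, vidx, fid) {
    key <- paste(txid, paste(vidx, collapse = ","), fid, sep = "|")
    hit <- allele_cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- tx$seqs[[txid]]
    vs <- var_by_tx[[txid]]
    if (length(vidx)) {
      ord <- vidx[order(vapply(vs[vidx], function(v) v$pos, numeric(1)),
                        decreasing = TRUE)]
      for (vi in ord) {
        v <- vs[[vi]]
        obs <- substr(s, v$pos + 1L, v$pos + nchar(v$ref))
        if (obs != v$ref)
          stop(sprintf("truth variant ref mismatch at %s:%d (panel has '%s')",
                       v$transcript, v$pos, obs))
        s <- paste0(substr(s, 1, v$pos), v$alt,
                    substr(s, v$pos + 1L + nchar(v$ref), nchar(s)))
      }
    }
    if (fid != "") {
      f <- Find(function(ff) ff$id == fid, fus_by_tx[[txid]])
      s <- paste0(substr(s, 1, f$boundary), f$partner_tail)
    }
    allele_cache[[key]] <- s
    s
  }

  L <- .trunc_norm(n, truth$insert_mean, truth$insert_sd, truth$insert_min)
  p5 <- prm$start[p_idx]
  plen <- prm$length[p_idx]

  insert <- character(n)
  rt_coord <- integer(n)
  umi_obs <- character(n)
  mism <- character(n)
  for (i in seq_len(n)) {
    s <- allele_seq(base_tx[i], var_flag[[i]], fus_flag[i])
    e <- min(p5[i] + L[i], nchar(s))
    e <- max(e, p5[i] + plen[i] + 12L)
    t0 <- e - 10L
    dec <- substr(s, t0 + 1L, e)
    nmm <- rbinom(1, 10, truth$rt_mismatch_rate)
    if (nmm > 0) {
      at <- sample.int(10, nmm)
      w10 <- .mutate_bases(dec, at)
      mism[i] <- paste(sort(10L - at), collapse = ",")  # R2 orientation, 0-based
    } else {
      w10 <- dec
      mism[i] <- ""
    }
    insert[i] <- paste0(substr(s, p5[i] + 1L, t0), w10)
    rt_coord[i] <- t0
    umi_obs[i] <- w10
  }
  umi_obs <- revcomp(umi_obs)  # as read: R2 prefix orientation

  dup <- 1L + rgeom(n, truth$dup_geometric_p)
  ledger <- data.table::data.table(
    template_id = sprintf("T%06d", seq_len(n)),
    primer = prm$name[p_idx], transcript = base_tx,
    rt_coordinate = rt_coord, umi_obs = umi_obs,
    umi_mismatch_positions = mism, duplicate_count = dup,
    variants = var_str, fusion = fus_flag)

  ad <- .adapter_readthrough()
  gpad <- strrep("G", 160)
  r1_t <- substr(paste0(insert, ad$r1, gpad), 1, 150)
  r2_t <- substr(paste0(revcomp(insert), ad$r2, gpad), 1, 150)

  ridx <- rep.int(seq_len(n), dup)
  dnum <- sequence(dup)
  ids <- sprintf("%s:D%02d", ledger$template_id[ridx], dnum)
  r1 <- r1_t[ridx]
  r2 <- r2_t[ridx]
  if (truth$seq_error_rate > 0) {
    for (nm in c("r1", "r2")) {
      v <- get(nm)
      k <- rbinom(length(v), 150L, truth$seq_error_rate)
      for (i in which(k > 0))
        v[i] <- .mutate_bases(v[i], sample.int(150, k[i]))
      assign(nm, v)
    }
  }
  ord <- sample.int(length(ids))
  qual <- strrep("?", 150)  # constant Q30 baseline
  reads <- data.table::data.table(id = ids[ord], r1 = r1[ord], q1 = qual,
                                  r2 = r2[ord], q2 = qual)
  out <- structure(list(reads = reads, ledger = ledger, truth = truth),
                   class = "race_sim")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "sample_R1.fastq.gz")
    f2 <- file.path(out_dir, "sample_R2.fastq.gz")
    write_fastq(reads$id, reads$r1, reads$q1, f1)
    write_fastq(reads$id, reads$r2, reads$q2, f2)
    ft <- file.path(out_dir, "truth.tsv")
    write_truth(ledger, ft)
    out$files <- list(fastq_r1 = f1, fastq_r2 = f2, truth = ft)
  }
  out
}

#' @export
print.race_sim <- function(x, ...) {
  cat(sprintf("<race_sim: %d templates, %d read pairs, seed %d>\n",
              nrow(x$ledger), nrow(x$reads), x$truth$seed))
  invisible(x)
}

#' Write / read a truth ledger TSV
#'
#' @param ledger ledger data.table from [simulate_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(ledger, path) {
  cols <- c("template_id", "primer", "transcript", "rt_coordinate",
            "umi_obs", "umi_mismatch_positions", "duplicate_count",
            "variants", "fusion")
  write.table(as.data.frame(ledger)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  data.table::as.data.table(
    read.table(path, header = TRUE, sep = "\t", quote = "",
               colClasses = c(umi_mismatch_positions = "character",
                              variants = "character", fusion = "character"),
               stringsAsFactors = FALSE))
}

#' Write a FASTQ file (optionally gzipped)
#'
#' @param ids,seqs,quals parallel character vectors.
#' @param path output path; `.gz` suffix triggers gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into id / sequence / quality vectors
#'
#' @param path FASTQ path (gzipped or plain).
#' @return list with `id`, `seq`, `qual` character vectors.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  list(id = sub("\\s.*$", "", names(dss)),
       seq = unname(as.character(dss)),
       qual = unname(as.character(S4Vectors::mcols(dss)$qualities)))
}
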