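#' Exact Fisher test for an r x c contingency table
#'
#' Two-sided exact test by complete enumeration of the margin-constrained
#' lattice: the p-value is the total hypergeometric probability of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table (within a relative tolerance of 1e-7 for
#' floating-point ties). This is the probability-mass definition used by
#' mainstream statistical environments.
#'
#' @param counts non-negative integer matrix (r x c).
#' @return p-value in [0, 1]; a table with a zero margin is degenerate
#'   and returns 1 with a warning.
#' @export
fisher_exact_rxc <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative cell in contingency table")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate table (zero margin); p = 1")
    return(1)
  }
  N <- sum(counts)
  lgN <- lgamma(N + 1)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgN
  logp_obs <- const - sum(lgamma(counts + 1))
  r <- length(rs); cc <- length(cs)
  total <- 0
  # recursive enumeration over rows; each row is a composition of rs[i]
  # into cc parts bounded by the remaining column sums
  row_compositions <- function(target, bounds) {
    if (length(bounds) == 1) {
      if (target <= bounds) return(list(target)) else return(list())
    }
    out <- list()
    for (x in 0:min(target, bounds[1])) {
      for (rest in row_compositions(target - x, bounds[-1]))
        out[[length(out) + 1L]] <- c(x, rest)
    }
    out
  }
  recurse <- function(i, colrem, acc_lfact) {
    if (i == r) {
      # last row forced
      if (any(colrem < 0)) return()
      lp <- const - acc_lfact - sum(lgamma(colrem + 1))
      if (lp <= logp_obs + 1e-7)
        total <<- total + exp(lp)
      return()
    }
    for (comp in row_compositions(rs[i], colrem)) {
      recurse(i + 1, colrem - comp, acc_lfact + sum(lgamma(comp + 1)))
    }
  }
  recurse(1, cs, 0)
  min(1, total)
}

#' Pearson chi-squared test for an r x c table
#'
#' No continuity correction; df = (r-1)(c-1).
#'
#' @param counts contingency matrix.
#' @return p-value.
#' @export
chi_squared_rxc <- function(counts) {
  counts <- as.matrix(counts)
  expd <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expd == 0))
    stop("zero expected cell; use the exact test (fisher_exact_rxc)")
  suppressWarnings(chisq.test(counts, correct = FALSE))$p.value
}

#' Kruskal-Wallis test over k groups
#'
#' Tie-corrected H statistic with the chi-squared approximation
#' (df = k - 1), as implemented in the standard test; all-identical data
#' return p = 1.
#'
#' @param groups list of (at least two) numeric vectors.
#' @return p-value.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
  if (length(unique(unlist(groups))) == 1) return(1)
  kruskal.test(groups)$p.value
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration for small samples without ties (n_x + n_y <= 12),
#' otherwise the tie-corrected normal approximation; identical samples
#' return p = 1.
#'
#' @param x,y numeric vectors.
#' @return p-value.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(x) + length(y) <= 12 && !ties)
    return(wilcox.test(x, y, exact = TRUE)$p.value)
  if (identical(sort(x), sort(y)) ||
      length(unique(c(x, y))) == 1) return(1)
  p <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  if (is.nan(p)) 1 else p
}

#' Build per-marker contingency tables from a cohort matrix
#'
#' For each marker column the per-group present/absent counts are
#' tabulated (samples with status `nd` are excluded listwise from that
#' marker's denominators), percentages are reported to one decimal, and
#' the exact Fisher p-value is attached.
#'
#' @param cohort data.frame with a `group` column and per-marker status
#'   columns taking values `present` / `absent` / `nd`.
#' @param markers marker column names (default: all non-`group`,
#'   non-`sample` character columns).
#' @return named list of marker tables (`counts` matrix, `nd`,
#'   `percent_present`, `p_value`).
#' @export
build_marker_tables <- function(cohort, markers = NULL) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!"group" %in% names(cohort)) stop("cohort needs a 'group' column")
  groups <- unique(cohort$group)
  if (length(groups) < 2) stop("cohort must contain at least two groups")
  if (is.null(markers))
    markers <- setdiff(names(cohort)[vapply(cohort, is.character,
                                            logical(1))],
                       c("group", "sample"))
  out <- list()
  for (m in markers) {
    st <- cohort[[m]]
    counts <- t(vapply(groups, function(g) {
      c(present = sum(st == "present" & cohort$group == g),
        absent = sum(st == "absent" & cohort$group == g))
    }, integer(2)))
    nd <- vapply(groups, function(g)
      sum(st == "nd" & cohort$group == g), integer(1))
    if (all(counts[, "present"] == 0)) {
      warning(sprintf("marker '%s' absent in all samples; p = 1", m))
      p <- 1
    } else {
      p <- fisher_exact_rxc(counts)
    }
    denom <- rowSums(counts)
    out[[m]] <- list(marker = m, groups = groups, counts = counts,
                     nd = nd,
                     percent_present = round(100 * counts[, "present"] /
                                               pmax(denom, 1), 1),
                     p_value = p)
  }
  out
}

#' Simulate a cohort marker matrix
#'
#' Independent Bernoulli marker statuses per group at the given
#' prevalences; deterministic for a fixed seed.
#'
#' @param prevalences named list: per group, a named numeric vector of
#'   marker prevalences in [0, 1].
#' @param n named integer vector of per-group sample counts.
#' @param seed integer seed.
#' @return data.frame cohort matrix usable by [build_marker_tables()].
#' @export
synth_cohort <- function(prevalences, n, seed = 1L) {
  stopifnot(all(names(prevalences) %in% names(n)))
  set.seed(seed)
  rows <- list()
  for (g in names(prevalences)) {
    pv <- prevalences[[g]]
    stopifnot(all(pv >= 0 & pv <= 1))
    for (i in seq_len(n[[g]])) {
      st <- ifelse(runif(length(pv)) < pv, "present", "absent")
      rows[[length(rows) + 1L]] <- c(list(sample = sprintf("%s_%03d", g, i),
                                          group = g), as.list(st))
    }
  }
  df <- data.table::rbindlist(rows)
  as.data.frame(df)
}
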