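test_that("exact Fisher p-values match hand-enumerated results", {
  # symmetric table
  expect_equal(fisher_exact_rxc(matrix(c(2, 2, 2, 2), 2, 2)), 1.0)
  # diagonal 2x2: only the two extreme tables are as unlikely; 2/C(10,5)
  expect_equal(fisher_exact_rxc(matrix(c(5, 0, 0, 5), 2, 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-10)
  expect_warning(p0 <- fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2, 2,
                                               byrow = TRUE)),
                 "degenerate")
  expect_equal(p0, 1)
})

test_that("exact Fisher agrees with the reference implementation on fuzzed tables", {
  set.seed(2024)
  for (i in 1:120) {
    r <- sample(2:3, 1)
    repeat {
      m <- matrix(rpois(r * 2, sample(2:7, 1)), r, 2)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0) && sum(m) <= 40) break
    }
    expect_equal(fisher_exact_rxc(m), fisher.test(m)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("Fisher p is invariant to group (row) order", {
  ct <- btc_cohort_counts()$markers
  for (m in c("KRAS", "FGFR2", "PIK3CA")) {
    p1 <- fisher_exact_rxc(ct[[m]])
    p2 <- fisher_exact_rxc(ct[[m]][c(3, 1, 2), ])
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("chi-squared test matches printed and derived values", {
  g <- btc_cohort_counts()$gender
  expect_equal(round(chi_squared_rxc(g), 3), 0.366)
  expect_equal(chi_squared_rxc(matrix(c(10, 10, 20, 20), 2, 2,
                                      byrow = TRUE)), 1, tolerance = 1e-12)
  expect_lt(chi_squared_rxc(matrix(c(10, 0, 0, 10), 2, 2, byrow = TRUE)),
            1e-4)
  expect_error(chi_squared_rxc(matrix(c(0, 0, 5, 5), 2, 2)), "exact")
})

test_that("Kruskal-Wallis handles ties, identical data, and matches a permutation oracle", {
  expect_equal(kruskal_wallis(list(c(1, 1, 1), c(1, 1), c(1, 1, 1))), 1)
  # no ties: H = 7.2 on 1..9 split in ordered thirds
  p <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(p, 1 - pchisq(7.2, df = 2), tolerance = 1e-12)
  # permutation oracle on small random data
  set.seed(99)
  x <- list(rnorm(5), rnorm(5, 0.5), rnorm(5, 1))
  p_asym <- kruskal_wallis(x)
  pooled <- unlist(x)
  H_obs <- kruskal.test(x)$statistic
  perm <- replicate(4000, {
    sh <- sample(pooled)
    kruskal.test(list(sh[1:5], sh[6:10], sh[11:15]))$statistic
  })
  p_perm <- mean(perm >= H_obs - 1e-12)
  expect_lt(abs(p_asym - p_perm), 0.01)
})

test_that("Mann-Whitney U uses exact enumeration for small untied samples", {
  expect_equal(mann_whitney_u(c(5, 6, 7), c(5, 6, 7)), 1)
  # complete separation of 3 vs 3: p = 2 / C(6,3) = 0.1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # exact and normal approximation agree at the exactness boundary
  set.seed(7)
  x <- rnorm(6); y <- rnorm(6, 0.8)
  p_exact <- mann_whitney_u(x, y)
  p_approx <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  expect_lt(abs(p_exact - p_approx), 0.02)
})

test_that("marker tables rebuild printed counts from a cohort matrix", {
  # a synthetic cohort with known statuses reproduces its own counts
  cohort <- synth_cohort(
    list(iCCA = c(KRAS = 0.3, FGFR2 = 0.2),
         eCCA = c(KRAS = 0.5, FGFR2 = 0.02),
         GBA = c(KRAS = 0.1, FGFR2 = 0)),
    n = c(iCCA = 60, eCCA = 40, GBA = 30), seed = 3L)
  tabs <- build_marker_tables(cohort)
  expect_equal(sum(tabs$KRAS$counts), 130)
  expect_equal(unname(rowSums(tabs$KRAS$counts)), c(60, 40, 30))
  expect_equal(tabs$KRAS$counts["iCCA", "present"],
               sum(cohort$KRAS == "present" & cohort$group == "iCCA"))
  # nd samples drop out of the denominators
  cohort$KRAS[1:5] <- "nd"
  tabs2 <- build_marker_tables(cohort, markers = "KRAS")
  expect_equal(sum(tabs2$KRAS$counts) + 5L, 130L)
  expect_equal(unname(tabs2$KRAS$nd[1]), 5L)
  expect_error(build_marker_tables(cohort[0, ]), "empty")
  cohort$NEVER <- "absent"
  expect_warning(t3 <- build_marker_tables(cohort, markers = "NEVER"),
                 "absent in all")
  expect_equal(t3$NEVER$p_value, 1)
})

test_that("synthetic cohorts hit their prevalences", {
  c0 <- synth_cohort(list(g1 = c(m = 0), g2 = c(m = 1)),
                     n = c(g1 = 50, g2 = 50), seed = 8L)
  expect_true(all(c0$m[c0$group == "g1"] == "absent"))
  expect_true(all(c0$m[c0$group == "g2"] == "present"))
  cbig <- synth_cohort(list(g = c(m = 0.2)), n = c(g = 10000), seed = 9L)
  prev <- mean(cbig$m == "present")
  expect_lt(abs(prev - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
})

test_that("the exact test keeps type-I error at or below nominal level", {
  set.seed(512)
  reject <- 0L
  n_sim <- 800L
  for (i in seq_len(n_sim)) {
    # null cohort: same prevalence in all three groups
    pr <- runif(1, 0.1, 0.5)
    counts <- cbind(present = rbinom(3, c(30, 20, 20), pr),
                    absent = 0L)
    counts[, "absent"] <- c(30, 20, 20) - counts[, "present"]
    if (any(colSums(counts) == 0)) next
    if (fisher_exact_rxc(counts) <= 0.05) reject <- reject + 1L
  }
  expect_lte(reject / n_sim, 0.055)
})
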