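# biochemical properties and group comparisons

test_that("pI matches the closed-form midpoint for two-group peptides", {
  # only termini ionizable: pI = (pKa_N + pKa_C)/2
  pka <- c(Nterm = 9.6, Cterm = 2.34)
  expect_equal(isoelectric_point("GG", pka_set = pka),
               (9.6 + 2.34) / 2, tolerance = 0.01)
})

test_that("pI agrees with a dense grid-scan oracle", {
  seqs <- c("DDDDDD", "KKKKKK", "MKLVRDDEEHACY", "GASTPQNLVF")
  for (s in seqs) {
    grid <- seq(0.001, 13.999, by = 0.001)
    ch <- net_charge(s, grid)
    oracle <- grid[which.min(abs(ch))]
    expect_equal(isoelectric_point(s), oracle, tolerance = 0.005)
    # root-finding contract
    expect_lt(abs(net_charge(s, isoelectric_point(s))), 1e-3)
  }
  expect_lt(isoelectric_point("DDDDDD"), 4)
})

test_that("pI depends on composition only", {
  s <- "MKLVRDDEEHACYKKRST"
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(isoelectric_point(s), isoelectric_point(perm))
  expect_warning(pi_x <- isoelectric_point("MKXZ"), "non-standard")
  expect_equal(pi_x, isoelectric_point("MK"))
  expect_error(isoelectric_point(""), "empty")
})

test_that("IDR coverage counts strict exceedances of the cutoff", {
  expect_equal(idr_coverage(rep(0.9, 10)), 1.0)
  expect_equal(idr_coverage(c(rep(0.5, 5), rep(0.2, 5))), 0.0)
  expect_equal(idr_coverage(c(rep(0.8, 30), rep(0.1, 70))), 0.30)
  # concatenating a track with itself leaves coverage unchanged
  set.seed(1)
  tr <- runif(57)
  expect_equal(idr_coverage(c(tr, tr)), idr_coverage(tr))
  expect_error(idr_coverage(numeric(0)), "empty")
  expect_error(idr_coverage(c(0.2, 1.4)), "0, 1")
})

test_that("disorder tracks and PrLD summaries parse from text", {
  tp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# predictor output", "# pos res score",
               "1\tM\t0.81", "2\tK\t0.62", "3\tL\t0.20"), tp)
  sc <- read_idr_track(tp)
  expect_equal(sc, c(0.81, 0.62, 0.20))
  expect_equal(idr_coverage(sc), 2 / 3)

  pp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SEQid\tLLR\tCORELEN",
               "p1\t10.2\t30", "p2\t-4\t0", "p3\t8\t41",
               "p4\t1\t22", "p5\t-2\t0"), pp)
  pr <- parse_prld(pp)
  expect_equal(pr$has_prld, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(sum(pr$has_prld), 3)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SEQid\tLLR", "p1\t10"), bad)
  expect_error(parse_prld(bad), "core-length")
})

test_that("continuous comparisons use Welch and ANOVA/Tukey correctly", {
  # direct-formula oracle: t = (m2 - m1)/sqrt(s1^2/n1 + s2^2/n2)
  a_ <- c(1, 2, 3); b_ <- c(4, 5, 6)
  t_oracle <- (mean(b_) - mean(a_)) /
    sqrt(var(a_) / 3 + var(b_) / 3)
  w <- compare_groups_continuous(c(a_, b_), rep(c("a", "b"), each = 3))
  expect_equal(w$method, "Welch t-test")
  expect_equal(abs(w$statistic), t_oracle)

  # three identical groups: F = 0, p = 1
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  a <- compare_groups_continuous(v, g)
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)
  expect_equal(nrow(a$pairwise), 3)

  expect_error(compare_groups_continuous(rep(1, 6),
                                         rep(c("a", "b"), each = 3)),
               "degenerate")
})

test_that("ANOVA p agrees with a permutation oracle", {
  set.seed(4)
  v <- c(rnorm(6, 0), rnorm(6, 1.2), rnorm(6, 0.4))
  g <- rep(c("a", "b", "c"), each = 6)
  a <- compare_groups_continuous(v, g)
  fstat <- function(vv) {
    fit <- summary(aov(vv ~ factor(g)))[[1]]
    fit[["F value"]][1]
  }
  f0 <- fstat(v)
  perm <- replicate(10000, fstat(sample(v)))
  p_perm <- mean(perm >= f0)
  expect_lt(abs(a$p_value - p_perm), 0.02)
})

test_that("chi-square reproduces the granule-fusion contrast", {
  tab <- matrix(c(46, 4, 14, 36), 2,
                dimnames = list(c("fused", "not"),
                                c("vehicle", "blebb")))
  cc <- compare_groups_categorical(tab)
  expect_equal(cc$statistic, 42.67, tolerance = 0.01 / 42.67)
  expect_equal(cc$df, 1)
  # hand oracle: sum (O - E)^2 / E
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(cc$statistic, sum((tab - e)^2 / e))

  eq <- compare_groups_categorical(matrix(c(10, 30, 5, 15), 2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  expect_error(compare_groups_categorical(matrix(c(0, 0, 3, 4), 2)),
               "zero margin")
})

test_that("chi-square and Fisher point the same way on random tables", {
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    cc <- compare_groups_categorical(tab)
    pf <- fisher.test(tab)$p.value
    # agreement in significance direction at 0.05 (skip borderline
    # tables where the two tests legitimately straddle the cutoff)
    if (min(cc$p_value, pf) > 0.04 || max(cc$p_value, pf) < 0.06)
      expect_equal(cc$p_value < 0.05, pf < 0.05)
  }
})

test_that("FASTA sequences round-trip through the reader", {
  fp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKLV", "RDDE",
               ">p2", "GGGG"), fp)
  s <- read_protein_fasta(fp)
  expect_equal(s, c(p1 = "MKLVRDDE", p2 = "GGGG"))
})

test_that("planted property differences reproduce the group pattern", {
  sim <- simulate_timecourse(sim_config(n_early = 60, n_late = 40,
                                        n_invariable = 30, seed = 3))
  props <- simulate_property_tables(sim$truth, seed = 3)
  pis <- vapply(props$sequences, isoelectric_point, numeric(1))
  cov <- vapply(props$idr_tracks, idr_coverage, numeric(1))
  cls <- sim$truth$class

  expect_gt(median(pis[cls == "early"]), median(pis[cls == "late"]))
  expect_gt(median(cov[cls == "early"]), median(cov[cls == "late"]))

  a <- compare_groups_continuous(pis, cls, variable = "pI")
  expect_lt(a$p_value, 0.01)

  rbp <- annotate_membership(sim$truth$accession, props$rbp_genes)
  tab <- table(rbp, cls)
  expect_gt(tab["TRUE", "early"] / sum(tab[, "early"]),
            tab["TRUE", "late"] / sum(tab[, "late"]))
})
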