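# independent oracles: hand-computed statistics and full enumeration

pearsonChisqByHand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# two-sided exact rank-sum p by full enumeration of group assignments
enumRankSumP <- function(a, b) {
  x <- c(a, b)
  n <- length(x); na <- length(a)
  r <- rank(x)
  wobs <- sum(r[seq_len(na)])
  combs <- utils::combn(n, na)
  ws <- apply(combs, 2, function(i) sum(r[i]))
  lo <- mean(ws <= wobs); hi <- mean(ws >= wobs)
  min(1, 2 * min(lo, hi))
}

test_that("chi-square independence matches hand computation", {
  r0 <- chiSquareIndependence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r1 <- chiSquareIndependence(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r1$statistic, 40)
  expect_equal(r1$df, 1)
  expect_equal(r1$statistic,
               pearsonChisqByHand(matrix(c(20, 0, 0, 20), 2)))

  r2 <- chiSquareIndependence(matrix(5, nrow = 2, ncol = 3))
  expect_equal(r2$statistic, 0)

  expect_warning(chiSquareIndependence(matrix(c(5, 5, 0, 0, 4, 6), 2)),
                 "dropped")
})

test_that("CMH reduces to (N-1)/N x chi-square on one stratum and is null-correct", {
  tab <- matrix(c(12, 5, 7, 14), 2)
  N <- sum(tab)
  r <- cmhTest(tab)
  expect_equal(r$statistic, (N - 1) / N * pearsonChisqByHand(tab),
               tolerance = 1e-12)

  # two identical strata with equal cell proportions: statistic 0, p = 1
  s <- matrix(c(10, 10, 20, 20), 2)
  arr <- array(c(s, s), dim = c(2, 2, 2))
  r0 <- cmhTest(arr)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  # degenerate stratum dropped with warning
  bad <- array(c(s, matrix(c(0, 0, 5, 5), 2)), dim = c(2, 2, 2))
  expect_warning(cmhTest(bad), "degenerate")
})

test_that("CMH post hoc Fisher comparisons cover all group pairs", {
  counts <- array(c(30, 10, 20, 20, 10, 30,
                    28, 12, 22, 18, 12, 28), dim = c(2, 3, 2),
                  dimnames = list(c("resp", "nonresp"),
                                  c("PA", "C1", "C2"), NULL))
  r <- cmhTest(counts)
  expect_equal(nrow(r$post_hoc), 3)
  expect_true(all(r$post_hoc$p_adjusted >= r$post_hoc$p_raw))
})

test_that("Kruskal-Wallis H and exact rank-sum p match enumeration", {
  r <- kruskalWallisPosthoc(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-9)  # 3.857
  expect_equal(r$post_hoc$p_raw, 0.1)
  expect_equal(r$post_hoc$p_raw,
               enumRankSumP(c(1, 2, 3), c(4, 5, 6)))

  same <- kruskalWallisPosthoc(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # enumeration equivalence across random small samples (N <= 8, no ties)
  set.seed(17)
  for (i in 1:10) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    x <- sample(100, na + nb)
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    r <- kruskalWallisPosthoc(list(a, b))
    expect_equal(r$post_hoc$p_raw, enumRankSumP(a, b), tolerance = 1e-12)
  }
})

test_that("one-way ANOVA with Tukey matches closed forms", {
  r <- anovaTukey(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$statistic, 3, tolerance = 1e-12)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(23)
  a <- rnorm(8); b <- rnorm(6, 1)
  r2 <- anovaTukey(list(a, b))
  t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(r2$statistic, unname(t2), tolerance = 1e-9)

  ident <- anovaTukey(list(c(1, 1), c(1, 1)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  degen <- anovaTukey(list(c(1, 1), c(2, 2)))
  expect_equal(degen$p_value, 0)
  expect_match(degen$method, "zero residual")
})

test_that("one-sample t vs 1 matches hand computation", {
  r <- oneSampleVsOne(c(0.9, 1.1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- oneSampleVsOne(c(1.2, 1.3, 1.1, 1.4))
  expect_equal(r2$statistic, 0.25 / (sqrt(0.05 / 3) / 2), tolerance = 1e-9)

  expect_error(oneSampleVsOne(c(1, 1, 1)), "zero standard deviation")
  expect_error(oneSampleVsOne(1), "two values")
})

test_that("Holm-Bonferroni adjustment is the step-down procedure", {
  expect_equal(holmBonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmBonferroni(0.2), 0.2)
  expect_equal(holmBonferroni(rep(1, 4)), rep(1, 4))
  # monotone, >= raw, capped at 1
  set.seed(3)
  p <- runif(12)
  adj <- holmBonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("tests are invariant to group order", {
  set.seed(29)
  g <- list(rnorm(7), rnorm(5, 0.5), rnorm(6, 1))
  expect_equal(kruskalWallisPosthoc(g)$statistic,
               kruskalWallisPosthoc(rev(g))$statistic)
  expect_equal(anovaTukey(g)$statistic, anovaTukey(rev(g))$statistic)
})

test_that("null rejection rates are calibrated at alpha = 0.05", {
  set.seed(41)
  nrep <- 2000
  kw <- mean(replicate(nrep, {
    kruskalWallisPosthoc(list(rnorm(20), rnorm(20), rnorm(20)))$p_value < 0.05
  }))
  expect_lt(abs(kw - 0.05), 2 * sqrt(0.05 * 0.95 / nrep) + 0.005)

  cmh <- mean(replicate(nrep, {
    counts <- array(rbinom(2 * 4 * 3, 25, 0.3), dim = c(2, 4, 3))
    counts[2, , ] <- 25 - counts[1, , ]
    cmhTest(counts)$p_value < 0.05
  }))
  expect_lt(abs(cmh - 0.05), 0.02)
})
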