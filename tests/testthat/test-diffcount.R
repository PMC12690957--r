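test_that("median-of-ratios size factors with geometric-mean normalisation", {
  m <- matrix(c(10, 20, 40, 20, 40, 80), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  f <- sizeFactors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  ident <- cbind(s1 = c(5, 9, 2), s2 = c(5, 9, 2))
  expect_equal(unname(sizeFactors(ident)), c(1, 1))
  # a zero in every feature forces the library-size fallback
  z <- matrix(c(0, 4, 6, 0, 3, 0, 0, 12), ncol = 2,
              dimnames = list(letters[1:4], c("s1", "s2")))
  f2 <- sizeFactors(z)
  libs <- colSums(z)
  expect_equal(unname(f2), unname((libs / mean(libs)) /
                                    exp(mean(log(libs / mean(libs))))))
  expect_error(sizeFactors(matrix(0, 2, 2)), "all-zero")
})

test_that("cpm and tpm identities", {
  cnt <- matrix(c(1, 1), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- tpmMatrix(cnt, lengths = c(100, 300))
  expect_equal(unname(tpm[, 1]), c(750000, 250000))
  set.seed(41)
  cnt2 <- matrix(rpois(60, 50), nrow = 6,
                 dimnames = list(letters[1:6], paste0("s", 1:10)))
  tpm2 <- tpmMatrix(cnt2, lengths = sample(200:900, 6))
  expect_equal(unname(colSums(tpm2)), rep(1e6, 10))
  unif <- matrix(7, nrow = 4, ncol = 3,
                 dimnames = list(letters[1:4], paste0("s", 1:3)))
  expect_true(all(abs(cpmMatrix(unif) - 1e6 / 4) < 1e-9))
  # doubling depth with matching factors leaves cpm comparable
  dbl <- cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
  rownames(dbl) <- letters[1:3]
  cpm <- cpmMatrix(dbl, sizeFactors(dbl))
  expect_equal(cpm[, 1], cpm[, 2])
})

test_that("dispersion estimation recovers the simulated magnitude", {
  set.seed(42)
  n <- 1000
  mu <- exp(runif(n, log(20), log(500)))
  pois <- matrix(nbDraw(n * 6, rep(mu, 6), 0), nrow = n,
                 dimnames = list(sprintf("f%04d", 1:n), paste0("s", 1:6)))
  groups <- rep(c("A", "B"), each = 3)
  est0 <- estimateDispersions(pois, groups)
  expect_lte(median(est0$tagwise), 0.02)
  nb <- matrix(nbDraw(n * 6, rep(mu, 6), 0.1), nrow = n,
               dimnames = dimnames(pois))
  est1 <- estimateDispersions(nb, groups)
  expect_gte(median(est1$tagwise), 0.05)
  expect_lte(median(est1$tagwise), 0.2)
  # constant feature: zero raw dispersion before shrinkage
  const <- rbind(f1 = rep(10, 6), f2 = c(3, 9, 4, 8, 2, 7))
  expect_identical(estimateDispersions(const, groups)$raw[["f1"]], 0)
  expect_error(estimateDispersions(nb[, 1:2], c("A", "B")), "replicated")
})

test_that("nbTest identities and degenerate groups", {
  cnt <- cbind(a1 = c(10, 5), a2 = c(10, 5), a3 = c(10, 5),
               b1 = c(10, 5), b2 = c(10, 5), b3 = c(10, 5))
  rownames(cnt) <- c("f1", "f2")
  res <- nbTest(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                dispersions = 0.1)
  expect_equal(res$log2_fc, c(0, 0))
  expect_equal(res$statistic, c(0, 0), tolerance = 1e-8)
  expect_equal(res$p_value, c(1, 1), tolerance = 1e-6)
  # all-zero group: finite negative fold change via the pseudocount
  cnt2 <- cbind(a1 = 100, a2 = 110, a3 = 90, b1 = 0, b2 = 0, b3 = 0)
  rownames(cnt2) <- "f1"
  res2 <- nbTest(cnt2, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                 dispersions = 0.1)
  expect_true(is.finite(res2$log2_fc) && res2$log2_fc < 0)
  expect_lt(res2$p_value, 0.01)
  expect_error(nbTest(cnt, c("a1", "a2"), c("a2", "b1")), "disjoint")
  expect_error(nbTest(cnt, "a1", c("b1", "b2")), "two samples")
})

test_that("Newton fits agree with the grid-search likelihood oracle", {
  # the spec fixture: ~4-fold induction
  cnt <- cbind(a1 = 100, a2 = 110, a3 = 90, b1 = 400, b2 = 420, b3 = 380)
  rownames(cnt) <- "f1"
  res <- nbTest(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                dispersions = 0.05)
  expect_equal(res$log2_fc, 2, tolerance = 0.01)
  expect_lt(res$p_value, 1e-6)
  llA <- gridNBLoglik(c(100, 110, 90), rep(1, 3), 0.05)
  llB <- gridNBLoglik(c(400, 420, 380), rep(1, 3), 0.05)
  ll0 <- gridNBLoglik(c(100, 110, 90, 400, 420, 380), rep(1, 6), 0.05)
  expect_equal(res$statistic, 2 * (llA + llB - ll0), tolerance = 1e-3)

  # random features, uneven size factors
  set.seed(43)
  for (i in 1:25) {
    y <- rnbinom(6, mu = exp(runif(1, log(5), log(500))), size = 10)
    s <- exp(runif(6, -0.5, 0.5))
    phi <- runif(1, 0.01, 0.3)
    cntr <- matrix(y, nrow = 1, dimnames = list("f", paste0("s", 1:6)))
    res <- nbTest(cntr, paste0("s", 1:3), paste0("s", 4:6),
                  factors = setNames(s, paste0("s", 1:6)), dispersions = phi)
    llA <- gridNBLoglik(y[1:3], s[1:3], phi)
    llB <- gridNBLoglik(y[4:6], s[4:6], phi)
    ll0 <- gridNBLoglik(y, s, phi)
    expect_equal(res$statistic, max(0, 2 * (llA + llB - ll0)),
                 tolerance = 2e-4, info = paste("feature", i))
  }
})

test_that("bhAdjust equals the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  set.seed(44)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    got <- bhAdjust(p)
    expect_equal(got, bruteBH(p), info = paste("vector", i))
    expect_true(all(got >= p))
    # invariant to permutation, up to reordering
    perm <- sample(seq_along(p))
    expect_equal(bhAdjust(p[perm]), got[perm])
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calls use strict inequalities", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2_fc = c(0.61, 0.6, -0.7, 0.9),
                    padj = c(0.049, 0.049, 0.01, 0.05))
  cs <- callSignificant(res, 0.05, 0.6)
  expect_identical(cs$up, "a")       # b fails lfc == threshold
  expect_identical(cs$down, "c")
  expect_true("d" %in% cs$ns)        # padj == alpha is not significant
  cs0 <- callSignificant(res, 0.05, 0)
  expect_setequal(cs0$up, c("a", "b"))
})
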