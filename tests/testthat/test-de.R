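## Size factors, moment dispersion, NB Wald test, BH adjustment, DEG
## calling, similarity QC and biotype composition.

test_that("median-of-ratios size factors match the two-pass oracle", {
  k <- matrix(rpois(60, 50) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  same <- k[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("s", 1:4)
  expect_equal(unname(morSizeFactors(same)), rep(1, 4))

  doubled <- cbind(k, s7 = 2 * k[, 1])
  s <- morSizeFactors(doubled)
  expect_equal(unname(s["s7"] / s["s1"]), 2)

  set.seed(21)
  big <- matrix(rnbinom(600, mu = 100, size = 5) + 1, 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  expect_equal(unname(morSizeFactors(big)), oracleSizeFactors(big),
               tolerance = 1e-12)
})

test_that("size factors agree with the standard implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  ## odd gene count: the median ratio is a single order statistic, so the
  ## ratio-scale and log-scale medians coincide exactly
  k <- matrix(rnbinom(1194, mu = 80, size = 2), 199, 6,
              dimnames = list(sprintf("g%03d", 1:199), paste0("s", 1:6)))
  k <- k + 1
  expect_equal(unname(morSizeFactors(k)),
               unname(DESeq2::estimateSizeFactorsForMatrix(k)),
               tolerance = 1e-10)
})

test_that("sparse matrices fall back to a pseudo-reference or error", {
  k <- rbind(g1 = c(0, 5, 9), g2 = c(4, 0, 2), g3 = c(3, 8, 0))
  colnames(k) <- paste0("s", 1:3)
  expect_error(morSizeFactors(k), "pseudo-reference")
  s <- morSizeFactors(k, allowPseudoReference = TRUE)
  expect_true(all(s > 0))
})

test_that("moment dispersion recovers simulated overdispersion", {
  ## exact equality of mean and variance floors the estimate
  k <- rbind(g1 = c(1, 3, 1, 3), g2 = c(2, 2, 2, 2))
  colnames(k) <- paste0("s", 1:4)
  d <- momentDispersion(k, sizeFactors = rep(1, 4),
                        condition = c("a", "a", "b", "b"))
  expect_equal(unname(d["g2"]), 1e-8)

  ## Poisson counts: estimates collapse toward the floor
  sim <- simulateRnaSeqCounts(nGenes = 400, nPerGroup = 50, fracDe = 0,
                              dispersion = 0, sizeFactorLog2 = 0,
                              meanRange = c(100, 100), seed = 6)
  d <- momentDispersion(assay(sim), sizeFactors = rep(1, 100),
                        condition = sampleConditions(sim))
  expect_lt(median(d), 1e-3)

  ## NB at alpha = 0.1 with 20 per group: median estimate in [0.05, 0.2]
  sim <- simulateRnaSeqCounts(nGenes = 500, nPerGroup = 20, fracDe = 0,
                              dispersion = 0.1, meanRange = c(50, 500),
                              seed = 7)
  d <- momentDispersion(sim)
  expect_gt(median(d), 0.05)
  expect_lt(median(d), 0.2)
})

test_that("Wald test is null on identical groups and recovers planted lfc", {
  k <- matrix(rep(c(10, 20, 30, 10, 20, 30), 4), 4, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  res <- nbWaldTest(k, condition = rep(c("u", "t"), each = 3))
  expect_equal(unname(res$log2fc), rep(0, 4))
  expect_equal(unname(res$p), rep(1, 4))

  sim <- simulateRnaSeqCounts(nGenes = 1500, nPerGroup = 5, fracDe = 0.1,
                              deLfc = 2, dispersion = 0.1,
                              meanRange = c(50, 1000), seed = 8)
  res <- nbWaldTest(sim)
  tt <- truthTable(sim)
  est <- res$log2fc[match(tt$id[tt$isDe], res$id)]
  expect_lt(abs(mean(abs(est)) - 2), 0.25)
})

test_that("BH adjustment equals the hand step-up and its invariances", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.4), 0.4)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracleBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                       # never decreases
    perm <- sample(seq_along(p))
    expect_equal(bhAdjust(p[perm]), adj[perm])       # permutation-equivariant
  }
})

test_that("DEG calling equals a brute-force filter", {
  set.seed(12)
  res <- DataFrame(id = sprintf("g%03d", 1:200), log2fc = rnorm(200),
                   padj = runif(200), deg = NA, direction = NA_character_)
  out <- callDegs(res, padjThreshold = 0.2)
  manual <- res$padj <= 0.2
  expect_identical(out$table$deg, manual)
  expect_identical(unname(out$summary["nDeg"]),
                   unname(out$summary["nUp"] + out$summary["nDown"]))
  expect_true(all(out$table$direction[manual & res$log2fc < 0] == "down"))
  expect_true(all(out$table$direction[!manual] == "none"))

  allOne <- DataFrame(id = "g1", log2fc = 1, padj = 1, deg = NA,
                      direction = NA_character_)
  expect_identical(unname(callDegs(allOne, 0.5)$summary[c("nDeg", "nUp",
                                                          "nDown")]),
                   c(0L, 0L, 0L))
  zero <- DataFrame(id = c("a", "b"), log2fc = c(0, 1), padj = c(0, 0.5),
                    deg = NA, direction = NA_character_)
  out0 <- callDegs(zero, padjThreshold = 0)
  expect_identical(unname(out0$summary["nDeg"]), 1L)
  expect_identical(out0$table$direction[1], "up")    # zero-lfc convention
})

test_that("sample similarity matches its definitional oracle", {
  set.seed(14)
  k <- matrix(rnbinom(300, mu = 60, size = 3), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  k[1, ] <- k[1, ] + 1   # guarantee an all-positive gene
  dup <- cbind(k, s7 = k[, 3])
  s <- morSizeFactors(dup)
  sim <- sampleSimilarity(dup, s)
  expect_equal(sim$euclidean["s3", "s7"], 0)
  expect_equal(sim$pearson["s3", "s7"], 1)
  expect_equal(sim$euclidean, t(sim$euclidean))
  expect_true(all(diag(sim$euclidean) == 0))
  expect_true(all(abs(sim$pearson) <= 1 + 1e-12, na.rm = TRUE))

  lg <- log2(sweep(dup, 2, s, "/") + 1)
  expect_equal(unname(sim$euclidean["s1", "s2"]),
               sqrt(sum((lg[, "s1"] - lg[, "s2"])^2)), tolerance = 1e-10)
  expect_equal(unname(sim$pearson["s1", "s2"]),
               cor(lg[, "s1"], lg[, "s2"]), tolerance = 1e-10)
})

test_that("a constant sample yields NA correlation, not zero", {
  k <- rbind(g1 = c(5, 8, 5), g2 = c(5, 9, 7), g3 = c(5, 1, 2))
  colnames(k) <- paste0("s", 1:3)
  sim <- sampleSimilarity(k, sizeFactors = c(1, 1, 1))
  expect_true(is.na(sim$pearson["s1", "s2"]))
  expect_false(is.na(sim$pearson["s2", "s3"]))
})

test_that("biotype composition uses largest-remainder integer rounding", {
  res <- DataFrame(id = paste0("g", 1:4), deg = c(TRUE, TRUE, FALSE, TRUE))
  bio <- setNames(c("protein_coding", "protein_coding", "lncRNA",
                    "pseudogene"), paste0("g", 1:4))
  comp <- biotypeComposition(res, bio)
  expect_identical(sum(comp), 100L)
  expect_identical(unname(comp["lncRNA"]), 0L)   # not a DEG
  expect_identical(unname(comp["protein_coding"]), 67L)

  two <- DataFrame(id = c("a", "b"), deg = c(TRUE, TRUE))
  comp2 <- biotypeComposition(two, c(a = "lncRNA", b = "TEC"))
  expect_identical(unname(comp2[c("lncRNA", "TEC")]), c(50L, 50L))

  set.seed(15)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    resR <- DataFrame(id = paste0("g", 1:n), deg = TRUE)
    bioR <- setNames(sample(c("protein_coding", "pseudogene", "lncRNA",
                              "TEC", "processed_transcript", "ncRNA"),
                            n, replace = TRUE), paste0("g", 1:n))
    expect_identical(sum(biotypeComposition(resR, bioR)), 100L)
  }
  expect_error(biotypeComposition(res, bio[-1]), "missing biotype")
})

test_that("scaling one sample scales its factor and preserves lfc", {
  sim <- simulateRnaSeqCounts(nGenes = 800, nPerGroup = 4, fracDe = 0.1,
                              dispersion = 0.05, meanRange = c(50, 500),
                              sizeFactorLog2 = 0, seed = 16)
  k <- assay(sim)
  cond <- sampleConditions(sim)
  res1 <- nbWaldTest(k, condition = cond)
  k2 <- k
  k2[, 1] <- k2[, 1] * 3L
  s1 <- morSizeFactors(k)
  s2 <- morSizeFactors(k2)
  ## size factors are relative scalings: the factor of the scaled sample
  ## grows by exactly c relative to any other sample
  expect_equal(unname((s2[1] / s2[2]) / (s1[1] / s1[2])), 3,
               tolerance = 1e-10)
  res2 <- nbWaldTest(k2, condition = cond)
  expect_lt(max(abs(res1$log2fc - res2$log2fc)), 0.05)
})

test_that("all-zero genes are dropped and reported", {
  k <- rbind(g1 = c(5, 6, 7, 8), g2 = c(0, 0, 0, 0), g3 = c(9, 2, 3, 4))
  colnames(k) <- paste0("s", 1:4)
  res <- nbWaldTest(k, condition = c("u", "u", "t", "t"))
  expect_identical(metadata(res)$droppedAllZero, "g2")
  expect_false("g2" %in% res$id)
})
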