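## Preranked GSEA: ranking, enrichment score, permutation null, NES,
## nominal p and FDR q.

test_that("ranking is descending and stable with duplicate/NA guards", {
  m <- setNames(c(3, 1, 2), c("a", "b", "c"))
  expect_identical(names(rankFromDE(m)), c("a", "c", "b"))
  expect_identical(names(rankFromDE(rev(m))), c("a", "c", "b"))
  tiesIn <- DataFrame(id = c("x", "y", "z"), log2fc = c(1, 2, 1))
  expect_identical(names(rankFromDE(tiesIn)), c("y", "x", "z"))
  expect_error(rankFromDE(setNames(c(1, 2), c("a", "a"))), "duplicate")
  expect_error(rankFromDE(setNames(c(1, NA), c("a", "b"))), "finite")
})

test_that("enrichment score reproduces hand-walked paths", {
  ## N = 4, metrics (3, 1, -1, -3), set {gene1}: +1 then -1/3 steps
  r <- rankFromDE(setNames(c(3, 1, -1, -3), paste0("gene", 1:4)))
  out <- enrichmentScore(r, "gene1")
  expect_equal(out$es, 1)
  expect_equal(out$runningSum, c(1, 2 / 3, 1 / 3, 0))
  expect_identical(out$peakIndex, 1L)

  ## all hits precede the single trailing zero-metric miss: es hits +1
  r2 <- rankFromDE(setNames(c(5, 4, 3, 2, 1, 0), paste0("g", 1:6)))
  out2 <- enrichmentScore(r2, paste0("g", 1:5))
  expect_equal(out2$es, 1)

  ## zero-weight members trigger the flagged unweighted fallback
  r3 <- rankFromDE(setNames(c(1, 0, 0, -1), paste0("g", 1:4)))
  out3 <- enrichmentScore(r3, c("g2", "g3"))
  expect_true(out3$unweighted)

  expect_error(enrichmentScore(r, "absent"), "intersect")
  expect_error(enrichmentScore(r, paste0("gene", 1:4)), "whole universe")
})

test_that("enrichment score equals the brute-force walk on random cases", {
  set.seed(17)
  for (i in 1:500) {
    N <- sample(3:20, 1)
    metric <- sort(round(rnorm(N), 3), decreasing = TRUE)
    names(metric) <- paste0("g", seq_len(N))
    nh <- sample(seq_len(N - 1), 1)
    hits <- sort(sample(seq_len(N), nh))
    w <- sample(c(0, 1, 1.5), 1)
    es <- enrichmentScore(metric, names(metric)[hits], weight = w)$es
    expect_equal(es, oracleES(metric, seq_len(N) %in% hits, w),
                 tolerance = 1e-12)
    expect_lte(abs(es), 1 + 1e-12)
  }
})

test_that("permutation null is seeded, symmetric where it should be", {
  set.seed(3)
  half <- sort(runif(100, 0.1, 2), decreasing = TRUE)
  r <- rankFromDE(setNames(c(half, -rev(half)), paste0("g", 1:200)))
  n1 <- permutationNull(r, setSize = 10, nperm = 50, seed = 4)
  n2 <- permutationNull(r, setSize = 10, nperm = 50, seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1, permutationNull(r, 10, nperm = 50, seed = 5)))

  ## antisymmetric metric: null ES mean within 3.5 SE of zero
  null <- permutationNull(r, setSize = 15, nperm = 5000, seed = 6)
  expect_lt(abs(mean(null)), 3.5 * sd(null) / sqrt(length(null)))

  ## equal-magnitude metrics: sign balance of the null
  r2 <- rankFromDE(setNames(c(rep(1, 100), rep(-1, 100)),
                            paste0("h", 1:200)))
  null2 <- permutationNull(r2, setSize = 20, nperm = 2000, seed = 7)
  expect_gt(binom.test(sum(null2 > 0), sum(null2 != 0))$p.value, 0.01)
})

test_that("NES and nominal p follow their definitions", {
  null <- c(0.2, 0.4, -0.3, 0.6, -0.1)
  sameSign <- null[null >= 0]
  out <- nesSignificance(mean(sameSign), null)
  expect_equal(out$nes, 1)

  big <- nesSignificance(0.99, null)
  expect_equal(big$pNominal, 1 / (length(sameSign) + 1))

  set.seed(18)
  for (i in 1:50) {
    es <- rnorm(1, 0, 0.4)
    nv <- rnorm(30, 0, 0.3)
    out <- nesSignificance(es, nv)
    side <- if (es >= 0) nv[nv >= 0] else nv[nv < 0]
    expect_equal(out$nes, es / abs(mean(side)))
    expect_equal(out$pNominal,
                 (1 + sum(abs(side) >= abs(es))) / (1 + length(side)))
    expect_gte(out$pNominal, 1 / (length(nv) + 1))
  }

  degen <- nesSignificance(0.5, c(-0.2, -0.4))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$nes))
})

test_that("FDR q is clipped, monotone within sign, calibrated when null", {
  set.seed(19)
  nes <- c(rnorm(20, 0, 1.2), NA)
  nullNes <- rnorm(2000)
  q <- gseaFdr(nes, nullNes)
  expect_true(all(q[!is.na(q)] >= 0 & q[!is.na(q)] <= 1))
  expect_true(is.na(q[21]))
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & sign(nes) == sgn)
    o <- order(abs(nes[idx]), decreasing = TRUE)
    expect_true(all(diff(q[idx][o]) >= -1e-12))
  }

  ## single set far beyond the null: q = 0
  expect_equal(gseaFdr(3, rnorm(500, 0, 0.2)), 0)

  ## observed drawn from the null itself: q should not be small overall
  obs <- rnorm(50)
  expect_gte(median(gseaFdr(obs, rnorm(5000))), 0.3)
})

test_that("runGsea surfaces planted signal and honours size filters", {
  set.seed(20)
  N <- 400
  metric <- rnorm(N)
  names(metric) <- paste0("g", 1:N)
  planted <- names(sort(metric, decreasing = TRUE))[1:25]
  sets <- c(list(PLANTED = planted,
                 TOO_SMALL = paste0("g", 1:4)),
            simulateGeneSets(names(metric), nSets = 10,
                             sizeRange = c(10, 50), seed = 21))
  ranked <- rankFromDE(metric)
  res <- runGsea(ranked, sets, nperm = 200, seed = 22)
  expect_identical(metadata(res)$dropped, "TOO_SMALL")
  expect_identical(res$name[which.max(abs(res$nes))], "PLANTED")
  expect_lte(res$fdrQ[res$name == "PLANTED"],
             min(res$fdrQ[res$name != "PLANTED"]))

  res2 <- runGsea(ranked, sets, nperm = 200, seed = 22)
  expect_identical(as.data.frame(res), as.data.frame(res2))  # deterministic

  expect_error(runGsea(ranked, list(ONLY = paste0("g", 1:3)), nperm = 10,
                       seed = 1), "no gene set retained")
})

test_that("relabeling genes by a bijection leaves all statistics unchanged", {
  set.seed(23)
  metric <- setNames(rnorm(100), paste0("g", 1:100))
  sets <- simulateGeneSets(names(metric), nSets = 5, sizeRange = c(8, 20),
                           seed = 24)
  ranked <- rankFromDE(metric)
  res <- runGsea(ranked, sets, nperm = 100, seed = 25)

  relabel <- setNames(paste0("X", 1:100), names(metric))
  metric2 <- setNames(metric, relabel[names(metric)])
  sets2 <- lapply(sets, function(s) unname(relabel[s]))
  res2 <- runGsea(rankFromDE(metric2), sets2, nperm = 100, seed = 25)
  expect_equal(res$es, res2$es)
  expect_equal(res$nes, res2$nes)
  expect_equal(res$pNominal, res2$pNominal)
})

test_that("enrichment score agrees with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(26)
  metric <- sort(rnorm(150), decreasing = TRUE)
  names(metric) <- paste0("g", 1:150)
  for (i in 1:10) {
    members <- sample(names(metric), sample(5:30, 1))
    mine <- enrichmentScore(metric, members)$es
    ref <- fgsea::calcGseaStat(metric,
                               selectedStats = which(names(metric) %in%
                                                       members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})
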