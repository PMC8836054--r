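## Independent brute-force oracles used to cross-check the package's
## primitives.  Each is written from the textbook definition, deliberately
## naive, and shares no code with the implementation it checks.

## hypergeometric upper tail by explicit combinatorial sum
oracleFisher <- function(k, K, n, N) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  js <- k:jmax
  sum(choose(n, js) * choose(N - n, K - js)) / choose(N, K)
}

## O(m^2) definitional BH step-up: the adjusted p of test i is the smallest
## value of m * t / #{p <= t} over thresholds t at least as large as p_i
oracleBH <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- p[p >= p[i]]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

## running-sum enrichment score by an explicit position-by-position walk
oracleES <- function(metric, isHit, weight = 1) {
  N <- length(metric)
  NH <- sum(isHit)
  NR <- sum(abs(metric[isHit])^weight)
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (isHit[i]) {
      acc <- acc + if (NR == 0) 1 / NH else abs(metric[i])^weight / NR
    } else {
      acc <- acc - 1 / (N - NH)
    }
    run[i] <- acc
  }
  bestPos <- 0; bestNeg <- 0
  for (v in run) {
    if (v > bestPos) bestPos <- v
    if (v < bestNeg) bestNeg <- v
  }
  ## the signed maximal deviation; |max| = |min| ties resolve positive
  ## (same fp tolerance as the tested definition)
  if (bestPos >= -bestNeg - 1e-12) bestPos else bestNeg
}

## two-pass median-of-ratios: explicit geometric means, explicit median
oracleSizeFactors <- function(k) {
  gm <- numeric(nrow(k))
  for (g in seq_len(nrow(k))) gm[g] <- prod(k[g, ])^(1 / ncol(k))
  use <- gm > 0
  s <- numeric(ncol(k))
  for (j in seq_len(ncol(k))) s[j] <- median(k[use, j] / gm[use])
  s
}

## nested-loop merge of selected miRNAs x target edges x DEGs
oracleIntegrate <- function(selected, db, degs, padjThreshold) {
  keepG <- degs$id[degs$padj < padjThreshold]
  out <- data.frame(mirna = character(0), gene = character(0))
  seen <- character(0)
  for (r in seq_len(nrow(db))) {
    m <- db$mirna[r]; g <- db$gene[r]
    key <- paste(m, g)
    if (key %in% seen) next
    seen <- c(seen, key)
    if (tolower(m) %in% tolower(selected) &&
        tolower(g) %in% tolower(keepG))
      out <- rbind(out, data.frame(mirna = m, gene = g))
  }
  out
}

## per-gene distinct-miRNA count by explicit double loop
oracleMultiplicity <- function(edges) {
  genes <- unique(edges$gene)
  cnt <- integer(length(genes))
  for (i in seq_along(genes)) {
    seenM <- character(0)
    for (r in seq_len(nrow(edges)))
      if (edges$gene[r] == genes[i] && !(edges$mirna[r] %in% seenM))
        seenM <- c(seenM, edges$mirna[r])
    cnt[i] <- length(seenM)
  }
  setNames(cnt, genes)
}

## per-miRNA distinct-gene tally
oracleMirnaTally <- function(edges) {
  ms <- unique(edges$mirna)
  cnt <- integer(length(ms))
  for (i in seq_along(ms))
    cnt[i] <- length(unique(edges$gene[edges$mirna == ms[i]]))
  setNames(cnt, ms)
}

## pooled two-sample t statistic and p from the textbook formula
oracleTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(t), na + nb - 2)
}

## random edge-table instance for the integration oracles
randomIntegrationInstance <- function(nm = 60, ng = 200) {
  mir <- paste0("m", seq_len(sample(5:nm, 1)))
  gen <- paste0("g", seq_len(sample(20:ng, 1)))
  db <- data.frame(
    mirna = sample(mir, 150, replace = TRUE),
    gene = sample(gen, 150, replace = TRUE))
  degs <- S4Vectors::DataFrame(
    id = gen,
    log2fc = rnorm(length(gen)),
    padj = runif(length(gen)),
    direction = sample(c("up", "down"), length(gen), replace = TRUE))
  selected <- sample(mir, max(1, rbinom(1, length(mir), 0.5)))
  list(db = db, degs = degs, selected = selected)
}
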