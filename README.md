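# exoCargo

Multi-omics analysis of extracellular-vesicle (EV) cargo and the response
of recipient cells, in Bioconductor style (SummarizedExperiment
containers, S4 classes, plain-text TSV/GMT interchange).

Tumour cells ship proteins and small RNAs to distant cells inside
extracellular vesicles.  Characterising that cargo and its effect on
recipient cells — here, osteoblast-lineage precursors conditioned by
prostate-cancer EVs — takes four quantitative analyses that this package
implements as one reusable, tested pipeline:

1. **EV proteome enrichment** (TMT reporter ions).  Intensities are
   log2-transformed and median-centred per channel; EV-vs-cell abundance
   is tested with an unpaired two-sided Student *t*; the fold-change
   cutoff is chosen *empirically* by a Fisher sweep — the one-sided
   hypergeometric enrichment of an ExoCarta-Top-100-style marker list
   among proteins above a descending grid of cutoffs, reduced until the
   p-value exceeds α = 0.05.  Proteins with log2FC above the cutoff and
   BH FDR < 0.01 are *EV-enriched*; raw p < 0.05 with |log2FC| > 0.1
   defines *differentially abundant* (DAP).
2. **Differential expression** (bulk RNA-seq counts).  A deliberately
   simplified negative-binomial stage: median-of-ratios size factors
   s_j = median_g(K_gj / geomean_g), moment dispersion
   α̂ = max(10⁻⁸, (v̄ − m̄)/m̄²) under Var = μ + αμ², and a delta-method
   Wald test on log2((μ̂_B + ½)/(μ̂_A + ½)) referred to a Student *t*
   with n_A + n_B − 2 df; DEGs are called at BH padj ≤ 0.1.
3. **Preranked GSEA**, from scratch: the weighted running-sum enrichment
   score (hits add |m_i|/N_R, misses subtract 1/(N − N_H); ES = signed
   maximal deviation), a size-matched random-set permutation null
   (nperm = 1000), side-wise NES = ES / |mean(same-sign null)|, add-one
   nominal p, and a ratio-estimator FDR q, monotone within each sign.
4. **miRNA–target integration**.  EV small-RNA counts are normalized to
   reads per million; the top 50 miRNAs above 2000 RPM are merged with a
   validated miRNA-target table and the DEG signature (padj < 0.05);
   genes targeted by ≥ 2 distinct miRNAs survive the multiplicity
   filter, and candidate miRNAs are ranked by their number of distinct
   filtered targets.

Closed-form assay metrics (ΔΔCT fold change 2^(−ΔΔCT), scratch closure
(x − y)/x) and a synthetic multi-omics generator with planted ground
truth (markers, DE genes with known effect sizes, NB dispersion, Zipf
miRNA abundances, regulator wiring) round out the package; every stage is
validated against brute-force oracles and planted-truth recovery.

## Worked example

`makeDemo()` writes a complete synthetic input bundle with planted ground
truth; `runPipeline()` runs all four stages from the generated YAML
configuration:

```r
library(exoCargo)

demo <- makeDemo(seed = 1, outDir = "demo")
manifest <- runPipeline(demo$config)   # ~15 s, writes demo/results/*.tsv

## proteome: planted markers recovered at the published rule
pd <- read.delim("demo/results/proteome_diff.tsv")
mean(pd$enriched[pd$id %in% demo$truth$markers])    # 0.99
sum(pd$enriched)                                    # 99 of 1000 proteins

## transcriptome: 420 DEGs at padj <= 0.1 (400 planted)
de <- read.delim("demo/results/de_results.tsv")
sum(de$deg)                                         # 420
mean(de$deg[de$id %in% demo$truth$deGenes])         # 0.9475 sensitivity

## GSEA: the planted up-shifted set tops the table
gs <- read.delim("demo/results/gsea_results.tsv")
head(gs[, c("name", "size", "nes", "pNominal", "fdrQ")], 1)
#         name size      nes    pNominal fdrQ
#   PLANTED_UP   40 2.751081 0.002004008    0

## integration: all five planted regulator miRNAs rank top-5
rk <- read.delim("demo/results/ranking.tsv")
head(rk$mirna, 5)
# "miR-0042" "miR-0003" "miR-0008" "miR-0015" "miR-0027"
```

The numbers mean: of 1000 simulated proteins, the 99 called EV-enriched
are almost exactly the 100 planted markers (99% recovery, zero background
false positives); of 4000 genes the DE stage calls 420 at a 10%
false-discovery budget, recovering 94.75% of the 400 planted effects; the
gene set planted inside up-regulated genes attains the largest normalized
enrichment score with q ≈ 0; and all five miRNAs wired to many DE genes
outrank 595 background miRNAs.

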