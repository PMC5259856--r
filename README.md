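# pxRNA

Microarray analysis of mRNAs associated with purified organelle
fractions — built for the peroxisome "localizome" setting, where total
RNA (T), mitochondrial/lysosomal gradient fractions (ML), peroxisomal
gradient fractions (PX) and immunopurified peroxisomes (IP) are profiled
on the same chip, each with three technical replicates, and the question
is which transcripts are preferentially associated with the organelle
surface.

Cross-fraction comparisons of this kind cannot rely on global
normalization (the fractions genuinely differ in composition), and with
only three replicates per group moderated test statistics are fragile.
pxRNA instead implements a deterministic, assumption-light workflow:

1. **Background correction** — per array, subtract the mean of the
   chip's negative-control probes and floor at a small positive value.
2. **Invariant-gene-set normalization** — per sample type, rank genes by
   the coefficient of variation (sd/mean, n−1 convention) across that
   type's replicates; take the top *k* = 400 lowest-CV genes; for a pair
   of types (i, j) intersect the two sets and fit ordinary least squares
   on the per-probe replicate medians over the intersection:

       (A_ij, B_ij) = argmin_{a,b} Σ_g ( x_i,g − a·x_j,g − b )²

   The dependent type's samples are mapped onto the independent
   (baseline) scale by the inverse affine map v ↦ (v − B)/A, anchored so
   the invariant-set medians agree.
3. **Differential association calls** — a gene is enriched in fraction A
   over baseline B when **all** of its replicate values in A strictly
   exceed **all** of its values in B (strict dominance; ties fail), and
   its median fold change FC = median(A)/median(B) reaches the
   threshold (2 or 4; calls at 4 are nested in calls at 2).
4. **Gene set overrepresentation** — one-sided Fisher's exact test
   (hypergeometric tail) per annotation term against the expressed
   background, Benjamini–Yekutieli adjustment within each comparison's
   family of terms, significance at adjusted p < 0.05, and an
   enrichment ratio (list proportion / background proportion).
5. **Proteome integration** — mass-spectrometry tables prefiltered to
   entries with ≥ 2 peptides and ≥ 10 % sequence coverage (inclusive
   boundaries), foreign-species symbols resolved through an ortholog
   map, overlaps of the PX/IP mRNA lists with the protein symbols, and
   a two-sided Fisher test of whether proteome-backed mRNAs distribute
   unevenly across PX and IP.
6. **QC** — covariance PCA (samples as observations, natural-log scale)
   with varimax-rotated top components, and spike-in normalized qPCR
   gradient profiles (percent per fraction, levels 2^−ΔCt).

Everything is exercised end to end on a built-in synthetic-data
generator that plants known structure (per-array gain/offset
distortions, invariant genes, fold-change enrichments, one enriched
annotation term, an mRNA–protein overlap), so every stage has a
recoverable ground truth without any download.

## Worked example

```r
library(pxRNA)

cfg <- simulationConfig(seed = 42)   # 5000 probes, 4 types x 3 replicates
bundle <- generateAll(cfg)
bundle$experiment
#> FractionExperiment with 5000 probes x 12 samples
#>   sample types: IP (3), ML (3), PX (3), T (3)
#>   negative-control probes: 200

corrected <- backgroundCorrect(bundle$experiment)
norm <- normalizePair(corrected, "PX", "T", k = 400)
S4Vectors::metadata(norm)$fits[[1]]
#> LinearMapFit PX ~ T: slope 1.0432, intercept -1.4095 (n = 141, RSS = 8579)
```

The fitted slope is the relative gain of the PX arrays against the T
arrays (the generator's planted ratio for this seed is within 0.3 % of
1.0432); 141 is the size of the invariant-set intersection the fit used.

```r
calls <- callDifferential(norm, "PX", "T", fcThreshold = 2)
nrow(calls)
#> [1] 50
head(calls, 3)
#>   probe_id gene_symbol median_enriched median_baseline fold_change threshold
#> 1  PR01424   GENE01424        3427.392        753.3355    4.549622         2
#> 2  PR03076   GENE03076        7219.786       1589.9197    4.540975         2
#> 3  PR00317   GENE00317        1571.534        349.3274    4.498742         2

planted <- bundle$truth@plantedGenes
mean(planted$probe_id[planted$fraction == "PX"] %in% calls$probe_id)
#> [1] 1
```

All 50 genes planted at fold change 4 in PX are called, and nothing
else: the call list *is* the planted list.

```r
enr <- runEnrichment(list(PX_vs_T = calls$gene_symbol), bundle$annotation,
                     na.omit(geneSymbols(corrected)))
head(enr[, c("term", "a", "b", "enrichment_ratio", "p_value", "p_adjusted")], 3)
#>     term a  b enrichment_ratio      p_value  p_adjusted
#> 1 GS0001 7 43            13.44 6.127572e-07 5.84564e-05
#> 2 GS0002 0 50             0.00 1.000000e+00 1.00000e+00
#> 3 GS0003 0 50             0.00 1.000000e+00 1.00000e+00
bundle$truth@plantedTerm
#> [1] "GS0001"
```

The planted term ranks first with a Benjamini–Yekutieli adjusted
p ≈ 6 × 10⁻⁵; 7 of the called genes fall inside it, a 13.4-fold
enrichment over the background proportion.

The orchestrated version of all of this is `runPipeline(runConfig(...))`
(or the thin CLI at `inst/scripts/pxrna.R`), which also writes per-pair
call tables, Venn summaries, the enrichment table and an overall JSON
report. Real data enter through `readFractionExperiment()` /
`readSeriesMatrix()` (GEO series-matrix text format), `readGMT()`,
`readMSTable()` and `readOrthologMap()`.

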