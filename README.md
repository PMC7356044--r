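# nueseq

Differential expression and expression-pattern classification for RNA-seq
studies that contrast a stress-tolerant and a stress-sensitive genotype —
here, a high– and a low–nitrogen-use-efficiency (NUE) genotype under
nitrogen deficit. The package answers the question behind such designs:
*which genes let the tolerant genotype respond less?* It separates the
genes that respond uniquely in the sensitive genotype into

- **frontloaded** genes — constitutively higher in the tolerant genotype
  under control conditions, muted once stress arrives;
- **stress-tolerance** genes — equal or lower in the tolerant genotype and
  insensitive to the stress there;
- **relatively upregulated** genes — downregulated under stress in the
  sensitive genotype while the tolerant genotype holds them relatively high.

## What it computes

For a gene × sample count matrix over a 2 genotype (T29 = high-NUE, T13 =
low-NUE) × 2 condition (C = control, T = N-deficit) factorial:

1. **NB differential expression**, self-contained: median-of-ratios size
   factors `s_j = median_i k_ij / (Π_j k_ij)^(1/m)`; method-of-moments
   dispersion (`Var = μ + αμ²`) shrunk towards the across-gene mean;
   the conditional exact test on group sums (Poisson/binomial in the `α = 0`
   limit); Benjamini–Hochberg step-up FDR; DEG calls at `padj < 0.05`;
   signed fold changes with `|FC| ≥ 1`; FPKM for replicate QC.
2. **Contrast set algebra** over the four canonical comparisons
   (R29: T29_T vs T29_C; R13: T13_T vs T13_C; GC: T29_C vs T13_C;
   GT: T29_T vs T13_T): unique responders, common responders, Venn counts.
3. **Pattern classification** of each unique responder from the
   cross-genotype ratios `r_C = T29_C/T13_C` and `r_T = T29_T/T13_T`
   (pseudocounted normalized means): up + `r_C > 1` + `r_T < 1` →
   frontloaded; down + `r_T > 1` → relatively upregulated; `r_C ≤ 1` (and
   `r_T ≤ 1` for down) → stress tolerance; discordant dual responders →
   opposite; plus a 1-df chi-square test of whether changes are larger in
   the sensitive genotype (50:50 null).
4. **Validation tools**: NB count simulation with planted archetypes and
   recovery scoring, replicate correlation on log10(FPKM+1), and qPCR
   2^−ΔΔCt concordance against DE calls.

## Worked example

```r
library(nueseq)
out <- runNuePipeline(list(nGenes = 1000, seed = 1,
  archetypeCounts = list(frontloaded = 40, stress_tolerance_up = 5,
                         stress_tolerance_down = 5,
                         relatively_upregulated = 40, opposite = 4)))
out$catalog
#> ContrastCatalog (padj < 0.05)
#>   R29 T29_T vs T29_C   up    4  down    5  of 1000 genes
#>   R13 T13_T vs T13_C   up   51  down   46  of 1000 genes
#>   GC  T29_C vs T13_C   up   36  down   12  of 1000 genes
#>   GT  T29_T vs T13_T   up   42  down   17  of 1000 genes
out$recovery
#>                    class tp fp fn precision recall
#> 1            frontloaded 37  2  3 0.9487179  0.925
#> 2       stress_tolerance 10  0  0 1.0000000  1.000
#> 3 relatively_upregulated 40  1  0 0.9756098  1.000
#> 4               opposite  4  0  0 1.0000000  1.000
```

The sensitive genotype shows a broad response (97 DEGs in R13) while the
tolerant one barely moves (9 in R29); 92 genes respond uniquely in T13, and
the classifier assigns 39/10/41 of them to the three planted classes with 4
opposite-pattern genes, recovering the planted truth with precision and
recall ≥ 0.92 per class. `out$summary` carries the same numbers (plus the
chi-square direction test and qPCR concordance) in a JSON-ready structure,
and `runNuePipeline(..., outDir = "run1")` writes every stage table plus
`summary.json` to disk.

Individual stages are exported — `simulateNueCounts()`, `medianOfRatios()`,
`momDispersion()`, `nbExactTest()`, `bhAdjust()`, `runContrast()`,
`buildContrastCatalog()`, `uniqueResponders()`, `classifyPatterns()`,
`chiSquareDirection()`, `computeFPKM()`, `replicateCorrelation()`,
`ddctRatio()`, `qpcrConcordance()` — see the methods vignette
(`vignettes/nueseq-methods.Rmd`) for the model and the design decisions.

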