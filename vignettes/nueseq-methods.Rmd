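---
title: "Methods: differential expression and expression-pattern classification in nueseq"
author: "nueseq maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and expression-pattern classification in nueseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nueseq)
```

## The scientific question

Two plant genotypes that differ strongly in nitrogen-use efficiency (NUE) —
a tolerant, high-NUE genotype (labelled T29) and a sensitive, low-NUE
genotype (T13) — are profiled by RNA-seq under control nitrogen (C) and
nitrogen deficit (T). The question is not merely which genes respond to the
stress, but *why the tolerant genotype needs to respond less*. Three
expression architectures can produce tolerance:

* **Frontloaded genes** are already expressed at a higher level in the
  tolerant genotype under control conditions, and barely move when stress
  arrives; the sensitive genotype has to induce them.
* **Stress-tolerance genes** sit at an equal or *lower* level in the tolerant
  genotype and are insensitive to the stress there, while the sensitive
  genotype reacts.
* **Relatively upregulated genes** collapse under stress in the sensitive
  genotype while the tolerant genotype holds (or raises) them, ending up
  relatively higher under deficit.

nueseq implements the full inferential path from a raw count matrix to these
three classes, together with a calibrated simulator so that every step can be
verified against planted truth.

## The statistical model

Counts $k_{ij}$ for gene $i$ in sample $j$ are modelled as negative binomial
with mean $s_j q_{ij}$ and variance $\mu + \alpha\mu^2$, where $s_j$ is a
per-sample size factor and $\alpha$ the dispersion. Note the
*dispersion* parameterization: `rnbinom()`'s `size` equals $1/\alpha$, and
$\alpha = 0$ is the Poisson limit.

**Size factors** are median-of-ratios: $s_j = \mathrm{median}_i\,
k_{ij}/(\prod_j k_{ij})^{1/m}$ over genes with positive counts in every
sample. If no such gene exists the estimator stops with an explicit error
rather than silently switching to a pseudo-reference. Two properties matter
in practice: the estimator is only defined up to the geometric-mean
reference (scaling one library by $c$ scales its factor by $c$ *relative to
the others*), and it assumes a majority of non-differential genes — in a
matrix where every gene responds, the factors absorb the response. The
worked examples and tests respect both.

**Dispersion** is estimated per gene by method of moments on normalized
counts: with $w_i$ the within-group pooled variance and $\bar q_i$ the
overall normalized mean, $\hat\alpha_i = \max(0, (w_i - \bar q_i)/\bar
q_i^2)$, with estimates below $10^{-8}$ set to 0. At typical replication (2–3
per group, 2–4 degrees of freedom) the raw estimate is very noisy, and
plugging it into an exact test is anti-conservative: genes whose within-group
variance is underestimated by chance are effectively tested as Poisson, and
with $10^4$ genes the extreme tail produces spurious discoveries that survive
FDR control. We therefore shrink each per-gene estimate halfway towards the
across-gene **mean** of the per-gene estimates. The mean (not the median) is
the right pooling target: the sampling distribution of a few-replicate
variance is strongly right-skewed, so the across-gene median underestimates
the common dispersion (in our null simulations, 0.039 for a true 0.05, versus
0.051 for the mean). With this default the per-gene raw $p<0.05$ rate on
all-null data sits near 0.057 and essentially no null gene survives BH, while
power for four-fold effects at moderate expression remains effectively 1.
`momDispersion()` exposes `"per-gene"` and `"pooled-median"` alternatives for
comparison.

**Testing** uses the conditional exact test of the classic DESeq lineage:
conditioning on the total $T = \sum_A k + \sum_B k$, the two-sided $p$ value
sums the probabilities of all partitions $(a, T-a)$ at most as likely as the
observed one, with group sums modelled as NB with means $q_0\sum_{j\in G}
s_j$ and variances $q_0\sum s_j + \alpha q_0^2 \sum s_j^2$. With $\alpha = 0$
and equal size factors this reduces exactly to the two-sided exact binomial
test — the identity the test suite verifies by full enumeration for all
totals up to 50. Totals above a cap (default 10,000, configurable) switch to
a continuity-corrected normal approximation of the same conditional
distribution; the DE table records how many genes took that path.

**Multiplicity** is handled by the Benjamini–Hochberg step-up rule,
implemented directly ($\tilde p_{(j)} = \min_{l\ge j} m p_{(l)}/l$, capped at
1) and checked against a brute-force implementation and `p.adjust`. Genes
with a total raw count below 10 across all samples are excluded from testing
(they carry $p = \tilde p = 1$); this guards the moment estimator, which is
meaningless at such depths. A gene is a DEG when $\tilde p < 0.05$.

**Reporting** uses both $\log_2$ fold change and the signed fold change
$r$ if $r \ge 1$ else $-1/r$ with $r = (\bar q_B + c)/(\bar q_A + c)$, so
magnitudes are always $\ge 1$ (the "+22.35 / −30.72" reporting style).
The pseudocount $c$ defaults to one normalized count, which keeps every ratio
finite when deficit libraries drop to zero.

## Contrasts and classification

Four contrasts with fixed orientation are computed on shared size factors:
R29 (T29_T vs T29_C), R13 (T13_T vs T13_C), GC (T29_C vs T13_C), GT (T29_T
vs T13_T); "up" is always the first-named group, so "up" in GC means higher
in the tolerant genotype. The **unique responders** of the focal genotype
(default T13) are the R13 DEGs that are not R29 DEGs — uniqueness is
membership-based, not an equivalence test of effect sizes; the muted response
of the other genotype is operationalized as its non-significance.

Classification uses pseudocounted cross-genotype ratios of normalized cell
means, $r_C$ (tolerant/focal under control) and $r_T$ (same under
treatment), with strict inequalities at 1 and an optional dead band
$\varepsilon$ on $|\ln r|$ (default 0; genes inside the band are left
unclassified rather than forced):

| rule | condition | label |
|------|-----------|-------|
| R0 | significant in both response contrasts, discordant directions | opposite |
| R1 | unique, up, $r_C > 1$, $r_T < 1$ | frontloaded |
| R2 | unique, down, $r_T > 1$ | relatively_upregulated |
| R3 | unique, up with $r_C \le 1$; or down with $r_C \le 1, r_T \le 1$ | stress_tolerance |
| R4 | anything else (incl. concordant dual responders) | unclassified |

R1 requires *both* the constitutive excess and the muted treated level;
genes with $r_C > 1$ but $r_T \ge 1$ fall to unclassified rather than being
forced into a class. The rules partition the responders (every gene gets
exactly one label), are mirror-symmetric (classifying with focal = T29 on a
genotype-swapped dataset reproduces the labels exactly), and are monotone in
the intended direction: raising $r_C$ with the other inputs fixed can only
promote a gene towards frontloaded.

The **direction-consistency test** asks whether responders change more in
the focal genotype: unique responders are split by $|\ln(\text{C/T})|$
computed within each genotype, and the two-cell split is tested against a
50:50 null with a one-degree-of-freedom goodness-of-fit chi-square. The null
is stated in the output because it is a modelling choice, not a given.

## The simulator and what it does (not) show

`simulateNueCounts()` draws per-gene baselines $\mu_0$ from a log-normal
(natural-log mean 5, sd 1.5 — median ≈ 150 counts with a realistic dynamic
range), builds the four cell means per archetype (response fold 4,
constitutive fold 3 by default), multiplies in per-sample library factors,
and samples NB counts at dispersion 0.05. Defaults use 3 replicates per cell:
two-replicate designs are common in the field and remain configurable, but
classification recovery needs the minimal extra power. The planted archetypes
are exactly the three target classes plus opposite, constitutive and null
genes; the truth table enables precision/recall scoring
(`scoreRecovery()`). For the stress-tolerance archetypes the tolerant
genotype is planted at a genuinely lower level (baseline divided by the
constitutive fold, and below the focal treated mean in the down case):
planting exact equality would put half of the estimated ratios on the wrong
side of 1 by sampling noise alone, which contradicts the class definition
("equal **or lower**") rather than testing it.

The simulator emulates the *statistical* structure the analysis assumes —
NB counts, library-size variation, factorial design, exchangeable replicates
— and nothing else. Real data add features it does not model: correlated
genes, dispersion that varies with expression, time/tissue pooling,
mapping ambiguity, and annotation redundancy. Passing recovery tests
therefore demonstrates that the inferential machinery is correct and
calibrated, not that any particular biological dataset will yield clean
classes.

A qPCR validation layer is included: `simulateQpcr()` generates
technical-triplicate Ct tables whose expected $2^{-\Delta\Delta Ct}$ equals a
known fold change (reference gene fixed, amplification efficiency fixed at
2, technical replicates averaged on the Ct scale), and `qpcrConcordance()`
checks sign agreement with DE calls using a 0.1 log2 dead band for
"no change".

## Numerical and design choices

* Exact-test ties use a $1 + 10^{-7}$ relative tolerance when comparing
  partition probabilities, the convention of the reference implementations.
* `nbExactTest` returns $p = 1$ for a zero total; such genes are filtered
  upstream anyway.
* BH is applied to tested genes only; filtered genes keep $p = \tilde p = 1$.
* Degenerate inputs error loudly: no all-positive gene row (size factors),
  empty or overlapping contrast groups, missing design cells (named),
  zero-total chi-square, missing qPCR cells.
* Problem sizes used in the shipped tests — $10^4$ genes for null
  calibration, 200 planted genes for power, 20 simulated studies of 4,224
  genes for recovery — were chosen to make simulation error small relative
  to the margins being tested while keeping a full run in minutes on one
  core.

## Known limitations

* Single-factor contrasts only: no interaction GLM, shrinkage estimator, or
  surrogate-variable correction; the four-contrast set algebra stands in for
  the factorial model, as in the classic analyses this mirrors.
* The exact test's normal-approximation branch is accurate in the bulk but
  approximate in extreme tails; for genome-scale totals this affects genes
  whose significance is never in doubt.
* Pattern labels inherit the DEG threshold: a gene just missing significance
  in the non-focal genotype counts as "muted". The dead-band parameter
  mitigates borderline ratio calls, not borderline significance calls.
* FPKM uses column totals as the mapped-read denominator; externally mapped
  read totals can be supplied only by scaling counts upstream.

## Reproducing the shipped numbers

```r
out <- runNuePipeline(list(seed = 1))        # full simulated study
out$summary$patternCounts
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
null calibration, power, per-class recovery, the chi-square direction test,
qPCR concordance and determinism from scratch; the test suite
(`tests/testthat/`) asserts the corresponding properties with fixed seeds.
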