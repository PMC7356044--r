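# Independent oracles, kept deliberately naive.

# Brute-force BH step-up straight from the definition:
# padj_(j) = min(1, min_{l >= j} m p_(l) / l) on the ascending sort.
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  padjSorted <- vapply(seq_len(m), function(j)
    min(1, min(m * ps[j:m] / (j:m))), numeric(1))
  out <- numeric(m)
  out[o] <- padjSorted
  out
}

# Two-sided exact binomial test by full enumeration, minimum-likelihood
# definition (probability of all outcomes at most as likely as the observed).
binomTwoSidedEnum <- function(a, size, prob) {
  pk <- dbinom(0:size, size, prob)
  sum(pk[pk <= pk[a + 1] * (1 + 1e-7)])
}

# Tiny deterministic four-cell experiment built by hand.
makeToyExperiment <- function(nGenes = 60, nReplicates = 2, mean = 200,
                              dispersion = 0.02, seed = 99) {
  set.seed(seed)
  n <- 4 * nReplicates
  k <- matrix(rnbinom(nGenes * n, mu = mean, size = 1 / dispersion), nGenes, n)
  geno <- rep(c("T29", "T13"), each = 2 * nReplicates)
  cond <- rep(rep(c("C", "T"), each = nReplicates), 2)
  NueExperiment(k, genotype = geno, condition = cond)
}

# Genotype-swapped copy of an experiment (T29 <-> T13), used for the mirror
# symmetry property.
swapGenotypes <- function(se) {
  geno <- ifelse(nueseq::genotype(se) == "T29", "T13", "T29")
  NueExperiment(counts(se), genotype = geno, condition = condition(se),
                replicate = SummarizedExperiment::colData(se)$replicate,
                geneLengths = geneLengths(se), archetype = archetypes(se))
}
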