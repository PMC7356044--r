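#' Draw negative-binomial counts with mean/dispersion parameterization
#'
#' Counts follow NB with `E[X] = mean` and `Var[X] = mean + dispersion *
#' mean^2`; `dispersion = 0` degenerates to Poisson. This is the
#' DESeq-family convention (`alpha`), not the `size` parameterization of
#' [stats::rnbinom] (`size = 1/alpha`).
#'
#' @param mean non-negative finite mean (scalar or vector recycled against `n`).
#' @param dispersion single non-negative dispersion `alpha`.
#' @param n number of draws.
#' @return integer vector of `n` counts.
#' @examples
#' sampleNBCounts(100, 0.5, 5)
#' @export
sampleNBCounts <- function(mean, dispersion, n) {
  if (any(!is.finite(mean)) || any(mean < 0))
    stop("mean must be finite and non-negative")
  if (length(dispersion) != 1 || !is.finite(dispersion) || dispersion < 0)
    stop("dispersion must be a single non-negative value")
  if (dispersion == 0) rpois(n, mean)
  else rnbinom(n, size = 1 / dispersion, mu = mean)
}

ARCHETYPES <- c("frontloaded", "stress_tolerance_up", "stress_tolerance_down",
                "relatively_upregulated", "opposite", "constitutive", "null")

# Expected cell means per archetype, expressed for a generic focal (responding)
# genotype F and other (tolerant) genotype O. mu0 is the focal control mean.
archetypeCellMeans <- function(archetype, mu0, responseFold, constitutiveFold) {
  rf <- responseFold; cf <- constitutiveFold
  m <- cbind(F_C = mu0, F_T = mu0, O_C = mu0, O_T = mu0)
  i <- archetype == "frontloaded"
  m[i, "F_T"] <- rf * mu0[i]
  m[i, c("O_C", "O_T")] <- cf * mu0[i]
  i <- archetype == "stress_tolerance_up"
  m[i, "F_T"] <- rf * mu0[i]
  m[i, c("O_C", "O_T")] <- mu0[i] / cf
  i <- archetype == "stress_tolerance_down"
  m[i, "F_T"] <- mu0[i] / rf
  m[i, c("O_C", "O_T")] <- mu0[i] / (cf * rf)
  i <- archetype == "relatively_upregulated"
  m[i, "F_T"] <- mu0[i] / rf
  i <- archetype == "opposite"
  m[i, "F_T"] <- rf * mu0[i]
  m[i, "O_T"] <- mu0[i] / rf
  i <- archetype == "constitutive"
  m[i, c("O_C", "O_T")] <- cf * mu0[i]
  m
}

#' Simulate a factorial NB count experiment with planted archetypes
#'
#' Generates a 2 genotype x 2 condition x `nReplicates` count matrix whose
#' genes follow planted expression archetypes mirroring the patterns sought in
#' low-N stress transcriptomics. With the default focal genotype `"T13"`
#' (the sensitive, low-NUE genotype) and `mu0` the per-gene baseline mean:
#' \describe{
#'   \item{frontloaded}{T13 responds up (`responseFold`); T29 sits at
#'     `constitutiveFold * mu0` in both conditions (constitutively primed,
#'     muted response).}
#'   \item{stress_tolerance_up / _down}{T13 responds up/down; T29 is flat at a
#'     lower level (`mu0/constitutiveFold`, and below the focal treated mean
#'     for the down case).}
#'   \item{relatively_upregulated}{T13 responds down; T29 is flat at `mu0`, so
#'     T29 ends relatively higher under stress.}
#'   \item{opposite}{up in the focal genotype, down in the other.}
#'   \item{constitutive}{genotype offset in both conditions, no treatment
#'     response.}
#'   \item{null}{one shared mean everywhere.}
#' }
#' Per-sample means are multiplied by that sample's library size factor before
#' NB sampling. Output is deterministic given `seed`.
#'
#' @param nGenes total number of genes; genes beyond the planted archetypes are
#'   null.
#' @param nReplicates replicates per genotype x condition cell.
#' @param archetypeCounts named integer vector of planted gene counts; names
#'   from `frontloaded`, `stress_tolerance_up`, `stress_tolerance_down`,
#'   `relatively_upregulated`, `opposite`, `constitutive`.
#' @param baselineLogMean,baselineLogSd natural-log mean and sd of the per-gene
#'   baseline expression level.
#' @param dispersion NB dispersion `alpha` shared by all genes.
#' @param responseFold treatment fold change in the responding genotype (> 1).
#' @param constitutiveFold control-condition genotype offset for frontloaded,
#'   stress-tolerance and constitutive genes (> 1).
#' @param librarySizeFactors one positive factor per sample (genotype-major
#'   order T29_C, T29_T, T13_C, T13_T, replicates within); default all 1.
#' @param focalGenotype which genotype carries the unique response.
#' @param seed integer RNG seed.
#' @return A [NueExperiment-class]; `rowData` holds the planted `archetype`
#'   (the truth table), gene `length` (log-uniform 200-10000 bp) and the four
#'   true cell means `mu_T29_C` ... `mu_T13_T`; `metadata(x)$simConfig` records
#'   the full configuration.
#' @examples
#' se <- simulateNueCounts(nGenes = 50, seed = 1,
#'                         archetypeCounts = c(frontloaded = 5))
#' table(archetypes(se))
#' @export
simulateNueCounts <- function(nGenes = 5000, nReplicates = 3,
                              archetypeCounts = c(frontloaded = 100,
                                                  stress_tolerance_up = 10,
                                                  stress_tolerance_down = 10,
                                                  relatively_upregulated = 100,
                                                  opposite = 4,
                                                  constitutive = 0),
                              baselineLogMean = 5, baselineLogSd = 1.5,
                              dispersion = 0.05, responseFold = 4,
                              constitutiveFold = 3,
                              librarySizeFactors = NULL,
                              focalGenotype = c("T13", "T29"), seed = 1) {
  focalGenotype <- match.arg(focalGenotype)
  if (nGenes < 1 || nReplicates < 1) stop("nGenes and nReplicates must be >= 1")
  if (responseFold <= 1 || constitutiveFold <= 1)
    stop("responseFold and constitutiveFold must be > 1")
  if (dispersion < 0 || baselineLogSd < 0)
    stop("dispersion and baselineLogSd must be >= 0")
  archetypeCounts <- archetypeCounts[archetypeCounts > 0]
  if (length(archetypeCounts) &&
      !all(names(archetypeCounts) %in% setdiff(ARCHETYPES, "null")))
    stop("unknown archetype name(s): ",
         paste(setdiff(names(archetypeCounts), ARCHETYPES), collapse = ", "))
  if (sum(archetypeCounts) > nGenes)
    stop("sum of archetypeCounts exceeds nGenes")

  nSamples <- 4L * nReplicates
  if (is.null(librarySizeFactors)) librarySizeFactors <- rep(1, nSamples)
  if (length(librarySizeFactors) != nSamples || any(librarySizeFactors <= 0))
    stop("librarySizeFactors must be ", nSamples, " positive values")

  set.seed(seed)
  archetype <- rep("null", nGenes)
  if (length(archetypeCounts))
    archetype[seq_len(sum(archetypeCounts))] <-
      rep(names(archetypeCounts), archetypeCounts)
  mu0 <- exp(rnorm(nGenes, baselineLogMean, baselineLogSd))
  cm <- archetypeCellMeans(archetype, mu0, responseFold, constitutiveFold)
  # map generic focal/other onto concrete genotypes
  if (focalGenotype == "T13") {
    cellMeans <- cbind(T29_C = cm[, "O_C"], T29_T = cm[, "O_T"],
                       T13_C = cm[, "F_C"], T13_T = cm[, "F_T"])
  } else {
    cellMeans <- cbind(T29_C = cm[, "F_C"], T29_T = cm[, "F_T"],
                       T13_C = cm[, "O_C"], T13_T = cm[, "O_T"])
  }

  genoCol <- rep(rep(GENOTYPES, each = 2L * nReplicates), times = 1)
  condCol <- rep(rep(CONDITIONS, each = nReplicates), times = 2)
  repCol  <- rep(seq_len(nReplicates), times = 4)
  cellCol <- paste(genoCol, condCol, sep = "_")
  sampleMeans <- sweep(cellMeans[, cellCol, drop = FALSE], 2,
                       librarySizeFactors, "*")
  k <- matrix(sampleNBCounts(as.vector(sampleMeans), dispersion,
                             length(sampleMeans)),
              nrow = nGenes,
              dimnames = list(sprintf("g%05d", seq_len(nGenes)),
                              paste0(cellCol, "_r", repCol)))
  lengths <- round(exp(runif(nGenes, log(200), log(10000))))

  se <- NueExperiment(k, genotype = genoCol, condition = condCol,
                      replicate = repCol, geneLengths = lengths,
                      archetype = archetype,
                      metadata = list(simConfig = list(
                        nGenes = nGenes, nReplicates = nReplicates,
                        archetypeCounts = as.list(archetypeCounts),
                        baselineLogMean = baselineLogMean,
                        baselineLogSd = baselineLogSd,
                        dispersion = dispersion, responseFold = responseFold,
                        constitutiveFold = constitutiveFold,
                        librarySizeFactors = librarySizeFactors,
                        focalGenotype = focalGenotype, seed = seed)))
  rowData(se) <- cbind(rowData(se), DataFrame(
    mu_T29_C = cellMeans[, "T29_C"], mu_T29_T = cellMeans[, "T29_T"],
    mu_T13_C = cellMeans[, "T13_C"], mu_T13_T = cellMeans[, "T13_T"]))
  se
}

#' Simulate a qPCR Ct table from known log2 fold changes
#'
#' Emulates the wet-lab validation step: for each gene, technical-triplicate
#' target and reference (18S rRNA) Ct values are drawn for a control and a
#' treatment cell such that the expected 2^-ddCt ratio equals
#' `2^log2FoldChange`, with Gaussian cycle noise.
#'
#' @param log2FoldChange named numeric vector (names are gene ids) of true
#'   treatment-vs-control log2 ratios.
#' @param ctNoiseSd per-well Ct noise sd in cycles.
#' @param nTech technical replicates per well.
#' @param targetBaseCt,referenceCt expected control-condition Ct of target and
#'   reference.
#' @return long-format data.frame with columns `gene`, `cell`
#'   (`"treatment"`/`"control"`), `replicate`, `Ct_target`, `Ct_reference`.
#'   Uses the current RNG stream; seed upstream for reproducibility.
#' @export
simulateQpcr <- function(log2FoldChange, ctNoiseSd = 0.2, nTech = 3,
                         targetBaseCt = 24, referenceCt = 10) {
  if (is.null(names(log2FoldChange)) || !length(log2FoldChange))
    stop("log2FoldChange must be a non-empty named vector")
  genes <- names(log2FoldChange)
  grid <- expand.grid(replicate = seq_len(nTech),
                      cell = c("control", "treatment"), gene = genes,
                      stringsAsFactors = FALSE)
  base <- targetBaseCt
  ctTarget <- ifelse(grid$cell == "treatment",
                     base - log2FoldChange[grid$gene], base) +
    rnorm(nrow(grid), 0, ctNoiseSd)
  ctRef <- referenceCt + rnorm(nrow(grid), 0, ctNoiseSd)
  data.frame(gene = grid$gene, cell = grid$cell, replicate = grid$replicate,
             Ct_target = ctTarget, Ct_reference = ctRef,
             stringsAsFactors = FALSE)
}
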