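rowVars <- function(x) {
  if (ncol(x) < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' Method-of-moments NB dispersion per gene
#'
#' On normalized counts, with `w_i` the within-group pooled sample variance and
#' `qbar_i` the overall normalized mean over both groups, the raw estimate is
#' \deqn{\hat\alpha_i = \max(0, (w_i - \bar q_i) / \bar q_i^2),} with values
#' below `floor` set to 0 (Poisson). Genes with `qbar = 0` get `NA` and must be
#' excluded from testing.
#'
#' With few replicates the per-gene estimate is noisy, and plugging it into the
#' exact test is anti-conservative in the lower tail (genes whose within-group
#' variance is underestimated by chance are tested as near-Poisson). The
#' default therefore shrinks each gene's estimate halfway towards the
#' across-gene mean of the per-gene estimates (`method = "blend"`); the mean,
#' unlike the median, is a nearly unbiased pooled summary under the skewed
#' sampling distribution of a few-replicate variance. `"per-gene"` and
#' `"pooled-median"` are available for comparison.
#'
#' @param normA,normB normalized count matrices (same genes) for the two
#'   groups.
#' @param method `"blend"` (default), `"per-gene"` or `"pooled-median"`.
#' @param floor estimates below this are set to 0.
#' @return numeric vector of dispersions (NA where undefined).
#' @export
momDispersion <- function(normA, normB,
                          method = c("blend", "per-gene", "pooled-median"),
                          floor = 1e-8) {
  method <- match.arg(method)
  normA <- as.matrix(normA); normB <- as.matrix(normB)
  if (nrow(normA) != nrow(normB)) stop("groups must share the gene set")
  nA <- ncol(normA); nB <- ncol(normB)
  qbar <- rowMeans(cbind(normA, normB))
  dfA <- max(nA - 1L, 0L); dfB <- max(nB - 1L, 0L)
  if (dfA + dfB == 0L) {
    warning("no within-group replication: falling back to Poisson (alpha = 0)")
    alpha <- rep(0, nrow(normA))
    alpha[qbar == 0] <- NA_real_
    return(alpha)
  }
  vA <- if (dfA > 0) rowVars(normA) else 0
  vB <- if (dfB > 0) rowVars(normB) else 0
  w <- (dfA * vA + dfB * vB) / (dfA + dfB)
  alpha <- pmax(0, (w - qbar) / qbar^2)
  alpha[alpha < floor] <- 0
  alpha[qbar == 0] <- NA_real_
  if (method != "per-gene") {
    pooled <- if (method == "blend") mean(alpha, na.rm = TRUE)
              else median(alpha, na.rm = TRUE)
    if (!is.finite(pooled)) pooled <- 0
    alpha <- switch(method,
                    blend = 0.5 * alpha + 0.5 * pooled,
                    `pooled-median` = ifelse(is.na(alpha), NA_real_, pooled))
  }
  alpha
}

#' Conditional NB exact test for two group sums
#'
#' Two-sided exact test in the DESeq (Anders-Huber) style: conditioning on the
#' total `T = sumA + sumB`, the p value is the probability of all partitions
#' `(a, T - a)` at most as likely as the observed one,
#' \deqn{p = \sum_{P(a) \le P(\mathrm{obs})} P(a, T-a) \Big/ \sum_a P(a, T-a),}
#' where each group sum is NB with mean \eqn{\mu_A = q_0 \sum_{j \in A} s_j}
#' and variance \eqn{\mu_A + \alpha q_0^2 \sum_{j \in A} s_j^2}; `alpha = 0`
#' uses the Poisson limit (for equal size factors this reduces to the exact
#' binomial test with success probability `nA/(nA+nB)`). For totals above
#' `cap` a continuity-corrected normal approximation of the conditional
#' distribution is substituted; the returned value then carries
#' `attr(p, "method") == "normal"`.
#'
#' @param sumA,sumB observed non-negative integer group sums of raw counts.
#' @param sfA,sfB size factors of the samples in each group.
#' @param q0 pooled normalized mean of the gene (must be > 0 when `T > 0`).
#' @param alpha NB dispersion (>= 0).
#' @param cap largest total enumerated exactly.
#' @return p value in \[0, 1\] with attribute `method` (`"exact"` or
#'   `"normal"`).
#' @export
nbExactTest <- function(sumA, sumB, sfA, sfB, q0, alpha, cap = 10000) {
  if (sumA < 0 || sumB < 0) stop("group sums must be non-negative")
  if (alpha < 0) stop("alpha must be non-negative")
  tot <- sumA + sumB
  if (tot == 0) return(structure(1, method = "exact"))
  SA <- sum(sfA); SB <- sum(sfB)
  muA <- q0 * SA; muB <- q0 * SB
  if (tot <= cap) {
    ks <- 0:tot
    if (alpha == 0) {
      pk <- dpois(ks, muA) * dpois(tot - ks, muB)
    } else {
      sizeA <- SA^2 / (alpha * sum(sfA^2))
      sizeB <- SB^2 / (alpha * sum(sfB^2))
      pk <- dnbinom(ks, size = sizeA, mu = muA) *
        dnbinom(tot - ks, size = sizeB, mu = muB)
    }
    denom <- sum(pk)
    if (denom == 0) return(structure(1, method = "exact"))
    pObs <- pk[sumA + 1]
    p <- sum(pk[pk <= pObs * (1 + 1e-7)]) / denom
    structure(min(1, p), method = "exact")
  } else {
    varA <- muA + alpha * q0^2 * sum(sfA^2)
    varB <- muB + alpha * q0^2 * sum(sfB^2)
    condMean <- muA + varA / (varA + varB) * (tot - muA - muB)
    condVar <- varA * varB / (varA + varB)
    z <- max(0, (abs(sumA - condMean) - 0.5) / sqrt(condVar))
    structure(min(1, 2 * pnorm(-z)), method = "normal")
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(j) = min(1, min_{l >= j} m p_(l) / l)` on the ascending sort,
#' returned in the original order; monotone non-decreasing in p.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values of the same length and order.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  padjSorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, padjSorted)[order(o)]
}

#' Signed fold change with a pseudocount
#'
#' With `r = (meanB + c) / (meanA + c)` the signed fold change is `r` when
#' `r >= 1` and `-1/r` otherwise, so its magnitude is always at least 1 — the
#' reporting convention behind summaries like "+22.35" / "-30.72".
#'
#' @param meanA,meanB non-negative group means (vectors recycled).
#' @param pseudocount added to both means; the default 1 normalized count keeps
#'   ratios finite at zero expression.
#' @return numeric vector of signed fold changes (B vs A).
#' @export
signedFoldChange <- function(meanA, meanB, pseudocount = 1) {
  if (any(meanA < 0) || any(meanB < 0)) stop("means must be non-negative")
  r <- (meanB + pseudocount) / (meanA + pseudocount)
  ifelse(r >= 1, r, -1 / r)
}

resolveGroup <- function(x, spec) {
  cells <- designCells(x)
  if (all(spec %in% colnames(x))) return(match(spec, colnames(x)))
  idx <- which(cells %in% spec)
  if (!length(idx))
    stop("group spec '", paste(spec, collapse = ","),
         "' matches no samples")
  idx
}

#' Two-group NB differential expression
#'
#' Chains the full single-contrast pipeline: median-of-ratios size factors
#' (estimated once on the full matrix unless supplied), method-of-moments
#' dispersion on the contrast's samples, the conditional NB exact test per
#' gene, Benjamini-Hochberg adjustment, and calls at `padj < alpha`. Genes
#' with total raw count below `minTotalCount` across all samples of `x` (or a
#' zero pooled normalized mean) are excluded from testing and carry
#' `p = padj = 1`, direction `"none"`. Fold changes are oriented B vs A
#' ("up" = higher in group B).
#'
#' @param x a [NueExperiment-class] (or SummarizedExperiment with a `counts`
#'   assay and genotype/condition columns).
#' @param groupA,groupB sample ids, or design-cell names such as `"T13_C"`.
#'   Groups must be non-empty and disjoint.
#' @param alpha FDR threshold for DEG calls.
#' @param sizeFactors optional pre-computed per-sample factors for all of `x`.
#' @param pseudocount used in fold-change ratios.
#' @param minTotalCount expression filter on the total raw count.
#' @param dispersionMethod passed to [momDispersion()].
#' @param cap passed to [nbExactTest()].
#' @return a `DataFrame` with one row per gene: `meanA`, `meanB` (normalized),
#'   `log2FC`, `signedFC`, `p`, `padj`, `isDEG`, `direction`; `metadata()`
#'   records the groups, alpha, and the number of genes tested by the normal
#'   approximation.
#' @export
runContrast <- function(x, groupA, groupB, alpha = 0.05, sizeFactors = NULL,
                        pseudocount = 1, minTotalCount = 10,
                        dispersionMethod = "blend", cap = 10000) {
  k <- counts(x)
  idxA <- resolveGroup(x, groupA)
  idxB <- resolveGroup(x, groupB)
  if (!length(idxA) || !length(idxB)) stop("both groups must be non-empty")
  if (length(intersect(idxA, idxB)))
    stop("groups must be disjoint (a group cannot be contrasted with itself)")
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(k)
  q <- normalizeCounts(k, sizeFactors)
  qA <- q[, idxA, drop = FALSE]; qB <- q[, idxB, drop = FALSE]
  meanA <- rowMeans(qA); meanB <- rowMeans(qB)
  qbar <- rowMeans(q[, c(idxA, idxB), drop = FALSE])
  tested <- rowSums(k) >= minTotalCount & qbar > 0
  disp <- rep(NA_real_, nrow(k))
  disp[tested] <- momDispersion(qA[tested, , drop = FALSE],
                                qB[tested, , drop = FALSE],
                                method = dispersionMethod)
  tested <- tested & !is.na(disp)

  sfA <- sizeFactors[idxA]; sfB <- sizeFactors[idxB]
  sumsA <- rowSums(k[, idxA, drop = FALSE])
  sumsB <- rowSums(k[, idxB, drop = FALSE])
  p <- rep(1, nrow(k))
  nApprox <- 0L
  for (i in which(tested)) {
    pi <- nbExactTest(sumsA[i], sumsB[i], sfA, sfB, qbar[i], disp[i], cap = cap)
    if (attr(pi, "method") == "normal") nApprox <- nApprox + 1L
    p[i] <- as.numeric(pi)
  }
  padj <- rep(1, nrow(k))
  if (any(tested)) padj[tested] <- bhAdjust(p[tested])
  log2FC <- log2((meanB + pseudocount) / (meanA + pseudocount))
  isDEG <- padj < alpha
  direction <- ifelse(!isDEG | log2FC == 0, "none",
                      ifelse(log2FC > 0, "up", "down"))
  meanA <- unname(meanA); meanB <- unname(meanB)
  log2FC <- unname(log2FC); direction <- unname(direction)
  res <- DataFrame(meanA = meanA, meanB = meanB, log2FC = log2FC,
                   signedFC = signedFoldChange(meanA, meanB, pseudocount),
                   p = p, padj = padj, isDEG = isDEG, direction = direction,
                   row.names = rownames(k))
  metadata(res) <- list(groupA = colnames(k)[idxA], groupB = colnames(k)[idxB],
                        contrast = paste0(paste(unique(designCells(x)[idxB]), collapse = "+"),
                                          " vs ",
                                          paste(unique(designCells(x)[idxA]), collapse = "+")),
                        alpha = alpha, pseudocount = pseudocount,
                        nTested = sum(tested), nApprox = nApprox,
                        sizeFactors = sizeFactors)
  res
}
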