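#' Replicate correlation on log10(FPKM + 1)
#'
#' Pearson correlation across genes for each named pair of replicate columns,
#' the standard scatter-plot QC for biological replicates.
#'
#' @param fpkm gene x sample FPKM matrix (see [computeFPKM()]).
#' @param pairs two-column data.frame or matrix of column names (replicate 1,
#'   replicate 2).
#' @param warnBelow pairs with `r` below this are flagged.
#' @return data.frame with columns `sample1`, `sample2`, `r`, `flagged`.
#' @export
replicateCorrelation <- function(fpkm, pairs, warnBelow = 0.9) {
  fpkm <- as.matrix(fpkm)
  if (nrow(fpkm) < 2) stop("need at least two genes to correlate")
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  if (!all(pairs %in% colnames(fpkm))) stop("unknown sample in pairs")
  r <- vapply(seq_len(nrow(pairs)), function(i)
    cor(log10(fpkm[, pairs[i, 1]] + 1), log10(fpkm[, pairs[i, 2]] + 1)),
    numeric(1))
  data.frame(sample1 = pairs[, 1], sample2 = pairs[, 2], r = r,
             flagged = r < warnBelow, stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = mean(Ct_target) - mean(Ct_reference)` within each cell;
#' `ddCt = dCt_treatment - dCt_control`; the relative expression ratio is
#' `2^-ddCt` (amplification efficiency fixed at 2; technical replicates are
#' averaged on the Ct scale).
#'
#' @param ctTargetTreatment,ctRefTreatment,ctTargetControl,ctRefControl
#'   numeric vectors of technical-replicate Ct values (cycles).
#' @return the relative expression ratio, with attribute `ddCt`.
#' @examples
#' ddctRatio(24, 10, 22, 10)   # ddCt = 2 -> 0.25
#' @export
ddctRatio <- function(ctTargetTreatment, ctRefTreatment,
                      ctTargetControl, ctRefControl) {
  vals <- list(ctTargetTreatment, ctRefTreatment, ctTargetControl, ctRefControl)
  if (any(vapply(vals, function(v) !length(v) || any(!is.finite(v)) ||
                   any(v <= 0), logical(1))))
    stop("all four cells need at least one finite positive Ct value")
  ddct <- (mean(ctTargetTreatment) - mean(ctRefTreatment)) -
    (mean(ctTargetControl) - mean(ctRefControl))
  structure(2^(-ddct), ddCt = ddct)
}

#' 2^-ddCt ratios for a long-format qPCR table
#'
#' @param qpcr data.frame with columns `gene`, `cell` (`"treatment"` /
#'   `"control"`), `replicate`, `Ct_target`, `Ct_reference` (the CSV layout
#'   written by [simulateQpcr()]).
#' @return named numeric vector of relative expression ratios, one per gene.
#' @export
ddctTable <- function(qpcr) {
  need <- c("gene", "cell", "Ct_target", "Ct_reference")
  if (!all(need %in% colnames(qpcr)))
    stop("qpcr table needs columns: ", paste(need, collapse = ", "))
  vapply(split(qpcr, qpcr$gene), function(d) {
    tr <- d[d$cell == "treatment", ]; ct <- d[d$cell == "control", ]
    if (!nrow(tr) || !nrow(ct))
      stop("gene ", d$gene[1], ": missing treatment or control cell")
    as.numeric(ddctRatio(tr$Ct_target, tr$Ct_reference,
                         ct$Ct_target, ct$Ct_reference))
  }, numeric(1))
}

#' Concordance of qPCR ratios with DE calls
#'
#' A gene is concordant when the sign of its log2 qPCR ratio agrees with the
#' DE direction; ratios within the dead band (`|log2 ratio| < deadband`) count
#' as "no change" and match direction `"none"`.
#'
#' @param qpcrRatios named vector of 2^-ddCt ratios.
#' @param deResult a DE table from [runContrast()] covering the same genes.
#' @param deadband log2 dead band for "no change".
#' @return list with `fraction` and a per-gene data.frame `table`.
#' @export
qpcrConcordance <- function(qpcrRatios, deResult, deadband = 0.1) {
  genes <- intersect(names(qpcrRatios), rownames(deResult))
  if (!length(genes)) stop("no genes shared between qPCR ratios and DE result")
  l2 <- log2(qpcrRatios[genes])
  qdir <- ifelse(abs(l2) < deadband, "none", ifelse(l2 > 0, "up", "down"))
  ddir <- deResult[genes, "direction"]
  conc <- qdir == ddir
  list(fraction = mean(conc),
       table = data.frame(gene = genes, qpcrRatio = qpcrRatios[genes],
                          log2Qpcr = l2, qpcrDirection = qdir,
                          deDirection = ddir, concordant = conc,
                          stringsAsFactors = FALSE, row.names = NULL))
}
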