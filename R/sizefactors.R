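#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes (restricted to
#' genes with positive counts in every sample) of the ratio of that gene's
#' count to its across-sample geometric mean:
#' \deqn{s_j = \mathrm{median}_i \; k_{ij} / (\prod_j k_{ij})^{1/m}.}
#'
#' @param counts gene x sample matrix of raw counts.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' medianOfRatios(cbind(s1 = c(4, 10), s2 = c(9, 10)))
#' @export
medianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1) stop("need at least one sample")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in every sample; median-of-ratios is ",
         "undefined (a pseudo-reference fallback is not applied silently)")
  logGeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(k) median(exp(log(k) - logGeo)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factors are not all finite and positive")
  sf
}

#' Divide counts by per-sample size factors
#'
#' @param counts gene x sample matrix.
#' @param sizeFactors positive scaling factor per sample.
#' @return matrix of normalized counts `k_ij / s_j`.
#' @export
normalizeCounts <- function(counts, sizeFactors) {
  counts <- as.matrix(counts)
  if (length(sizeFactors) != ncol(counts))
    stop("need one size factor per sample")
  if (any(!is.finite(sizeFactors)) || any(sizeFactors <= 0))
    stop("size factors must be finite and positive")
  sweep(counts, 2, sizeFactors, "/")
}

#' Fragments per kilobase per million mapped reads
#'
#' \deqn{\mathrm{FPKM}_{ij} = 10^9 \, k_{ij} / (L_i N_j)} with gene length
#' `L_i` in bp and `N_j` the column (library) total of raw counts.
#'
#' @param counts gene x sample matrix of raw counts.
#' @param lengths positive gene lengths in bp.
#' @return matrix of FPKM values.
#' @export
computeFPKM <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) stop("need one length per gene")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive")
  N <- colSums(counts)
  if (any(N == 0)) stop("zero column sum: FPKM undefined for empty library")
  1e9 * sweep(sweep(counts, 1, lengths, "/"), 2, N, "/")
}
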