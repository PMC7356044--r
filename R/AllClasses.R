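#' @import methods
#' @importFrom stats median rnorm rpois rnbinom runif var cor pchisq pnorm
#'   dpois dnbinom setNames
#' @importFrom utils read.csv read.delim write.csv write.table
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<-
#' @importFrom BiocGenerics counts
NULL

GENOTYPES  <- c("T29", "T13")   # high-NUE, low-NUE
CONDITIONS <- c("C", "T")       # control, N-deficit
CELLS      <- c("T29_C", "T29_T", "T13_C", "T13_T")
CONTRASTS  <- c("R29", "R13", "GC", "GT")

#' Container for a genotype x condition RNA-seq count experiment
#'
#' `NueExperiment` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `counts` assay of non-negative integers and column metadata assigning every
#' sample to one genotype (`"T29"` high-NUE or `"T13"` low-NUE), one condition
#' (`"C"` control or `"T"` nitrogen deficit) and a replicate index. Optional
#' row metadata carries gene lengths (bp) and, for simulated data, the planted
#' expression archetype used for recovery scoring.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @export
setClass("NueExperiment", contains = "SummarizedExperiment")

setValidity("NueExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    k <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(k)) || any(k < 0))
      msg <- c(msg, "counts must be finite and non-negative")
    else if (any(k != round(k)))
      msg <- c(msg, "counts must be integral")
  }
  cd <- SummarizedExperiment::colData(object)
  for (col in c("genotype", "condition", "replicate"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("genotype" %in% colnames(cd) && !all(cd$genotype %in% GENOTYPES))
    msg <- c(msg, "genotype must be one of 'T29', 'T13'")
  if ("condition" %in% colnames(cd) && !all(cd$condition %in% CONDITIONS))
    msg <- c(msg, "condition must be one of 'C', 'T'")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct a NueExperiment
#'
#' @param counts gene x sample matrix of non-negative integer read counts with
#'   row (gene) and column (sample) names.
#' @param genotype character vector, one of `"T29"`/`"T13"` per sample.
#' @param condition character vector, one of `"C"`/`"T"` per sample.
#' @param replicate integer replicate index per sample; defaults to the running
#'   index within each genotype x condition cell.
#' @param geneLengths optional numeric vector of gene lengths in bp.
#' @param archetype optional character vector of planted archetypes (simulated
#'   data only).
#' @param metadata list of experiment-level metadata.
#' @return A [NueExperiment-class] object.
#' @examples
#' k <- matrix(rpois(40, 50), 10, 4,
#'             dimnames = list(paste0("g", 1:10),
#'                             c("T29_C_r1", "T29_T_r1", "T13_C_r1", "T13_T_r1")))
#' NueExperiment(k, genotype = c("T29", "T29", "T13", "T13"),
#'               condition = c("C", "T", "C", "T"))
#' @export
NueExperiment <- function(counts, genotype, condition, replicate = NULL,
                          geneLengths = NULL, archetype = NULL,
                          metadata = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  if (is.null(replicate)) {
    cell <- paste(genotype, condition, sep = "_")
    replicate <- stats::ave(seq_along(cell), cell, FUN = seq_along)
  }
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(genotype, "_", condition, "_r", replicate)
  cd <- DataFrame(genotype = as.character(genotype),
                  condition = as.character(condition),
                  replicate = as.integer(replicate),
                  row.names = colnames(counts))
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(geneLengths)) rd$length <- as.numeric(geneLengths)
  if (!is.null(archetype))  rd$archetype <- as.character(archetype)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd, metadata = metadata)
  new("NueExperiment", se)
}

#' @describeIn NueExperiment the raw count matrix.
#' @param object,x a `NueExperiment`.
#' @export
setMethod("counts", "NueExperiment", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))
#' @describeIn NueExperiment per-sample genotype labels.
#' @export
setMethod("genotype", "NueExperiment", function(x) colData(x)$genotype)

#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @describeIn NueExperiment per-sample condition labels.
#' @export
setMethod("condition", "NueExperiment", function(x) colData(x)$condition)

#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))
#' @describeIn NueExperiment gene lengths in bp (or NULL).
#' @export
setMethod("geneLengths", "NueExperiment", function(x) rowData(x)$length)

#' @export
setGeneric("archetypes", function(x) standardGeneric("archetypes"))
#' @describeIn NueExperiment planted archetype per gene (simulated data; NULL
#'   otherwise).
#' @export
setMethod("archetypes", "NueExperiment", function(x) rowData(x)$archetype)

#' @export
setGeneric("designCells", function(x) standardGeneric("designCells"))
#' @describeIn NueExperiment the genotype x condition cell of every sample,
#'   e.g. `"T13_T"`.
#' @export
setMethod("designCells", "NueExperiment", function(x)
  paste(genotype(x), condition(x), sep = "_"))

setMethod("show", "NueExperiment", function(object) {
  callNextMethod()
  tab <- table(designCells(object))
  cat("design cells:", paste(sprintf("%s(n=%d)", names(tab), tab), collapse = " "), "\n")
})

#' Catalog of the four canonical contrasts
#'
#' Holds one differential-expression table per contrast, with a fixed
#' orientation:
#' \describe{
#'   \item{R29}{T29_T vs T29_C — treatment response of the high-NUE genotype.}
#'   \item{R13}{T13_T vs T13_C — treatment response of the low-NUE genotype.}
#'   \item{GC}{T29_C vs T13_C — genotype difference under control N.}
#'   \item{GT}{T29_T vs T13_T — genotype difference under N deficit.}
#' }
#' "up" always means higher in the first-named (numerator) group.
#'
#' @slot results named list of per-contrast `DataFrame`s (see [runContrast()]).
#' @slot alpha the FDR threshold used for DEG calls.
#' @slot sizeFactors the shared per-sample size factors.
#' @export
setClass("ContrastCatalog",
         representation(results = "list", alpha = "numeric",
                        sizeFactors = "numeric"))

setValidity("ContrastCatalog", function(object) {
  msg <- character()
  if (!identical(sort(names(object@results)), sort(CONTRASTS)))
    msg <- c(msg, "results must be named R29, R13, GC, GT")
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be a single value in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("deResult", function(x, contrast) standardGeneric("deResult"))
#' @describeIn ContrastCatalog the DE table of one contrast.
#' @param x a `ContrastCatalog`.
#' @param contrast one of `"R29"`, `"R13"`, `"GC"`, `"GT"`.
#' @export
setMethod("deResult", "ContrastCatalog", function(x, contrast) {
  contrast <- match.arg(contrast, CONTRASTS)
  x@results[[contrast]]
})

#' @export
setGeneric("degIDs", function(x, contrast, direction = "any")
  standardGeneric("degIDs"))
#' @describeIn ContrastCatalog gene ids called differentially expressed in one
#'   contrast, optionally restricted to one direction.
#' @param direction `"any"`, `"up"` or `"down"`.
#' @export
setMethod("degIDs", "ContrastCatalog", function(x, contrast, direction = "any") {
  direction <- match.arg(direction, c("any", "up", "down"))
  res <- deResult(x, contrast)
  keep <- res$isDEG
  if (direction != "any") keep <- keep & res$direction == direction
  rownames(res)[keep]
})

#' @export
setGeneric("fdrAlpha", function(x) standardGeneric("fdrAlpha"))
#' @describeIn ContrastCatalog the FDR threshold used for calls.
#' @export
setMethod("fdrAlpha", "ContrastCatalog", function(x) x@alpha)

setMethod("show", "ContrastCatalog", function(object) {
  cat(sprintf("ContrastCatalog (padj < %g)\n", object@alpha))
  for (cn in CONTRASTS) {
    res <- object@results[[cn]]
    cat(sprintf("  %-3s %-16s up %4d  down %4d  of %d genes\n", cn,
                metadata(res)$contrast,
                sum(res$isDEG & res$direction == "up"),
                sum(res$isDEG & res$direction == "down"), nrow(res)))
  }
})
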