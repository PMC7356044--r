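#' Build the four canonical contrasts
#'
#' Runs [runContrast()] four times with a fixed orientation (size factors are
#' estimated once on the full matrix and shared):
#' R29 = T29_T vs T29_C, R13 = T13_T vs T13_C, GC = T29_C vs T13_C,
#' GT = T29_T vs T13_T. "up" means higher in the first-named group, so "up"
#' in GC/GT means higher in the high-NUE genotype.
#'
#' @param x a [NueExperiment-class] containing all four design cells.
#' @param alpha FDR threshold for DEG calls.
#' @param ... further arguments passed to [runContrast()].
#' @return a [ContrastCatalog-class].
#' @export
buildContrastCatalog <- function(x, alpha = 0.05, ...) {
  present <- unique(designCells(x))
  missing <- setdiff(CELLS, present)
  if (length(missing))
    stop("missing design cell(s): ", paste(missing, collapse = ", "))
  sf <- medianOfRatios(counts(x))
  spec <- list(R29 = c(A = "T29_C", B = "T29_T"),
               R13 = c(A = "T13_C", B = "T13_T"),
               GC  = c(A = "T13_C", B = "T29_C"),
               GT  = c(A = "T13_T", B = "T29_T"))
  results <- lapply(spec, function(s)
    runContrast(x, groupA = s[["A"]], groupB = s[["B"]], alpha = alpha,
                sizeFactors = sf, ...))
  new("ContrastCatalog", results = results, alpha = alpha, sizeFactors = sf)
}

#' Genotype-unique and common responder sets
#'
#' The focal genotype's unique responders are the DEGs of its
#' treatment-vs-control contrast that are not DEGs in the other genotype's
#' response contrast, partitioned by their direction in the focal contrast.
#'
#' @param catalog a [ContrastCatalog-class].
#' @param focal `"T13"` (default, the low-NUE genotype) or `"T29"`.
#' @return list with `focal`, `uniqueUp`, `uniqueDown`, `unique` (their
#'   union), `commonResponse` (DEGs in both response contrasts),
#'   `genotypeCommon` (GC-DEGs intersected with GT-DEGs) and `unionAll`
#'   (DEGs in any of the four contrasts).
#' @export
uniqueResponders <- function(catalog, focal = c("T13", "T29")) {
  focal <- match.arg(focal)
  focalContrast <- if (focal == "T13") "R13" else "R29"
  otherContrast <- if (focal == "T13") "R29" else "R13"
  degF <- degIDs(catalog, focalContrast)
  degO <- degIDs(catalog, otherContrast)
  uniq <- setdiff(degF, degO)
  list(focal = focal,
       uniqueUp = intersect(uniq, degIDs(catalog, focalContrast, "up")),
       uniqueDown = intersect(uniq, degIDs(catalog, focalContrast, "down")),
       unique = uniq,
       commonResponse = intersect(degF, degO),
       genotypeCommon = intersect(degIDs(catalog, "GC"), degIDs(catalog, "GT")),
       unionAll = Reduce(union, lapply(CONTRASTS, degIDs, x = catalog)))
}

#' Pairwise overlap counts of the four DEG sets
#'
#' @param catalog a [ContrastCatalog-class].
#' @return list with `pairs`, a data.frame of `|A|`, `|B|`, `|A intersect B|`
#'   and `|A union B|` for each contrast pair, and `unionAll`, the size of the
#'   union over all four DEG sets.
#' @export
vennCounts <- function(catalog) {
  sets <- lapply(CONTRASTS, degIDs, x = catalog)
  names(sets) <- CONTRASTS
  combs <- utils::combn(CONTRASTS, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    data.frame(contrastA = a, contrastB = b,
               nA = length(sets[[a]]), nB = length(sets[[b]]),
               overlap = length(intersect(sets[[a]], sets[[b]])),
               union = length(union(sets[[a]], sets[[b]])),
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, unionAll = length(Reduce(union, sets)))
}
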