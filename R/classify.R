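PATTERN_LABELS <- c("frontloaded", "stress_tolerance", "relatively_upregulated",
                    "opposite", "unclassified")

#' Cross-genotype expression ratios per gene
#'
#' For the focal (responding) genotype F and the other (tolerant) genotype O,
#' using normalized cell means taken from the catalog's response contrasts:
#' `rC = (O_C + c)/(F_C + c)` and `rT = (O_T + c)/(F_T + c)` compare the
#' tolerant genotype to the focal one within each condition, and
#' `rhoFocal = ln((F_C + c)/(F_T + c))`, `rhoOther = ln((O_C + c)/(O_T + c))`
#' are the within-genotype control-over-treatment log ratios used for the
#' direction-consistency comparison. With the default focal `"T13"`, `rC` is
#' the classic T29_C / T13_C ratio.
#'
#' @param catalog a [ContrastCatalog-class].
#' @param focal `"T13"` or `"T29"`.
#' @param pseudocount added to every mean; keeps ratios finite and positive.
#' @return `DataFrame` with columns `rC`, `rT`, `rhoFocal`, `rhoOther` over the
#'   catalog's gene universe.
#' @export
computeRatios <- function(catalog, focal = c("T13", "T29"), pseudocount = 1) {
  focal <- match.arg(focal)
  r29 <- deResult(catalog, "R29"); r13 <- deResult(catalog, "R13")
  cellMean <- list(T29_C = r29$meanA, T29_T = r29$meanB,
                   T13_C = r13$meanA, T13_T = r13$meanB)
  other <- setdiff(GENOTYPES, focal)
  cm <- function(g, cond) cellMean[[paste(g, cond, sep = "_")]] + pseudocount
  DataFrame(rC = cm(other, "C") / cm(focal, "C"),
            rT = cm(other, "T") / cm(focal, "T"),
            rhoFocal = log(cm(focal, "C") / cm(focal, "T")),
            rhoOther = log(cm(other, "C") / cm(other, "T")),
            row.names = rownames(r13))
}

# Vectorized rule engine shared by classifyGene and classifyPatterns.
# status: "unique" (significant only in the focal response contrast) or
# "dual_discordant"/"dual_concordant" (significant in both).
classifyCore <- function(rC, rT, direction, status, epsilon = 0) {
  n <- length(rC)
  lab <- rep("unclassified", n)
  rule <- rep("R4", n)
  sC <- ifelse(abs(log(rC)) < epsilon, 0, sign(log(rC)))
  sT <- ifelse(abs(log(rT)) < epsilon, 0, sign(log(rT)))
  tie <- epsilon > 0 & (abs(log(rC)) < epsilon | abs(log(rT)) < epsilon)

  opp <- status == "dual_discordant"
  lab[opp] <- "opposite"; rule[opp] <- "R0"
  conc <- status == "dual_concordant"
  rule[conc] <- "dual-concordant"

  uniq <- status == "unique" & !tie
  r1 <- uniq & direction == "up" & sC > 0 & sT < 0
  lab[r1] <- "frontloaded"; rule[r1] <- "R1"
  r2 <- uniq & !r1 & direction == "down" & sT > 0
  lab[r2] <- "relatively_upregulated"; rule[r2] <- "R2"
  r3 <- uniq & !r1 & !r2 &
    ((direction == "up" & sC <= 0) |
       (direction == "down" & sC <= 0 & sT <= 0))
  lab[r3] <- "stress_tolerance"; rule[r3] <- "R3"
  rule[status == "unique" & tie] <- "tie"
  list(label = lab, rule = rule)
}

#' Classify one responder gene from its expression ratios
#'
#' Rule set (strict inequalities at ratio 1; `epsilon` defines an optional
#' dead band on `|ln r|` inside which comparisons are ties and the gene is
#' left unclassified):
#' \describe{
#'   \item{R0 opposite}{significant in both response contrasts with opposite
#'     directions.}
#'   \item{R1 frontloaded}{unique responder, `direction == "up"`, `rC > 1` and
#'     `rT < 1`: the tolerant genotype is constitutively higher and muted
#'     under stress.}
#'   \item{R2 relatively_upregulated}{unique responder, `direction == "down"`
#'     and `rT > 1`: the tolerant genotype sits relatively higher under
#'     stress while the focal genotype drops.}
#'   \item{R3 stress_tolerance}{unique responder with `rC <= 1` (up case), or
#'     `rC <= 1` and `rT <= 1` (down case): equal-or-lower constitutive level
#'     and a muted response.}
#'   \item{R4}{anything else is unclassified; dual responders with concordant
#'     directions are also unclassified.}
#' }
#'
#' @param rC,rT positive cross-genotype ratios (see [computeRatios()]).
#' @param direction focal response direction, `"up"` or `"down"`.
#' @param status `"unique"`, `"dual_discordant"` or `"dual_concordant"`.
#' @param epsilon dead band on `|ln r|` (default 0: strict).
#' @return list with `label` and the `rule` that fired.
#' @examples
#' classifyGene(2.0, 0.5, "up", "unique")$label     # frontloaded
#' classifyGene(0.9, 1.5, "down", "unique")$label   # relatively_upregulated
#' classifyGene(0.8, 0.9, "up", "unique")$label     # stress_tolerance
#' @export
classifyGene <- function(rC, rT, direction, status, epsilon = 0) {
  if (any(rC <= 0) || any(rT <= 0)) stop("ratios must be positive")
  if (!all(direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  if (!all(status %in% c("unique", "dual_discordant", "dual_concordant")))
    stop("gene is not a responder (status must be unique or dual)")
  out <- classifyCore(rC, rT, direction, status, epsilon)
  if (length(rC) == 1) list(label = out$label, rule = out$rule) else out
}

#' Classify every genotype-unique and dual responder
#'
#' Applies the [classifyGene()] rules to each unique responder of the focal
#' genotype and to each dual responder (significant in both response
#' contrasts), using ratios from [computeRatios()].
#'
#' @param catalog a [ContrastCatalog-class].
#' @param focal `"T13"` or `"T29"`; the mirrored mode swaps genotype roles in
#'   every ratio.
#' @param epsilon dead band on `|ln r|`.
#' @param pseudocount passed to [computeRatios()].
#' @return a `DataFrame` (the pattern table) with one row per responder:
#'   `label`, `direction`, `rC`, `rT`, `rhoFocal`, `rhoOther`, `status`,
#'   `rule`; `metadata()` holds `focal`, `epsilon` and per-label counts.
#' @export
classifyPatterns <- function(catalog, focal = c("T13", "T29"), epsilon = 0,
                             pseudocount = 1) {
  focal <- match.arg(focal)
  focalContrast <- if (focal == "T13") "R13" else "R29"
  otherContrast <- if (focal == "T13") "R29" else "R13"
  resF <- deResult(catalog, focalContrast)
  resO <- deResult(catalog, otherContrast)
  degF <- rownames(resF)[resF$isDEG]
  degO <- rownames(resO)[resO$isDEG]
  responders <- degF  # dual responders are a subset of the focal DEG set
  ratios <- computeRatios(catalog, focal, pseudocount)[responders, , drop = FALSE]
  dirF <- resF[responders, "direction"]
  dual <- responders %in% degO
  discordant <- dual & dirF != resO[responders, "direction"]
  status <- ifelse(!dual, "unique",
                   ifelse(discordant, "dual_discordant", "dual_concordant"))
  out <- classifyCore(ratios$rC, ratios$rT, dirF, status, epsilon)
  pt <- DataFrame(label = out$label, direction = dirF,
                  rC = ratios$rC, rT = ratios$rT,
                  rhoFocal = ratios$rhoFocal, rhoOther = ratios$rhoOther,
                  status = status, rule = out$rule, row.names = responders)
  counts <- vapply(PATTERN_LABELS, function(l) sum(pt$label == l), integer(1))
  metadata(pt) <- list(focal = focal, epsilon = epsilon,
                       labelCounts = as.list(counts),
                       nUnique = sum(!dual), nDual = sum(dual))
  pt
}

#' One-degree-of-freedom direction-consistency chi-squared test
#'
#' Goodness-of-fit of an observed two-cell split (genes whose absolute
#' expression change is greater in the focal genotype vs greater in the other)
#' against a 50:50 null: `chi2 = sum (O - E)^2 / E` with `E = total/2`, one
#' degree of freedom.
#'
#' @param nFocalGreater,nOtherGreater non-negative integer counts.
#' @return list with `statistic`, `p.value`, `observed` and `expected`.
#' @examples
#' chiSquareDirection(70, 30)   # chi2 = 16
#' @export
chiSquareDirection <- function(nFocalGreater, nOtherGreater) {
  o <- c(nFocalGreater, nOtherGreater)
  if (any(o < 0) || any(o != round(o))) stop("counts must be non-negative integers")
  tot <- sum(o)
  if (tot == 0) stop("zero total: the test is undefined")
  e <- tot / 2
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = o, expected = c(e, e))
}

#' Direction-consistency test over the unique-responder set
#'
#' Splits the unique responders of a pattern table by whether the magnitude of
#' their within-genotype log change is greater in the focal genotype
#' (`|rhoFocal| > |rhoOther|`) or in the other, and applies
#' [chiSquareDirection()] (exact ties are dropped).
#'
#' @param patternTable output of [classifyPatterns()].
#' @return the [chiSquareDirection()] result, plus `nFocalGreater`,
#'   `nOtherGreater` and `nTies`.
#' @export
directionConsistency <- function(patternTable) {
  u <- patternTable[patternTable$status == "unique", , drop = FALSE]
  nF <- sum(abs(u$rhoFocal) > abs(u$rhoOther))
  nO <- sum(abs(u$rhoFocal) < abs(u$rhoOther))
  res <- chiSquareDirection(nF, nO)
  c(res, list(nFocalGreater = nF, nOtherGreater = nO,
              nTies = nrow(u) - nF - nO))
}
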