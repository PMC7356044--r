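# 32-bit polynomial rolling hash over a string; cheap reproducible config
# fingerprint (not cryptographic).
stringHash32 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

nuePipelineDefaults <- function() list(
  nGenes = 5000, nReplicates = 3,
  archetypeCounts = list(frontloaded = 100, stress_tolerance_up = 10,
                         stress_tolerance_down = 10,
                         relatively_upregulated = 100, opposite = 4,
                         constitutive = 0),
  baselineLogMean = 5, baselineLogSd = 1.5, dispersion = 0.05,
  responseFold = 4, constitutiveFold = 3, librarySizeFactors = NULL,
  focalGenotype = "T13", seed = 1,
  alpha = 0.05, epsilon = 0, pseudocount = 1,
  countsFile = NULL, samplesFile = NULL, lengthsFile = NULL, truthFile = NULL,
  skipQpcr = FALSE, qpcrPanelSize = 15, qpcrCtSd = 0.2)

#' Score classification recovery against the planted truth
#'
#' Maps planted archetypes onto pattern labels (`stress_tolerance_up/_down`
#' both map to `stress_tolerance`; `constitutive` and `null` map to no class)
#' and computes per-class precision `TP/(TP+FP)` and recall `TP/(TP+FN)`.
#' Genes absent from the pattern table count as unclassified.
#'
#' @param patternTable output of [classifyPatterns()].
#' @param truth data.frame with columns `gene` and `archetype` (or a
#'   [NueExperiment-class] carrying archetypes).
#' @return data.frame with one row per class: `tp`, `fp`, `fn`, `precision`,
#'   `recall` (precision is `NA` when a class was never predicted).
#' @export
scoreRecovery <- function(patternTable, truth) {
  if (is(truth, "NueExperiment"))
    truth <- data.frame(gene = rownames(truth), archetype = archetypes(truth),
                        stringsAsFactors = FALSE)
  if (is.null(truth$gene) || is.null(truth$archetype))
    stop("truth needs 'gene' and 'archetype'")
  if (nrow(patternTable) > 0 &&
      !length(intersect(rownames(patternTable), truth$gene)))
    stop("pattern table and truth table have disjoint gene universes")
  map <- c(frontloaded = "frontloaded",
           stress_tolerance_up = "stress_tolerance",
           stress_tolerance_down = "stress_tolerance",
           relatively_upregulated = "relatively_upregulated",
           opposite = "opposite", constitutive = "none", null = "none")
  truthLabel <- unname(map[truth$archetype])
  predicted <- rep("unclassified", nrow(truth))
  hit <- match(truth$gene, rownames(patternTable))
  predicted[!is.na(hit)] <- patternTable$label[hit[!is.na(hit)]]
  classes <- c("frontloaded", "stress_tolerance", "relatively_upregulated",
               "opposite")
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truthLabel == cl)
    fp <- sum(predicted == cl & truthLabel != cl)
    fn <- sum(predicted != cl & truthLabel == cl)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

qpcrPanelLog2FC <- function(se) {
  cfg <- metadata(se)$simConfig
  lf <- log2(cfg$responseFold)
  arch <- archetypes(se)
  fc <- rep(NA_real_, nrow(se))
  fc[arch %in% c("frontloaded", "stress_tolerance_up", "opposite")] <- lf
  fc[arch %in% c("stress_tolerance_down", "relatively_upregulated")] <- -lf
  names(fc) <- rownames(se)
  fc[!is.na(fc)]
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) the count experiment, build the four-contrast catalog,
#' derive unique responders and Venn counts, classify expression patterns, run
#' the direction-consistency test, optionally simulate a qPCR panel from the
#' planted fold changes and check concordance, and score recovery against the
#' truth table. All randomness flows from `config$seed`; two runs with the
#' same config produce byte-identical summaries.
#'
#' @param config named list overriding the defaults (see
#'   `nueseq:::nuePipelineDefaults()`); unknown keys are an error. When
#'   `countsFile`/`samplesFile` are set the dataset is read instead of
#'   simulated.
#' @param outDir optional directory: writes counts/sample/truth tables, one
#'   DE table per contrast, the pattern table and `summary.json`.
#' @param configFile optional YAML file merged over the defaults (explicit
#'   `config` entries win).
#' @return invisibly, a list with `summary` (the run summary), `se`,
#'   `catalog`, `responders`, `patterns`, `recovery` and `concordance`.
#' @export
runNuePipeline <- function(config = list(), outDir = NULL, configFile = NULL) {
  cfg <- nuePipelineDefaults()
  if (!is.null(configFile)) {
    fileCfg <- yaml::read_yaml(configFile)
    cfg[names(fileCfg)] <- fileCfg
  }
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  hash <- stringHash32(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                                        digits = NA))

  set.seed(cfg$seed)
  if (!is.null(cfg$countsFile)) {
    message("[data] reading counts from ", cfg$countsFile)
    se <- readNueDataset(cfg$countsFile, cfg$samplesFile, cfg$lengthsFile,
                         cfg$truthFile)
  } else {
    message("[data] simulating ", cfg$nGenes, " genes, seed ", cfg$seed)
    se <- simulateNueCounts(
      nGenes = cfg$nGenes, nReplicates = cfg$nReplicates,
      archetypeCounts = unlist(cfg$archetypeCounts),
      baselineLogMean = cfg$baselineLogMean,
      baselineLogSd = cfg$baselineLogSd, dispersion = cfg$dispersion,
      responseFold = cfg$responseFold, constitutiveFold = cfg$constitutiveFold,
      librarySizeFactors = cfg$librarySizeFactors,
      focalGenotype = cfg$focalGenotype, seed = cfg$seed)
  }

  message("[de] building the four-contrast catalog")
  catalog <- buildContrastCatalog(se, alpha = cfg$alpha,
                                  pseudocount = cfg$pseudocount)
  focal <- cfg$focalGenotype
  responders <- uniqueResponders(catalog, focal)
  venn <- vennCounts(catalog)
  message("[classify] ", length(responders$unique), " unique responders (",
          focal, ")")
  patterns <- classifyPatterns(catalog, focal, epsilon = cfg$epsilon,
                               pseudocount = cfg$pseudocount)
  chi <- tryCatch(directionConsistency(patterns), error = function(e) NULL)

  concordance <- NULL
  if (!isTRUE(cfg$skipQpcr) && !is.null(archetypes(se)) &&
      !is.null(metadata(se)$simConfig)) {
    trueFC <- qpcrPanelLog2FC(se)
    if (length(trueFC)) {
      panel <- sample(names(trueFC), min(cfg$qpcrPanelSize, length(trueFC)))
      message("[qc] qPCR concordance on a ", length(panel), "-gene panel")
      qpcr <- simulateQpcr(trueFC[panel], ctNoiseSd = cfg$qpcrCtSd)
      focalContrast <- if (focal == "T13") "R13" else "R29"
      concordance <- qpcrConcordance(ddctTable(qpcr),
                                     deResult(catalog, focalContrast))
    }
  }

  recovery <- NULL
  if (!is.null(archetypes(se)))
    recovery <- scoreRecovery(patterns, se)

  degCount <- function(cn, dir) length(degIDs(catalog, cn, dir))
  summary <- list(
    seed = cfg$seed, configHash = hash, alpha = cfg$alpha,
    focalGenotype = focal, nGenes = nrow(se), nSamples = ncol(se),
    contrasts = lapply(stats::setNames(CONTRASTS, CONTRASTS), function(cn)
      list(up = degCount(cn, "up"), down = degCount(cn, "down"),
           total = degCount(cn, "any"))),
    uniqueResponders = list(focal = focal,
                            up = length(responders$uniqueUp),
                            down = length(responders$uniqueDown),
                            total = length(responders$unique),
                            commonResponse = length(responders$commonResponse),
                            genotypeCommon = length(responders$genotypeCommon),
                            unionAll = length(responders$unionAll)),
    venn = list(pairs = venn$pairs, unionAll = venn$unionAll),
    patternCounts = metadata(patterns)$labelCounts,
    chiSquare = if (!is.null(chi))
      list(statistic = chi$statistic, p = chi$p.value,
           focalGreater = chi$nFocalGreater, otherGreater = chi$nOtherGreater),
    qpcrConcordance = if (!is.null(concordance))
      list(fraction = concordance$fraction,
           nGenes = nrow(concordance$table)),
    recovery = if (!is.null(recovery))
      lapply(split(recovery, recovery$class), function(d)
        list(precision = d$precision, recall = d$recall, tp = d$tp,
             fp = d$fp, fn = d$fn)))
  summary <- summary[!vapply(summary, is.null, logical(1))]

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeNueDataset(se, outDir)
    for (cn in CONTRASTS)
      writeDETable(deResult(catalog, cn),
                   file.path(outDir, paste0("de_", cn, ".tsv")))
    writeCommented(as.data.frame(patterns),
                   file.path(outDir, "patterns.tsv"),
                   comments = c(focal = focal, epsilon = cfg$epsilon),
                   rowColName = "gene")
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(summary = summary, se = se, catalog = catalog,
                 responders = responders, patterns = patterns,
                 recovery = recovery, concordance = concordance))
}
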