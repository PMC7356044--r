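writeCommented <- function(df, file, comments = character(), sep = "\t",
                           rowColName = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(comments))
    writeLines(sprintf("# %s=%s", nm, comments[[nm]]), con)
  if (!is.null(rowColName)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                rowColName),
                as.data.frame(df))
    rownames(df) <- NULL
  }
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write a simulated or imported dataset as plain-text files
#'
#' Writes `counts.tsv` (first column `gene`, one column per sample named
#' `<genotype>_<condition>_r<k>`), `samples.csv`
#' (sample,genotype,condition,replicate), `gene_lengths.tsv` and, when the
#' object carries planted archetypes, `truth.tsv` (gene,archetype). Header
#' comment lines (`# key=value`) record the simulation seed when available.
#'
#' @param x a [NueExperiment-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeNueDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- metadata(x)$simConfig
  comments <- if (!is.null(cfg)) c(seed = cfg$seed) else character()
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.csv"),
             lengths = file.path(dir, "gene_lengths.tsv"))
  writeCommented(counts(x), paths["counts"], comments, rowColName = "gene")
  write.csv(as.data.frame(colData(x))[c("genotype", "condition", "replicate")] |>
              (\(d) cbind(sample = rownames(d), d))(),
            paths["samples"], row.names = FALSE, quote = FALSE)
  if (!is.null(geneLengths(x)))
    writeCommented(data.frame(length_bp = geneLengths(x),
                              row.names = rownames(x)),
                   paths["lengths"], comments, rowColName = "gene")
  if (!is.null(archetypes(x))) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    writeCommented(data.frame(archetype = archetypes(x),
                              row.names = rownames(x)),
                   paths["truth"], comments, rowColName = "gene")
  }
  invisible(paths)
}

#' Read a dataset from counts TSV + sample sheet CSV
#'
#' @param countsFile TSV whose first column is the gene id; `#` lines are
#'   skipped.
#' @param samplesFile CSV with columns sample, genotype, condition, replicate.
#' @param lengthsFile optional TSV with columns gene, length_bp.
#' @param truthFile optional TSV with columns gene, archetype.
#' @return a [NueExperiment-class].
#' @export
readNueDataset <- function(countsFile, samplesFile, lengthsFile = NULL,
                           truthFile = NULL) {
  kdf <- read.delim(countsFile, comment.char = "#", check.names = FALSE)
  k <- as.matrix(kdf[, -1, drop = FALSE])
  rownames(k) <- kdf[[1]]
  ss <- read.csv(samplesFile, stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "condition", "replicate")
  if (!all(need %in% colnames(ss)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (!setequal(ss$sample, colnames(k)))
    stop("sample sheet and count matrix disagree on sample ids")
  ss <- ss[match(colnames(k), ss$sample), ]
  lengths <- archetype <- NULL
  if (!is.null(lengthsFile)) {
    ld <- read.delim(lengthsFile, comment.char = "#")
    lengths <- ld[[2]][match(rownames(k), ld[[1]])]
  }
  if (!is.null(truthFile)) {
    td <- read.delim(truthFile, comment.char = "#")
    archetype <- td[[2]][match(rownames(k), td[[1]])]
  }
  NueExperiment(k, genotype = ss$genotype, condition = ss$condition,
                replicate = ss$replicate, geneLengths = lengths,
                archetype = archetype)
}

#' Write one contrast's DE table as TSV
#'
#' @param res a DE `DataFrame` from [runContrast()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeDETable <- function(res, file) {
  md <- metadata(res)
  writeCommented(as.data.frame(res), file,
                 comments = c(contrast = md$contrast, alpha = md$alpha),
                 rowColName = "gene")
  invisible(file)
}
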