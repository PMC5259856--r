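#' Write a FractionExperiment as plain TSV files
#'
#' Emits the expression matrix (first column \code{probe_id}, header =
#' sample ids), the sample sheet (\code{sample_id}, \code{sample_type},
#' \code{replicate}) and the probe annotation (\code{probe_id},
#' \code{gene_symbol}, \code{is_negative_control}).
#'
#' @param object a \linkS4class{FractionExperiment}.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
writeFractionExperiment <- function(object, dir) {
  stopifnot(is(object, "FractionExperiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("expression_matrix.tsv", "sample_sheet.tsv",
                            "probe_annotation.tsv"))
  utils::write.table(
    data.frame(probe_id = rownames(object), intensity(object),
               check.names = FALSE),
    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(object),
               sample_type = sampleType(object),
               replicate = replicateIndex(object)),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = rownames(object),
               gene_symbol = geneSymbols(object),
               is_negative_control = isNegativeControl(object)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a FractionExperiment from the package's TSV schema
#'
#' @param matrixPath expression TSV (first column probe id, header sample
#'   ids).
#' @param sampleSheetPath TSV with sample_id, sample_type, replicate.
#' @param annotationPath TSV with probe_id, gene_symbol,
#'   is_negative_control.
#' @return a \linkS4class{FractionExperiment}.
#' @export
readFractionExperiment <- function(matrixPath, sampleSheetPath,
                                   annotationPath) {
  m <- utils::read.delim(matrixPath, check.names = FALSE,
                         stringsAsFactors = FALSE)
  values <- as.matrix(m[, -1, drop = FALSE])
  rownames(values) <- m[[1]]
  ss <- utils::read.delim(sampleSheetPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "sample_type", "replicate")
  if (!all(need %in% colnames(ss)))
    stop("sample sheet must contain: ", paste(need, collapse = ", "))
  miss <- setdiff(colnames(values), ss$sample_id)
  if (length(miss))
    stop("samples missing from the sample sheet: ",
         paste(miss, collapse = ", "))
  ss <- ss[match(colnames(values), ss$sample_id), ]
  pa <- utils::read.delim(annotationPath, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol", "is_negative_control") %in%
           colnames(pa)))
    stop("probe annotation must contain probe_id, gene_symbol, ",
         "is_negative_control")
  miss <- setdiff(rownames(values), pa$probe_id)
  if (length(miss))
    stop(length(miss), " probes lack annotation (first: ", miss[1], ")")
  pa <- pa[match(rownames(values), pa$probe_id), ]
  sym <- as.character(pa$gene_symbol)
  sym[sym == ""] <- NA_character_
  FractionExperiment(values, sampleType = ss$sample_type,
                     replicate = ss$replicate, geneSymbol = sym,
                     isNegativeControl = as.logical(pa$is_negative_control))
}

#' Read and write gene sets in GMT format
#'
#' One term per line: term id, description, then tab-separated gene
#' symbols. Symbols are case-normalized on read.
#'
#' @param path file path.
#' @return \code{readGMT}: an \linkS4class{AnnotationSets}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(normalizeSymbols(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  descs <- stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  new("AnnotationSets", sets = sets, descriptions = descs)
}

#' @rdname readGMT
#' @param annotation an \linkS4class{AnnotationSets} to write.
#' @export
writeGMT <- function(annotation, path) {
  stopifnot(is(annotation, "AnnotationSets"))
  lines <- vapply(names(geneSets(annotation)), function(nm)
    paste(c(nm, termDescriptions(annotation)[[nm]],
            geneSets(annotation)[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a mass-spectrometry protein table
#'
#' TSV with columns protein_id, gene_symbol, n_peptides, coverage_pct (a
#' \code{species} column is optional).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readMSTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "gene_symbol", "n_peptides", "coverage_pct")
  if (!all(need %in% colnames(df)))
    stop("MS table must contain: ", paste(need, collapse = ", "))
  df
}

#' Read an ortholog map (species-B symbol to species-A symbol)
#'
#' @param path TSV with columns symbol_species_B, symbol_species_A.
#' @return data.frame.
#' @export
readOrthologMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol_species_B", "symbol_species_A") %in% colnames(df)))
    stop("ortholog map must contain symbol_species_B and symbol_species_A")
  df
}

#' Read the expression table of a GEO series-matrix file
#'
#' Parses the tab-separated block between the
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end}
#' sentinels of a GEO series-matrix text file (e.g. accession GSE84972)
#' and returns the probe x sample value matrix; sample accessions come
#' from the table header. Sample metadata lines are returned alongside so
#' a sample sheet can be assembled.
#'
#' @param path path to the (uncompressed) series-matrix text file.
#' @return list with \code{values} (numeric matrix, probe ids as
#'   rownames) and \code{sampleTitles} (named character vector from the
#'   \code{!Sample_title} line, if present).
#' @export
readSeriesMatrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no series-matrix table found in ", path)
  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  titles <- grep("^!Sample_title", lines, value = TRUE)
  sampleTitles <- if (length(titles)) {
    tt <- strsplit(titles[1], "\t", fixed = TRUE)[[1]][-1]
    stats::setNames(gsub('^"|"$', "", tt), colnames(values))
  } else NULL
  list(values = values, sampleTitles = sampleTitles)
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns fraction, target_ct, spike_ct.
#' @return data.frame.
#' @export
readQpcrTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("fraction", "target_ct", "spike_ct") %in% colnames(df)))
    stop("qPCR table must contain fraction, target_ct, spike_ct")
  df
}

#' Write the full synthetic bundle to a directory
#'
#' Writes the expression TSVs, GMT annotation, MS tables, ortholog map and
#' the ground-truth JSON produced by [generateAll()].
#'
#' @param bundle list as returned by [generateAll()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeSyntheticBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFractionExperiment(bundle$experiment, dir)
  writeGMT(bundle$annotation, file.path(dir, "annotation.gmt"))
  utils::write.table(bundle$speciesA, file.path(dir, "ms_species_A.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$speciesB, file.path(dir, "ms_species_B.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$orthologMap, file.path(dir, "ortholog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- bundle$truth
  jsonlite::write_json(list(
    seed = tr@seed, gains = as.list(tr@gains), offsets = as.list(tr@offsets),
    planted_genes = tr@plantedGenes,
    invariant_probes = tr@invariantProbes,
    planted_term = tr@plantedTerm,
    planted_term_genes = tr@plantedTermGenes,
    ms_overlap_genes = tr@msOverlapGenes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
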