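#' Assemble a pipeline run configuration
#'
#' Either \code{simulation} (a \linkS4class{SimulationConfig}) for
#' synthetic mode or \code{inputs} (named list of file paths: matrix,
#' sample_sheet, probe_annotation, gmt, and optionally ms_species_A,
#' ms_species_B, ortholog_map) for real data, not both.
#'
#' @param simulation a \linkS4class{SimulationConfig}, or NULL.
#' @param inputs named list of input paths, or NULL.
#' @param kInvariant invariant-set size per type (default 400; capped at
#'   the number of gene probes at run time).
#' @param floor flooring value passed to the normalization steps.
#' @param fcThresholds fold-change thresholds (default c(2, 4)).
#' @param comparisons list of c(enriched, baseline) fraction pairs; the
#'   baseline acts as the independent (reference) type of the regression.
#' @param alpha significance level for enrichment (default 0.05).
#' @param reference reference type for the PCA-wide normalization.
#' @param outDir optional output directory for all tables and the report.
#' @param seed integer seed (used in synthetic mode).
#' @return a list of class \code{"pxRunConfig"}.
#' @export
runConfig <- function(simulation = NULL, inputs = NULL,
                      kInvariant = 400L, floor = NULL,
                      fcThresholds = c(2, 4),
                      comparisons = list(c("PX", "T"), c("IP", "T"),
                                         c("ML", "T"), c("PX", "ML"),
                                         c("IP", "ML"), c("IP", "PX")),
                      alpha = 0.05, reference = "T", outDir = NULL,
                      seed = 1L) {
  if (is.null(simulation) && is.null(inputs))
    stop("either a simulation config or real input paths are required")
  if (!is.null(simulation) && !is.null(inputs))
    stop("simulation mode and real inputs are mutually exclusive")
  if (any(fcThresholds <= 1)) stop("fold-change thresholds must exceed 1")
  structure(list(simulation = simulation, inputs = inputs,
                 kInvariant = as.integer(kInvariant), floor = floor,
                 fcThresholds = sort(fcThresholds), comparisons = comparisons,
                 alpha = alpha, reference = reference, outDir = outDir,
                 seed = as.integer(seed)),
            class = "pxRunConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Flat keys mirroring [runConfig()]; a \code{simulation:} block is passed
#' to [simulationConfig()], an \code{inputs:} block is taken as file paths
#' (relative to the YAML's directory), \code{comparisons} as a list of
#' two-element vectors.
#'
#' @param path YAML file path.
#' @return a \code{"pxRunConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("kInvariant", "floor", "fcThresholds", "alpha",
                        "reference", "outDir", "seed"))]
  if (!is.null(y$comparisons))
    args$comparisons <- lapply(y$comparisons, as.character)
  if (!is.null(y$simulation)) {
    s <- y$simulation
    if (!is.null(s$plantedEnrichments))
      s$plantedEnrichments <- as.data.frame(s$plantedEnrichments)
    args$simulation <- do.call(simulationConfig, s)
  }
  if (!is.null(y$inputs))
    args$inputs <- lapply(y$inputs, function(p)
      if (file.exists(p)) p else file.path(dirname(path), p))
  do.call(runConfig, args)
}

#' Run the full fraction-association analysis
#'
#' Stages, in order: data acquisition (synthetic generation or TSV
#' reading), negative-control background correction, reference-scale
#' normalization plus PCA QC, pairwise invariant-gene normalization and
#' two-criterion differential calls at every threshold, Venn overlap of
#' the PX and IP enrichment lists, annotation-term overrepresentation per
#' comparison (Benjamini-Yekutieli adjusted), and integration with the
#' mass-spectrometry tables when available. Reruns with the same config
#' are bit-identical.
#'
#' @param config a \code{"pxRunConfig"} from [runConfig()] or
#'   [readRunConfig()].
#' @return a run report: list with \code{calls} (per comparison and
#'   threshold), \code{callCounts}, \code{venn}, \code{enrichment},
#'   \code{pca}, \code{ms} and \code{provenance}. Written as TSV/JSON
#'   under \code{config$outDir} when set.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pxRunConfig"))
  truth <- NULL
  annotation <- NULL
  msA <- msB <- orthologMap <- NULL
  if (!is.null(config$simulation)) {
    bundle <- generateAll(config$simulation)
    fe <- bundle$experiment
    annotation <- bundle$annotation
    msA <- bundle$speciesA; msB <- bundle$speciesB
    orthologMap <- bundle$orthologMap
    truth <- bundle$truth
  } else {
    inp <- config$inputs
    fe <- readFractionExperiment(inp$matrix, inp$sample_sheet,
                                 inp$probe_annotation)
    if (!is.null(inp$gmt)) annotation <- readGMT(inp$gmt)
    if (!is.null(inp$ms_species_A)) msA <- readMSTable(inp$ms_species_A)
    if (!is.null(inp$ms_species_B)) msB <- readMSTable(inp$ms_species_B)
    if (!is.null(inp$ortholog_map))
      orthologMap <- readOrthologMap(inp$ortholog_map)
  }
  types <- unique(sampleType(fe))
  for (cmp in config$comparisons) {
    absent <- setdiff(cmp, types)
    if (length(absent))
      stop("comparison (", paste(cmp, collapse = " vs "),
           ") requests absent sample type(s): ",
           paste(absent, collapse = ", "))
  }

  corrected <- backgroundCorrect(fe, floor = config$floor)
  k <- min(config$kInvariant, nrow(corrected))

  refNorm <- normalizeToReference(corrected, reference = config$reference,
                                  k = k)
  pca <- pcaVariance(refNorm, k = min(3L, ncol(refNorm)))

  calls <- list()
  for (cmp in config$comparisons) {
    norm <- normalizePair(corrected, cmp[1], cmp[2], k = k)
    for (th in config$fcThresholds) {
      nm <- sprintf("%s_vs_%s_fc%g", cmp[1], cmp[2], th)
      calls[[nm]] <- callDifferential(norm, cmp[1], cmp[2],
                                      fcThreshold = th)
    }
  }
  callCounts <- vapply(calls, nrow, integer(1))

  venn <- list()
  for (th in config$fcThresholds) {
    px <- calls[[sprintf("PX_vs_T_fc%g", th)]]
    ip <- calls[[sprintf("IP_vs_T_fc%g", th)]]
    if (!is.null(px) && !is.null(ip))
      venn[[sprintf("fc%g", th)]] <-
        vennCounts(PX = px$gene_symbol, IP = ip$gene_symbol)
  }

  enrichment <- NULL
  if (!is.null(annotation)) {
    background <- stats::na.omit(geneSymbols(corrected))
    th1 <- config$fcThresholds[1]
    lists <- calls[grepl(sprintf("_fc%g$", th1), names(calls))]
    lists <- lapply(lists, `[[`, "gene_symbol")
    enrichment <- runEnrichment(lists, annotation, background,
                                alpha = config$alpha)
  }

  ms <- NULL
  if (!is.null(msA)) {
    th1 <- config$fcThresholds[1]
    px <- calls[[sprintf("PX_vs_T_fc%g", th1)]]
    ip <- calls[[sprintf("IP_vs_T_fc%g", th1)]]
    if (!is.null(px) && !is.null(ip)) {
      ms <- list()
      protA <- prefilterMS(msA)$gene_symbol
      ms$species_A <- overlapMrnaProtein(px$gene_symbol, ip$gene_symbol,
                                         protA)
      ms$species_A$p_distribution <- fractionDistributionTest(
        ms$species_A$counts["px"], ms$species_A$counts["ip"],
        length(unique(normalizeSymbols(px$gene_symbol))),
        length(unique(normalizeSymbols(ip$gene_symbol))))
      if (!is.null(msB) && !is.null(orthologMap)) {
        protB <- prefilterMS(msB)$gene_symbol
        mapped <- mapOrthologs(protB, orthologMap)
        ms$species_B <- overlapMrnaProtein(px$gene_symbol, ip$gene_symbol,
                                           mapped$mapped)
        ms$species_B$unmapped <- mapped$unmapped
        ms$species_B$p_distribution <- fractionDistributionTest(
          ms$species_B$counts["px"], ms$species_B$counts["ip"],
          length(unique(normalizeSymbols(px$gene_symbol))),
          length(unique(normalizeSymbols(ip$gene_symbol))))
      }
    }
  }

  report <- list(
    calls = calls,
    callCounts = as.list(callCounts),
    venn = venn,
    enrichment = enrichment,
    pca = list(variance_fraction = pca@varianceFraction),
    ms = if (!is.null(ms)) lapply(ms, function(s)
      list(counts = as.list(s$counts), p_distribution = s$p_distribution)),
    provenance = list(seed = config$seed,
                      k_invariant = k,
                      fc_thresholds = config$fcThresholds,
                      package_version =
                        as.character(utils::packageVersion("pxRNA")))
  )
  if (!is.null(truth)) report$truth <- truth
  report$pcaSummary <- pca

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(calls))
      utils::write.table(calls[[nm]],
                         file.path(config$outDir, paste0("calls_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment))
      utils::write.table(enrichment,
                         file.path(config$outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(call_counts = as.list(callCounts),
           venn = lapply(venn, function(v) as.list(stats::setNames(
             v$count, apply(v[names(v) != "count"], 1L, function(r)
               paste(ifelse(r, "in", "out"), collapse = "_"))))),
           ms = report$ms,
           pca_variance_fraction = pca@varianceFraction,
           provenance = report$provenance),
      file.path(config$outDir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
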