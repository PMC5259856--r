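#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

#' Container for fraction microarray intensities
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{"intensity"} assay of probe-level fluorescence values together with
#' the sample sheet (fraction type and replicate index in \code{colData}) and
#' the probe annotation (gene symbol and negative-control flag in
#' \code{rowData}).
#'
#' Validity requires: one assay named \code{"intensity"} with finite,
#' non-negative values and no missing entries; \code{colData} columns
#' \code{sample_type} (character) and \code{replicate} (integer); and
#' \code{rowData} columns \code{gene_symbol} (character, \code{NA} for
#' negative controls) and \code{is_negative_control} (logical).
#'
#' @seealso [FractionExperiment()] for the user constructor,
#'   [backgroundCorrect()], [normalizePair()].
#' @export
setClass("FractionExperiment", contains = "SummarizedExperiment")

setValidity("FractionExperiment", function(object) {
  msg <- character()
  if (!("intensity" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    x <- assay(object, "intensity")
    if (anyNA(x) || !all(is.finite(x)))
      msg <- c(msg, "intensities must be finite with no missing values")
    else if (any(x < 0))
      msg <- c(msg, "intensities must be non-negative")
  }
  cd <- colData(object)
  if (!all(c("sample_type", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'sample_type' and 'replicate'")
  rd <- rowData(object)
  if (!all(c("gene_symbol", "is_negative_control") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'gene_symbol' and 'is_negative_control'")
  else {
    nc <- rd$is_negative_control
    if (!is.logical(nc) || anyNA(nc))
      msg <- c(msg, "'is_negative_control' must be logical without NAs")
    else if (any(!is.na(rd$gene_symbol[nc])))
      msg <- c(msg, "negative-control probes must have NA gene_symbol")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique probe ids (rownames) are required")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic fraction-array generator
#'
#' Holds every knob of the generative model: probe and negative-control
#' counts, the fraction design (sample types x replicates), the log-normal
#' intensity model, per-array affine distortions, the invariant-gene share,
#' planted fold-change enrichments, the planted annotation term and the
#' planted mRNA-protein overlap. Construct with [simulationConfig()], which
#' supplies defaults mirroring the study design (4 fraction types, 3
#' technical replicates).
#'
#' @slot nProbes total probes on the array, negative controls included.
#' @slot nNegativeControls number of negative-control probes.
#' @slot sampleTypes ordered fraction labels.
#' @slot nReplicates technical replicates per fraction type.
#' @slot baselineLogMean,baselineLogSd natural-log mean/sd of true probe
#'   abundances across genes.
#' @slot noiseLogSd sd of the multiplicative log-normal replicate noise.
#' @slot invariantNoiseFactor multiplier (< 1) shrinking replicate noise on
#'   invariant genes.
#' @slot typeEffectLogSd sd of the per-type biological effect on
#'   non-invariant genes.
#' @slot invariantFraction share of gene probes with near-zero biological
#'   variability.
#' @slot gainRange,offsetRange per-array multiplicative gain and additive
#'   offset ranges.
#' @slot backgroundSd sd of the additive background on negative controls.
#' @slot plantedEnrichments data.frame with columns \code{fraction},
#'   \code{size}, \code{fold_change} (> 1).
#' @slot nTerms,termSizeRange,plantedTermSize,plantedTermOverlap annotation
#'   generator settings.
#' @slot msTableSize,msOverlapSize,msFailureRate mass-spectrometry table
#'   generator settings.
#' @slot seed integer seed driving all randomness.
#' @export
setClass("SimulationConfig", slots = c(
  nProbes = "integer",
  nNegativeControls = "integer",
  sampleTypes = "character",
  nReplicates = "integer",
  baselineLogMean = "numeric",
  baselineLogSd = "numeric",
  noiseLogSd = "numeric",
  invariantNoiseFactor = "numeric",
  typeEffectLogSd = "numeric",
  invariantFraction = "numeric",
  gainRange = "numeric",
  offsetRange = "numeric",
  backgroundSd = "numeric",
  plantedEnrichments = "data.frame",
  nTerms = "integer",
  termSizeRange = "integer",
  plantedTermSize = "integer",
  plantedTermOverlap = "integer",
  msTableSize = "integer",
  msOverlapSize = "integer",
  msFailureRate = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nProbes < 1L) msg <- c(msg, "nProbes must be positive")
  if (object@nNegativeControls < 1L ||
      object@nNegativeControls >= object@nProbes)
    msg <- c(msg, "need 1 <= nNegativeControls < nProbes")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be positive")
  if (anyDuplicated(object@sampleTypes))
    msg <- c(msg, "sampleTypes must be unique")
  if (object@baselineLogSd < 0 || object@noiseLogSd < 0)
    msg <- c(msg, "log-scale sds must be non-negative")
  if (object@invariantFraction <= 0 || object@invariantFraction > 1)
    msg <- c(msg, "invariantFraction must lie in (0, 1]")
  for (nm in c("gainRange", "offsetRange", "termSizeRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || r[1] > r[2])
      msg <- c(msg, sprintf("%s must be an ordered pair", nm))
  }
  if (any(object@gainRange <= 0)) msg <- c(msg, "gains must be positive")
  if (any(object@offsetRange < 0)) msg <- c(msg, "offsets must be non-negative")
  pe <- object@plantedEnrichments
  if (nrow(pe)) {
    if (!all(c("fraction", "size", "fold_change") %in% colnames(pe)))
      msg <- c(msg, "plantedEnrichments needs fraction/size/fold_change columns")
    else {
      if (any(pe$fold_change <= 1))
        msg <- c(msg, "planted fold changes must exceed 1")
      if (!all(pe$fraction %in% object@sampleTypes))
        msg <- c(msg, "planted fractions must be among sampleTypes")
      if (anyDuplicated(pe$fraction))
        msg <- c(msg, "planted gene sets must be disjoint: one entry per fraction")
    }
  }
  nPlanted <- if (nrow(pe)) sum(pe$size) else 0L
  if (object@plantedTermOverlap > min(object@plantedTermSize, nPlanted))
    msg <- c(msg, "plantedTermOverlap exceeds planted term size or planted genes")
  if (object@msOverlapSize > nPlanted)
    msg <- c(msg, "msOverlapSize exceeds the number of planted genes")
  if (object@msFailureRate < 0 || object@msFailureRate > 1)
    msg <- c(msg, "msFailureRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated dataset
#'
#' Records exactly what the generator planted: the affine distortion applied
#' to each array, the enriched genes and their true fold changes, the
#' invariant probes, the planted annotation term, the planted mRNA-protein
#' overlap, and the seed. Every recovery test downstream compares against
#' this object.
#'
#' @slot gains,offsets named numeric vectors, one entry per sample.
#' @slot plantedGenes data.frame with \code{probe_id}, \code{gene_symbol},
#'   \code{fraction}, \code{fold_change}.
#' @slot invariantProbes probe ids generated with near-zero variability.
#' @slot geneSymbols all non-control gene symbols on the array.
#' @slot plantedTerm id of the planted annotation term.
#' @slot plantedTermGenes symbols inside the planted term.
#' @slot msOverlapGenes symbols planted into both MS tables.
#' @slot seed seed used.
#' @export
setClass("SimulationTruth", slots = c(
  gains = "numeric",
  offsets = "numeric",
  plantedGenes = "data.frame",
  invariantProbes = "character",
  geneSymbols = "character",
  plantedTerm = "character",
  plantedTermGenes = "character",
  msOverlapGenes = "character",
  seed = "integer"
))

#' Invariant gene set for one pair of sample types
#'
#' The per-type low-variance probe sets (lowest coefficient of variation
#' across that type's replicates) and their intersection, which anchors the
#' pairwise regression normalization.
#'
#' @slot pair character of length 2: (dependent type, independent type).
#' @slot setDependent,setIndependent the per-type low-variance probe ids.
#' @slot intersection probes common to both sets, used for fitting.
#' @export
setClass("InvariantGeneSet", slots = c(
  pair = "character",
  setDependent = "character",
  setIndependent = "character",
  intersection = "character"
))

setValidity("InvariantGeneSet", function(object) {
  msg <- character()
  if (length(object@pair) != 2L) msg <- c(msg, "pair must have length 2")
  if (!all(object@intersection %in% object@setDependent) ||
      !all(object@intersection %in% object@setIndependent))
    msg <- c(msg, "intersection must be contained in both per-type sets")
  if (length(msg)) msg else TRUE
})

#' Affine map fitted on an invariant gene set
#'
#' Ordinary least squares fit of the dependent sample type's invariant-gene
#' values on the independent type's, i.e. the slope/intercept pair that
#' minimizes the squared loss sum((x_dep - a * x_indep - b)^2). The median
#' of the independent values over the invariant set is kept as the
#' normalization basis to which the transformed dependent samples are
#' anchored.
#'
#' @slot slope,intercept fitted coefficients (slope dimensionless,
#'   intercept in intensity units).
#' @slot nPoints number of invariant genes used.
#' @slot rss residual sum of squares (intensity squared).
#' @slot medianIndependent median of the independent values over the
#'   invariant set.
#' @slot probeIds invariant probe ids the fit was computed on.
#' @slot pair character of length 2: (dependent, independent) sample types.
#' @export
setClass("LinearMapFit", slots = c(
  slope = "numeric",
  intercept = "numeric",
  nPoints = "integer",
  rss = "numeric",
  medianIndependent = "numeric",
  probeIds = "character",
  pair = "character"
))

setValidity("LinearMapFit", function(object) {
  msg <- character()
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (!is.finite(object@slope)) msg <- c(msg, "slope must be finite")
  if (length(msg)) msg else TRUE
})

#' Collection of gene sets (annotation terms)
#'
#' A named list of character vectors of gene symbols plus one description
#' per term, as read from or written to GMT. Symbols are stored
#' case-normalized (upper case, whitespace stripped).
#'
#' @slot sets named list of character vectors; no empty terms.
#' @slot descriptions one description per term, same names as \code{sets}.
#' @export
setClass("AnnotationSets", slots = c(
  sets = "list",
  descriptions = "character"
))

setValidity("AnnotationSets", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must have unique names")
  if (any(lengths(object@sets) == 0L)) msg <- c(msg, "empty terms not allowed")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "one description per term required")
  if (length(msg)) msg else TRUE
})

#' Principal component QC summary
#'
#' Variance fractions for all components of a samples-as-observations
#' covariance PCA, plus varimax-rotated loadings and sample scores for the
#' retained top components.
#'
#' @slot varianceFraction per-component variance fractions, in [0,1],
#'   descending before rotation, summing to 1.
#' @slot loadings rotated loadings (probes x k).
#' @slot scores rotated sample scores (samples x k).
#' @slot rotation the k x k orthogonal varimax rotation matrix.
#' @export
setClass("PcaSummary", slots = c(
  varianceFraction = "numeric",
  loadings = "matrix",
  scores = "matrix",
  rotation = "matrix"
))
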