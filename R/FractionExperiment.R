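#' Construct a FractionExperiment
#'
#' @param intensity numeric matrix of probe intensities (probes x samples),
#'   with rownames giving probe ids and colnames sample ids.
#' @param sampleType character vector, one fraction label per sample
#'   (e.g. \code{"T"}, \code{"ML"}, \code{"PX"}, \code{"IP"}).
#' @param replicate integer replicate index per sample.
#' @param geneSymbol character vector of gene symbols per probe (\code{NA}
#'   for negative controls).
#' @param isNegativeControl logical vector flagging negative-control probes.
#'
#' @return a \linkS4class{FractionExperiment}.
#' @examples
#' m <- matrix(100, 4, 2, dimnames = list(paste0("P", 1:4), c("s1", "s2")))
#' fe <- FractionExperiment(m, sampleType = c("T", "PX"),
#'                          replicate = c(1L, 1L),
#'                          geneSymbol = c("A", "B", "C", NA),
#'                          isNegativeControl = c(FALSE, FALSE, FALSE, TRUE))
#' sampleType(fe)
#' @export
FractionExperiment <- function(intensity, sampleType, replicate,
                               geneSymbol, isNegativeControl) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)))
    stop("intensity matrix must carry probe ids as rownames")
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste0("sample_", seq_len(ncol(intensity)))
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = DataFrame(sample_type = as.character(sampleType),
                        replicate = as.integer(replicate),
                        row.names = colnames(intensity)),
    rowData = DataFrame(gene_symbol = as.character(geneSymbol),
                        is_negative_control = as.logical(isNegativeControl),
                        row.names = rownames(intensity))
  )
  new("FractionExperiment", se)
}

#' @rdname FractionExperiment
#' @param object,x a \code{FractionExperiment}.
#' @export
setGeneric("sampleType", function(object) standardGeneric("sampleType"))

#' @rdname FractionExperiment
#' @export
setMethod("sampleType", "FractionExperiment", function(object)
  colData(object)$sample_type)

#' @rdname FractionExperiment
#' @export
setGeneric("replicateIndex", function(object) standardGeneric("replicateIndex"))

#' @rdname FractionExperiment
#' @export
setMethod("replicateIndex", "FractionExperiment", function(object)
  colData(object)$replicate)

#' @rdname FractionExperiment
#' @export
setGeneric("geneSymbols", function(object) standardGeneric("geneSymbols"))

#' @rdname FractionExperiment
#' @export
setMethod("geneSymbols", "FractionExperiment", function(object)
  rowData(object)$gene_symbol)

#' @rdname FractionExperiment
#' @export
setGeneric("isNegativeControl",
           function(object) standardGeneric("isNegativeControl"))

#' @rdname FractionExperiment
#' @export
setMethod("isNegativeControl", "FractionExperiment", function(object)
  rowData(object)$is_negative_control)

#' @rdname FractionExperiment
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname FractionExperiment
#' @export
setMethod("intensity", "FractionExperiment", function(object)
  assay(object, "intensity"))

#' Subset a FractionExperiment to the samples of given fraction types
#'
#' @param object a \linkS4class{FractionExperiment}.
#' @param types character vector of fraction labels to keep.
#' @return the experiment restricted to samples of those types.
#' @export
selectTypes <- function(object, types) {
  stopifnot(is(object, "FractionExperiment"))
  missing <- setdiff(types, unique(sampleType(object)))
  if (length(missing))
    stop("sample type(s) absent from the experiment: ",
         paste(missing, collapse = ", "))
  object[, sampleType(object) %in% types]
}

setMethod("show", "FractionExperiment", function(object) {
  cat("FractionExperiment with", nrow(object), "probes x",
      ncol(object), "samples\n")
  tt <- table(sampleType(object))
  cat("  sample types:",
      paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "), "\n")
  cat("  negative-control probes:", sum(isNegativeControl(object)), "\n")
})

setMethod("show", "LinearMapFit", function(object) {
  cat(sprintf("LinearMapFit %s ~ %s: slope %.4f, intercept %.4f (n = %d, RSS = %.4g)\n",
              object@pair[1], object@pair[2], object@slope, object@intercept,
              object@nPoints, object@rss))
})

setMethod("show", "InvariantGeneSet", function(object) {
  cat(sprintf("InvariantGeneSet (%s, %s): %d / %d per-type probes, %d common\n",
              object@pair[1], object@pair[2], length(object@setDependent),
              length(object@setIndependent), length(object@intersection)))
  if (length(object@intersection) == 0L)
    cat("  warning: empty intersection, regression cannot be fitted\n")
})

setMethod("show", "AnnotationSets", function(object) {
  cat("AnnotationSets with", length(object@sets), "terms; sizes",
      min(lengths(object@sets)), "-", max(lengths(object@sets)), "\n")
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth: seed", object@seed, "\n")
  cat("  planted genes:", nrow(object@plantedGenes),
      "| invariant probes:", length(object@invariantProbes), "\n")
})

#' @rdname AnnotationSets-accessors
#' @param object an \linkS4class{AnnotationSets}.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' Access the gene sets and descriptions of an AnnotationSets
#'
#' @return \code{geneSets} returns the named list of symbol vectors;
#'   \code{termDescriptions} the per-term description vector.
#' @name AnnotationSets-accessors
#' @export
setMethod("geneSets", "AnnotationSets", function(object) object@sets)

#' @rdname AnnotationSets-accessors
#' @export
setGeneric("termDescriptions",
           function(object) standardGeneric("termDescriptions"))

#' @rdname AnnotationSets-accessors
#' @export
setMethod("termDescriptions", "AnnotationSets", function(object)
  object@descriptions)
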