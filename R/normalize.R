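#' Background-correct intensities using negative-control probes
#'
#' Subtracts, per sample, the mean intensity of that sample's
#' negative-control probes from every probe, floors the result at a small
#' positive value, and drops the control rows from the returned experiment.
#' On Illumina-style chips the negative controls carry only optical and
#' hybridization background, so their per-array mean is an unbiased
#' estimate of the additive offset of that array.
#'
#' @param object a \linkS4class{FractionExperiment} still containing its
#'   negative-control probes.
#' @param floor positive value at which corrected intensities are floored.
#'   Default (\code{NULL}): half the smallest positive post-subtraction
#'   value, so the floor never dominates real signal.
#' @return a \code{FractionExperiment} without control rows;
#'   \code{metadata()$background} records the per-sample control means and
#'   the floor used.
#' @examples
#' m <- matrix(c(100, 10, 12, 14), 4, 1,
#'             dimnames = list(c("P1", "N1", "N2", "N3"), "T_1"))
#' fe <- FractionExperiment(m, "T", 1L, c("A", NA, NA, NA),
#'                          c(FALSE, TRUE, TRUE, TRUE))
#' intensity(backgroundCorrect(fe))  # 100 - mean(10,12,14) = 88
#' @export
backgroundCorrect <- function(object, floor = NULL) {
  stopifnot(is(object, "FractionExperiment"))
  ctrl <- isNegativeControl(object)
  if (!any(ctrl))
    stop("no negative-control probes: background correction impossible")
  if (!is.null(floor) && floor <= 0)
    stop("floor must be positive")
  x <- intensity(object)
  ctrlMeans <- colMeans(x[ctrl, , drop = FALSE])
  corrected <- sweep(x[!ctrl, , drop = FALSE], 2, ctrlMeans, `-`)
  if (is.null(floor)) {
    pos <- corrected[corrected > 0]
    floor <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  }
  corrected[corrected < floor] <- floor
  out <- object[!ctrl, ]
  SummarizedExperiment::assay(out, "intensity") <- corrected
  metadata(out)$background <- list(control_means = ctrlMeans, floor = floor)
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, the
#' ranking statistic used to pick invariant genes.
#'
#' @param values numeric vector with at least 2 values and positive mean.
#' @return non-negative real.
#' @examples
#' coefficientOfVariation(c(1, 2, 3))  # 0.5
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive to rank by CV")
  stats::sd(values) / m
}

#' Select the invariant (lowest-CV) genes of one sample type
#'
#' Ranks every non-control probe by the coefficient of variation across the
#' chosen type's technical replicates and returns the \code{k} probes with
#' the smallest CV. Boundary ties are broken by lexicographic probe id, so
#' the selection is reproducible.
#'
#' @param object a background-corrected \linkS4class{FractionExperiment}.
#' @param type fraction label whose replicates are used.
#' @param k number of probes to select (default 400).
#' @return character vector of \code{k} probe ids.
#' @export
selectInvariantGenes <- function(object, type, k = 400L) {
  stopifnot(is(object, "FractionExperiment"))
  keep <- !isNegativeControl(object)
  x <- intensity(object)[keep, sampleType(object) == type, drop = FALSE]
  if (ncol(x) < 2L)
    stop("sample type '", type, "' needs >= 2 replicates for CV ranking")
  if (k > nrow(x))
    stop("k exceeds the number of non-control probes")
  cv <- apply(x, 1L, coefficientOfVariation)
  ids <- rownames(x)
  ids[order(cv, ids)][seq_len(k)]
}

#' Intersect two per-type invariant sets
#'
#' The probes common to both types' low-variance sets are the invariant
#' genes specific to that pair and anchor the regression. An empty
#' intersection is allowed here but flagged (the downstream fit refuses to
#' run on it).
#'
#' @param setDependent,setIndependent probe ids from
#'   [selectInvariantGenes()] for the two types.
#' @param pair character of length 2 naming (dependent, independent) types.
#' @return an \linkS4class{InvariantGeneSet}.
#' @export
pairInvariantSet <- function(setDependent, setIndependent,
                             pair = c("dependent", "independent")) {
  obj <- new("InvariantGeneSet", pair = as.character(pair),
             setDependent = as.character(setDependent),
             setIndependent = as.character(setIndependent),
             intersection = sort(intersect(setDependent, setIndependent)))
  if (length(obj@intersection) == 0L)
    warning("empty invariant-set intersection for pair (",
            pair[1], ", ", pair[2], ")")
  obj
}

#' Fit the invariant-gene regression between two sample types
#'
#' Ordinary least squares of the dependent type's invariant-gene values on
#' the independent type's: minimizes \code{sum((dep - a * indep - b)^2)}.
#' Values are paired by probe id via their names when available.
#'
#' @param depValues,indepValues numeric vectors of matching length (one
#'   value per invariant gene, typically the per-probe median across that
#'   type's replicates).
#' @param pair character of length 2 naming (dependent, independent) types.
#' @return a \linkS4class{LinearMapFit} with slope, intercept, number of
#'   points, residual sum of squares and the median of the independent
#'   values (the normalization basis).
#' @examples
#' f <- fitInvariantRegression(2 * (1:5) + 1, 1:5)
#' c(f@slope, f@intercept, f@rss)  # 2, 1, 0
#' @export
fitInvariantRegression <- function(depValues, indepValues,
                                   pair = c("dependent", "independent")) {
  if (length(depValues) != length(indepValues))
    stop("dependent and independent values must pair up")
  if (!is.null(names(depValues)) && !is.null(names(indepValues))) {
    if (!setequal(names(depValues), names(indepValues)))
      stop("probe ids of the two value vectors differ")
    indepValues <- indepValues[names(depValues)]
  }
  n <- length(depValues)
  if (n < 2L) stop("need at least 2 invariant genes to fit")
  if (stats::var(indepValues) == 0)
    stop("independent values have zero variance; regression undefined")
  fit <- stats::lm.fit(cbind(intercept = 1, slope = indepValues),
                       depValues)
  a <- unname(fit$coefficients["slope"])
  b <- unname(fit$coefficients["intercept"])
  new("LinearMapFit", slope = a, intercept = b, nPoints = as.integer(n),
      rss = sum(fit$residuals^2),
      medianIndependent = stats::median(indepValues),
      probeIds = if (is.null(names(depValues))) character()
                 else names(depValues),
      pair = as.character(pair))
}

#' Apply a fitted pair normalization to an experiment
#'
#' Samples of the independent type are left untouched; every value v of the
#' dependent type is mapped onto the independent scale by the inverse
#' affine map (v - b) / a. Any residual shift is then removed by a final
#' additive adjustment so the dependent samples' median over the invariant
#' set equals the fit's \code{medianIndependent} (the normalization basis).
#' Values are re-floored at \code{floor}.
#'
#' @param object a \linkS4class{FractionExperiment} containing (at least)
#'   the pair's samples.
#' @param fit a \linkS4class{LinearMapFit} for this pair, carrying the
#'   invariant probe ids.
#' @param dependentType fraction label whose samples are transformed.
#' @param floor positive re-flooring value (default: the floor recorded by
#'   [backgroundCorrect()], else the smallest positive machine number).
#' @return the experiment with the dependent samples transformed;
#'   \code{metadata()$fits} accumulates the applied fits.
#' @export
applyPairNormalization <- function(object, fit, dependentType,
                                   floor = NULL) {
  stopifnot(is(object, "FractionExperiment"), is(fit, "LinearMapFit"))
  if (fit@slope <= 0)
    stop("non-positive slope: orientation-reversing map rejected")
  dep <- sampleType(object) == dependentType
  if (!any(dep)) stop("no samples of dependent type '", dependentType, "'")
  if (is.null(floor))
    floor <- metadata(object)$background$floor %||% .Machine$double.eps
  x <- intensity(object)
  x[, dep] <- (x[, dep, drop = FALSE] - fit@intercept) / fit@slope
  if (length(fit@probeIds)) {
    inv <- intersect(fit@probeIds, rownames(x))
    depMed <- stats::median(rowMedians_(x[inv, dep, drop = FALSE]))
    x[, dep] <- x[, dep, drop = FALSE] + (fit@medianIndependent - depMed)
  }
  x[, dep][x[, dep, drop = FALSE] < floor] <- floor
  SummarizedExperiment::assay(object, "intensity") <- x
  metadata(object)$fits <- c(metadata(object)$fits, list(fit))
  object
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize one pair of sample types by the invariant-gene-set method
#'
#' Full pairwise step on background-corrected data: per-type invariant gene
#' selection (top \code{k} lowest CV), intersection, OLS of the dependent
#' type's per-probe replicate medians on the independent type's over the
#' intersection, and application of the inverse map (with median anchoring)
#' to the dependent samples.
#'
#' @param object a background-corrected \linkS4class{FractionExperiment}.
#' @param dependentType,independentType the pair; the independent type is
#'   the reference/baseline of the contrast and is left unchanged.
#' @param k invariant-set size per type (default 400).
#' @param floor re-flooring value, see [applyPairNormalization()].
#' @return the experiment restricted to the pair's samples, normalized;
#'   \code{metadata()$fits} holds the \linkS4class{LinearMapFit},
#'   \code{metadata()$invariantSet} the \linkS4class{InvariantGeneSet}.
#' @export
normalizePair <- function(object, dependentType, independentType,
                          k = 400L, floor = NULL) {
  stopifnot(is(object, "FractionExperiment"))
  pairObj <- selectTypes(object, c(dependentType, independentType))
  invSet <- pairInvariantSet(
    selectInvariantGenes(pairObj, dependentType, k),
    selectInvariantGenes(pairObj, independentType, k),
    pair = c(dependentType, independentType))
  if (length(invSet@intersection) < 2L)
    stop("fewer than 2 common invariant genes for pair (",
         dependentType, ", ", independentType, ")")
  x <- intensity(pairObj)[invSet@intersection, , drop = FALSE]
  st <- sampleType(pairObj)
  depMed <- rowMedians_(x[, st == dependentType, drop = FALSE])
  indMed <- rowMedians_(x[, st == independentType, drop = FALSE])
  names(depMed) <- names(indMed) <- invSet@intersection
  fit <- fitInvariantRegression(depMed, indMed,
                                pair = c(dependentType, independentType))
  out <- applyPairNormalization(pairObj, fit, dependentType, floor = floor)
  metadata(out)$invariantSet <- invSet
  out
}

#' Normalize every sample type onto a common reference scale
#'
#' Applies [normalizePair()] with each non-reference type as dependent and
#' the reference as independent, and reassembles one experiment on the
#' reference scale (used for PCA QC across all samples).
#'
#' @param object a background-corrected \linkS4class{FractionExperiment}.
#' @param reference fraction label serving as the common scale
#'   (default \code{"T"}).
#' @inheritParams normalizePair
#' @return the full experiment with all non-reference samples transformed.
#' @export
normalizeToReference <- function(object, reference = "T", k = 400L,
                                 floor = NULL) {
  stopifnot(is(object, "FractionExperiment"))
  types <- unique(sampleType(object))
  if (!reference %in% types) stop("reference type '", reference,
                                  "' absent from the experiment")
  x <- intensity(object)
  fits <- list()
  for (tp in setdiff(types, reference)) {
    norm <- normalizePair(object, tp, reference, k = k, floor = floor)
    x[, sampleType(object) == tp] <-
      intensity(norm)[rownames(x), sampleType(norm) == tp]
    fits[[tp]] <- metadata(norm)$fits[[1L]]
  }
  SummarizedExperiment::assay(object, "intensity") <- x
  metadata(object)$fits <- fits
  object
}
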