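#' Strict dominance between two replicate groups
#'
#' TRUE iff every value in \code{valuesA} strictly exceeds every value in
#' \code{valuesB}, i.e. \code{min(valuesA) > max(valuesB)}; ties fail. This
#' is the first of the two criteria of the differential-association rule.
#'
#' @param valuesA,valuesB non-empty numeric vectors (replicate intensities
#'   of one gene in the enriched and the baseline group).
#' @return logical flag.
#' @examples
#' strictDominance(c(4, 5, 6), c(1, 1, 2))  # TRUE
#' strictDominance(c(3, 5, 6), c(1, 3, 2))  # FALSE: tie at 3
#' @export
strictDominance <- function(valuesA, valuesB) {
  if (!length(valuesA) || !length(valuesB))
    stop("both replicate groups must be non-empty")
  min(valuesA) > max(valuesB)
}

#' Median fold change between two replicate groups
#'
#' Ratio of the median of \code{valuesA} to the median of \code{valuesB}
#' (the median of an even count is the mean of the two central values),
#' the second criterion of the differential-association rule.
#'
#' @inheritParams strictDominance
#' @return positive real.
#' @examples
#' foldChange(c(4, 5, 6), c(1, 1, 2))  # 5
#' foldChange(c(2, 8), c(1, 3))        # 2.5
#' @export
foldChange <- function(valuesA, valuesB) {
  if (!length(valuesA) || !length(valuesB))
    stop("both replicate groups must be non-empty")
  mB <- stats::median(valuesB)
  if (mB <= 0) stop("baseline median must be positive for a fold change")
  stats::median(valuesA) / mB
}

#' Call genes differentially associated between two sample types
#'
#' Applies the two-criterion rule probe by probe on a pair-normalized
#' experiment: a gene is called enriched in \code{enrichedType} over
#' \code{baselineType} when (1) all its replicate values in the enriched
#' type strictly exceed all its values in the baseline type, and (2) its
#' median fold change is at least \code{fcThreshold}. Only the
#' enriched-over-baseline direction is reported; swap the arguments for
#' depletion lists. Calls at threshold 4 are by construction a subset of
#' calls at threshold 2 on the same input.
#'
#' @param object a pair-normalized \linkS4class{FractionExperiment}
#'   (see [normalizePair()]).
#' @param enrichedType,baselineType the fraction pair.
#' @param fcThreshold fold-change threshold, conventionally 2 or 4.
#' @param collapse if TRUE, collapse probes to gene symbols keeping, per
#'   symbol, the probe with the highest baseline median.
#' @return data.frame with one row per call: probe_id, gene_symbol,
#'   median_enriched, median_baseline, fold_change, threshold.
#' @export
callDifferential <- function(object, enrichedType, baselineType,
                             fcThreshold = 2, collapse = FALSE) {
  stopifnot(is(object, "FractionExperiment"))
  st <- sampleType(object)
  for (tp in c(enrichedType, baselineType))
    if (!tp %in% st) stop("unknown sample type '", tp, "'")
  keep <- !isNegativeControl(object)
  xA <- intensity(object)[keep, st == enrichedType, drop = FALSE]
  xB <- intensity(object)[keep, st == baselineType, drop = FALSE]
  medA <- rowMedians_(xA)
  medB <- rowMedians_(xB)
  dominant <- apply(xA, 1L, min) > apply(xB, 1L, max)
  fc <- medA / medB
  pass <- dominant & medB > 0 & fc >= fcThreshold
  out <- data.frame(probe_id = rownames(xA)[pass],
                    gene_symbol = geneSymbols(object)[keep][pass],
                    median_enriched = medA[pass],
                    median_baseline = medB[pass],
                    fold_change = fc[pass],
                    threshold = rep(fcThreshold, sum(pass)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  if (collapse && nrow(out)) {
    out <- out[order(-out$median_baseline, out$probe_id), , drop = FALSE]
    out <- out[!duplicated(out$gene_symbol), , drop = FALSE]
    out <- out[order(-out$fold_change, out$probe_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Venn region counts for up to three gene lists
#'
#' @param ... two or three character vectors (or a single named list of
#'   them); duplicates within a list are ignored.
#' @return data.frame with one row per Venn region: the membership pattern
#'   over the lists and the exclusive count of that region. Counts sum to
#'   the union size.
#' @examples
#' vennCounts(first = c("A", "B", "C"), second = c("B", "C", "D"))
#' @export
vennCounts <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1L]])) lists <- lists[[1L]]
  if (length(lists) < 2L || length(lists) > 3L)
    stop("vennCounts supports 2 or 3 lists")
  if (is.null(names(lists)) || any(names(lists) == ""))
    names(lists) <- paste0("list", seq_along(lists))
  lists <- lapply(lists, unique)
  universe <- unique(unlist(lists))
  membership <- vapply(lists, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(lists)))[-2^length(lists), , drop = FALSE]
  colnames(patterns) <- names(lists)
  counts <- apply(patterns, 1L, function(p)
    sum(apply(membership, 1L, function(m) all(m == p))))
  out <- cbind(patterns, count = as.integer(counts))
  rownames(out) <- NULL
  out
}
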