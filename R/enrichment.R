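#' Build a 2x2 contingency table for term overrepresentation
#'
#' Counts, within the background universe: \code{a} genes in the list and
#' in the term, \code{b} in the list only, \code{c} in the term only,
#' \code{d} in neither. Term genes outside the background are ignored;
#' the gene list must be a subset of the background.
#'
#' @param geneList character vector of (normalized) gene symbols.
#' @param termGenes character vector of the term's symbols.
#' @param background character vector, the gene universe.
#' @return named integer vector \code{c(a, b, c, d)}.
#' @examples
#' buildContingency(c("A", "B"), c("B", "C"), c("A", "B", "C", "D"))
#' @export
buildContingency <- function(geneList, termGenes, background) {
  background <- unique(background)
  geneList <- unique(geneList)
  termGenes <- unique(termGenes)
  if (!all(geneList %in% background))
    stop("gene list must be a subset of the background universe")
  termGenes <- intersect(termGenes, background)
  a <- length(intersect(geneList, termGenes))
  b <- length(geneList) - a
  cc <- length(termGenes) - a
  d <- length(background) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided Fisher exact test for overrepresentation
#'
#' Exact hypergeometric upper-tail probability of observing at least
#' \code{a} term genes in the list given the table margins:
#' P(X >= a) with X ~ Hypergeometric(term size, non-term size, list size).
#'
#' @param table named vector \code{c(a, b, c, d)} as from
#'   [buildContingency()], or four separate counts.
#' @param b,c,d optional separate counts if \code{table} is scalar \code{a}.
#' @return p-value in (0, 1].
#' @examples
#' fisherExactGreater(c(a = 2, b = 0, c = 0, d = 2))  # 1/6
#' @export
fisherExactGreater <- function(table, b = NULL, c = NULL, d = NULL) {
  k <- contingencyCounts(table, b, c, d)
  stats::phyper(k[1] - 1, m = k[1] + k[3], n = k[2] + k[4],
                k = k[1] + k[2], lower.tail = FALSE)
}

#' Two-sided Fisher exact test
#'
#' Sums the probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table (the
#' minimum-likelihood convention, with a small relative tolerance for
#' floating-point ties).
#'
#' @inheritParams fisherExactGreater
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(c(a = 2, b = 0, c = 0, d = 2))  # 1/3
#' @export
fisherExactTwoSided <- function(table, b = NULL, c = NULL, d = NULL) {
  k <- contingencyCounts(table, b, c, d)
  m <- k[1] + k[3]; nn <- k[2] + k[4]; kk <- k[1] + k[2]
  support <- max(0, kk - nn):min(kk, m)
  probs <- stats::dhyper(support, m, nn, kk)
  pObs <- stats::dhyper(k[1], m, nn, kk)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

contingencyCounts <- function(table, b, c, d) {
  k <- if (is.null(b)) table else c(table, b, c, d)
  if (length(k) != 4L) stop("need counts a, b, c, d")
  k <- as.numeric(k)
  if (any(k < 0) || any(k != round(k)))
    stop("contingency counts must be non-negative integers")
  unname(k)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary
#' dependence: adjusted_(i) = min over j >= i of p_(j) * m * c(m) / j,
#' capped at 1, with c(m) the harmonic sum 1 + 1/2 + ... + 1/m. Delegates
#' to \code{stats::p.adjust(method = "BY")} after validating the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, elementwise >= the raw ones.
#' @examples
#' benjaminiYekutieli(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
benjaminiYekutieli <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Enrichment ratio of a contingency table
#'
#' Proportion of the gene list annotated to the term divided by the
#' background proportion: \code{(a/(a+b)) / ((a+c)/(a+b+c+d))}.
#'
#' @inheritParams fisherExactGreater
#' @return non-negative real (0 when the term is absent from the list).
#' @export
enrichmentRatio <- function(table, b = NULL, c = NULL, d = NULL) {
  k <- contingencyCounts(table, b, c, d)
  if ((k[1] + k[2]) == 0 || (k[1] + k[3]) == 0)
    stop("empty list or empty term: enrichment ratio undefined")
  (k[1] / (k[1] + k[2])) / ((k[1] + k[3]) / sum(k))
}

#' Test annotation-term overrepresentation in differential gene lists
#'
#' For each gene list (one per pairwise comparison) and each annotation
#' term: builds the contingency table against the background, computes the
#' one-sided Fisher exact p, the enrichment ratio, and the
#' Benjamini-Yekutieli adjusted p within that list's family of terms.
#' Significance is declared at adjusted p below \code{alpha}. Symbols are
#' case-normalized before matching; terms with no background gene are
#' dropped.
#'
#' @param geneLists named list of character vectors of gene symbols
#'   (e.g. the \code{gene_symbol} column of [callDifferential()] output).
#' @param annotation an \linkS4class{AnnotationSets}.
#' @param background character vector of the gene universe (all non-control
#'   symbols detected in the compared pair).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame with columns list, term, description, a, b, c, d,
#'   enrichment_ratio, p_value, p_adjusted, significant; ordered by list
#'   then adjusted p.
#' @export
runEnrichment <- function(geneLists, annotation, background, alpha = 0.05) {
  stopifnot(is(annotation, "AnnotationSets"))
  background <- unique(normalizeSymbols(background))
  if (!length(background)) stop("empty background universe")
  if (is.null(names(geneLists)))
    names(geneLists) <- paste0("list", seq_along(geneLists))
  sets <- lapply(geneSets(annotation), normalizeSymbols)
  sets <- lapply(sets, intersect, background)
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  descs <- termDescriptions(annotation)[keep]
  out <- lapply(names(geneLists), function(nm) {
    gl <- unique(normalizeSymbols(geneLists[[nm]]))
    tabs <- vapply(sets, buildContingency, integer(4), geneList = gl,
                   background = background)
    p <- apply(tabs, 2L, fisherExactGreater)
    ratio <- apply(tabs, 2L, function(k)
      if (k[1] + k[3] == 0 || k[1] + k[2] == 0) NA_real_
      else enrichmentRatio(k))
    padj <- benjaminiYekutieli(p)
    data.frame(list = nm, term = names(sets), description = unname(descs),
               a = tabs[1, ], b = tabs[2, ], c = tabs[3, ], d = tabs[4, ],
               enrichment_ratio = ratio, p_value = p, p_adjusted = padj,
               significant = padj < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$list, out$p_adjusted, out$p_value, out$term), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
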