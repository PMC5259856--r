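#' Prefilter mass-spectrometry protein entries by identification quality
#'
#' Retains entries identified by at least 2 peptides covering at least 10%
#' of the protein length; both boundaries are inclusive. The filter is
#' monotone: relaxing either threshold never removes a retained entry.
#'
#' @param entries data.frame with columns \code{n_peptides} and
#'   \code{coverage_pct} (and typically protein_id / gene_symbol).
#' @param minPeptides,minCoverage thresholds (defaults 2 and 10).
#' @return the retained rows of \code{entries}.
#' @export
prefilterMS <- function(entries, minPeptides = 2L, minCoverage = 10) {
  stopifnot(all(c("n_peptides", "coverage_pct") %in% colnames(entries)))
  if (any(entries$n_peptides < 0))
    stop("negative peptide counts are invalid")
  if (any(entries$coverage_pct < 0 | entries$coverage_pct > 100))
    stop("coverage_pct must lie in [0, 100]")
  entries[entries$n_peptides >= minPeptides &
          entries$coverage_pct >= minCoverage, , drop = FALSE]
}

#' Map foreign-species gene symbols onto the reference species
#'
#' Substitutes each symbol through the ortholog map; symbols without a map
#' entry are reported separately and excluded from downstream overlaps.
#' Matching is case-normalized on both sides.
#'
#' @param symbols character vector of species-B symbols.
#' @param map data.frame with columns \code{symbol_species_B} and
#'   \code{symbol_species_A}.
#' @return list with \code{mapped} (named character vector: input symbol ->
#'   reference symbol) and \code{unmapped} (character vector).
#' @export
mapOrthologs <- function(symbols, map) {
  stopifnot(all(c("symbol_species_B", "symbol_species_A") %in% colnames(map)))
  from <- normalizeSymbols(map$symbol_species_B)
  to <- normalizeSymbols(map$symbol_species_A)
  s <- normalizeSymbols(symbols)
  idx <- match(s, from)
  hit <- !is.na(idx)
  list(mapped = stats::setNames(to[idx[hit]], s[hit]),
       unmapped = unique(s[!hit]))
}

#' Overlap differential mRNA lists with a proteome symbol set
#'
#' Intersects the PX and IP differential gene lists with the (prefiltered,
#' ortholog-mapped) protein symbols and reports the per-fraction overlap
#' sets, their intersection and Venn counts. All matching is
#' case-normalized and duplicate-free.
#'
#' @param pxSymbols,ipSymbols differential gene symbols of the PX and IP
#'   fractions.
#' @param proteinSymbols proteome gene symbols (reference species).
#' @return list with \code{px} and \code{ip} overlap symbol vectors,
#'   \code{common} (their intersection), \code{counts} (named integer
#'   vector) and \code{venn} (the [vennCounts()] table of the two overlap
#'   sets).
#' @export
overlapMrnaProtein <- function(pxSymbols, ipSymbols, proteinSymbols) {
  px <- unique(normalizeSymbols(pxSymbols))
  ip <- unique(normalizeSymbols(ipSymbols))
  prot <- unique(normalizeSymbols(proteinSymbols))
  pxOv <- sort(intersect(px, prot))
  ipOv <- sort(intersect(ip, prot))
  list(px = pxOv, ip = ipOv, common = intersect(pxOv, ipOv),
       counts = c(px = length(pxOv), ip = length(ipOv),
                  common = length(intersect(pxOv, ipOv))),
       venn = vennCounts(px_overlap = pxOv, ip_overlap = ipOv))
}

#' Test whether proteome-backed mRNAs distribute unevenly over PX and IP
#'
#' Two-sided Fisher exact test on the 2x2 table
#' [overlap, non-overlap] x [PX, IP]: does the proportion of
#' proteome-represented mRNAs differ between the two peroxisomal lists?
#'
#' @param pxOverlap,ipOverlap overlap counts per fraction list.
#' @param pxSize,ipSize the corresponding list sizes.
#' @return two-sided p-value.
#' @examples
#' fractionDistributionTest(10, 10, 100, 100)  # 1: identical proportions
#' @export
fractionDistributionTest <- function(pxOverlap, ipOverlap, pxSize, ipSize) {
  if (pxOverlap > pxSize || ipOverlap > ipSize ||
      any(c(pxOverlap, ipOverlap, pxSize, ipSize) < 0))
    stop("inconsistent counts: overlaps must not exceed list sizes")
  fisherExactTwoSided(c(pxOverlap, pxSize - pxOverlap,
                        ipOverlap, ipSize - ipOverlap))
}

#' Flag symbols present in an RNA-binding-protein table
#'
#' @param symbols character vector of gene symbols.
#' @param rbpTable character vector of RBP symbols, or a data.frame whose
#'   first column holds them.
#' @return the (normalized) subset of \code{symbols} found in the table.
#' @export
rbpMembership <- function(symbols, rbpTable) {
  if (is.data.frame(rbpTable)) rbpTable <- rbpTable[[1L]]
  s <- unique(normalizeSymbols(symbols))
  s[s %in% normalizeSymbols(rbpTable)]
}
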