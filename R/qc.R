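#' Principal component QC with varimax rotation
#'
#' Covariance PCA with samples as observations (probes as variables) on
#' natural-log intensities, reporting the variance fraction of every
#' component, followed by an orthogonal varimax rotation of the top-k
#' loadings (scores recomputed accordingly). The rotation redistributes
#' variance inside the retained subspace but preserves its total, so the
#' overall variance fractions describe the unrotated decomposition.
#'
#' @param object a (typically background-corrected and normalized)
#'   \linkS4class{FractionExperiment}.
#' @param k number of components to retain and rotate (default 3).
#' @param logTransform take natural logs of the intensities first
#'   (default TRUE; values are floored at the smallest positive entry
#'   before the log, which is a no-op on floored data).
#' @return a \linkS4class{PcaSummary}.
#' @export
pcaVariance <- function(object, k = 3L, logTransform = TRUE) {
  stopifnot(is(object, "FractionExperiment"))
  x <- t(intensity(object)[!isNegativeControl(object), , drop = FALSE])
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  if (k > nrow(x)) stop("k exceeds the number of samples")
  if (logTransform) {
    x[x < min(x[x > 0])] <- min(x[x > 0])
    x <- log(x)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  vf <- v / sum(v)
  k <- min(k, ncol(pc$rotation))
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  S <- pc$x[, seq_len(k), drop = FALSE]
  if (k >= 2L) {
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-6)
    rot <- vm$rotmat
    L <- L %*% rot
    S <- S %*% rot
  } else {
    rot <- diag(1)
  }
  new("PcaSummary", varianceFraction = vf, loadings = L, scores = S,
      rotation = rot)
}

setMethod("show", "PcaSummary", function(object) {
  vf <- object@varianceFraction
  cat("PcaSummary:", length(vf), "components;",
      ncol(object@loadings), "rotated\n")
  cat("  top variance fractions:",
      paste(sprintf("%.3f", utils::head(vf, 4)), collapse = ", "), "\n")
})

#' Spike-in normalized qPCR profile across gradient fractions
#'
#' Normalizes each fraction's target Ct to the spike-in control Ct of the
#' same fraction (Thr spike-in added equally to every fraction before RNA
#' extraction), converts to relative levels assuming perfect doubling per
#' cycle, and expresses each fraction as the percentage of the summed
#' signal: level_f = 2^-(Ct_target,f - Ct_spike,f),
#' percent_f = 100 * level_f / sum(levels).
#'
#' @param ctTarget,ctSpike positive Ct vectors, one value per gradient
#'   fraction (typically 18 fractions), pairwise matched.
#' @param fraction optional fraction labels (default 1..n).
#' @return data.frame with fraction, delta_ct, relative_level, percent;
#'   the percents sum to 100.
#' @examples
#' p <- qpcrFractionProfile(rep(20, 18), rep(15, 18))
#' p$percent[1]  # 100/18
#' @export
qpcrFractionProfile <- function(ctTarget, ctSpike,
                                fraction = seq_along(ctTarget)) {
  if (length(ctTarget) != length(ctSpike))
    stop("target and spike-in Ct vectors must pair per fraction")
  if (!length(ctTarget)) stop("need at least one fraction")
  if (anyNA(ctSpike)) stop("missing spike-in Ct")
  if (anyNA(ctTarget)) stop("missing target Ct")
  if (any(ctTarget <= 0) || any(ctSpike <= 0))
    stop("Ct values must be positive")
  dct <- ctTarget - ctSpike
  level <- 2^(-dct)
  data.frame(fraction = fraction, delta_ct = dct, relative_level = level,
             percent = 100 * level / sum(level))
}
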