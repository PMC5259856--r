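# Independent oracles used across the suite. These deliberately avoid the
# code paths (and the distribution functions) used by the implementation:
# Fisher probabilities come from explicit binomial-coefficient enumeration,
# the BY adjustment from the step-up formula written out directly, and the
# OLS fit from a refined grid search over the squared loss.

# exact hypergeometric point probability via choose()
.pointProb <- function(x, a, b, c, d) {
  N <- a + b + c + d
  choose(a + c, x) * choose(b + d, a + b - x) / choose(N, a + b)
}

oracleFisherGreater <- function(a, b, c, d) {
  support <- max(0, a + b - (b + d)):min(a + b, a + c)
  sum(.pointProb(support[support >= a], a, b, c, d))
}

oracleFisherTwoSided <- function(a, b, c, d) {
  support <- max(0, a + b - (b + d)):min(a + b, a + c)
  probs <- .pointProb(support, a, b, c, d)
  pObs <- .pointProb(a, a, b, c, d)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

oracleBY <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  # step-up: running minimum from the largest rank down
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# brute-force minimizer of sum((y - a*x - b)^2) over a refined 2-D grid.
# The loss is evaluated on centred data, where it equals
# sum((yc - a*xc - c)^2) exactly with b = c + mean(y) - a*mean(x); this
# keeps the grid axes orthogonal so refinement cannot lose the optimum.
# Returns c(a, b, resA, resB) with the final grid resolutions.
oracleGridOLS <- function(x, y, span = 5, steps = 4L, gridN = 41L) {
  xc <- x - mean(x); yc <- y - mean(y)
  aRange <- c(-span, span) * max(1, diff(range(y)) / max(diff(range(x)), 1e-8))
  cRange <- c(-1, 1) * diff(range(y))
  for (s in seq_len(steps)) {
    aGrid <- seq(aRange[1], aRange[2], length.out = gridN)
    cGrid <- seq(cRange[1], cRange[2], length.out = gridN)
    sse <- matrix(NA_real_, gridN, gridN)
    for (i in seq_len(gridN))
      for (j in seq_len(gridN))
        sse[i, j] <- sum((yc - aGrid[i] * xc - cGrid[j])^2)
    ij <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    aBest <- aGrid[ij[1]]; cBest <- cGrid[ij[2]]
    da <- diff(aGrid)[1]; dc <- diff(cGrid)[1]
    aRange <- aBest + c(-2, 2) * da
    cRange <- cBest + c(-2, 2) * dc
  }
  c(a = aBest, b = cBest + mean(y) - aBest * mean(x),
    resA = da, resB = dc + abs(mean(x)) * da)
}

# shared small generator config so tests stay fast; ... overrides defaults
smallConfig <- function(...) {
  args <- list(nProbes = 800L, nNegativeControls = 80L,
               plantedEnrichments = data.frame(fraction = "PX",
                                               size = 20L,
                                               fold_change = 4),
               plantedTermSize = 50L, plantedTermOverlap = 10L,
               msTableSize = 120L, msOverlapSize = 8L, seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulationConfig, args)
}
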