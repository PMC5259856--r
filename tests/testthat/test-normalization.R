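makeFe <- function(values, types, reps = NULL, controls = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  colnames(values) <- paste0(types, "_", ave(seq_along(types), types,
                                             FUN = seq_along))
  if (is.null(reps)) reps <- ave(seq_along(types), types, FUN = seq_along)
  if (is.null(controls)) controls <- rep(FALSE, nrow(values))
  sym <- ifelse(controls, NA_character_, rownames(values))
  FractionExperiment(values, types, as.integer(reps), sym, controls)
}

test_that("background correction subtracts the control mean and floors", {
  values <- rbind(P1 = c(100, 50), P2 = c(5, 30),
                  N1 = c(10, 8), N2 = c(12, 10), N3 = c(14, 12))
  fe <- makeFe(values, c("T", "T"), controls = c(F, F, T, T, T))
  corr <- backgroundCorrect(fe, floor = 0.5)
  expect_equal(unname(intensity(corr)["P1", 1]), 88)      # 100 - mean(10,12,14)
  expect_equal(unname(intensity(corr)["P2", 1]), 0.5)     # 5 - 12 floored
  expect_equal(unname(intensity(corr)["P1", 2]), 40)      # 50 - mean(8,10,12)
  expect_equal(nrow(corr), 2L)                            # controls dropped
  expect_error(backgroundCorrect(corr), "no negative-control")
  expect_error(backgroundCorrect(fe, floor = -1), "floor")
})

test_that("corrected values recover the planted per-array offset", {
  cfg <- smallConfig()
  sim <- generateDataset(cfg)
  corr <- backgroundCorrect(sim$experiment)
  est <- S4Vectors::metadata(corr)$background$control_means
  # control mean estimates the offset within its standard error
  tol <- 5 * cfg@backgroundSd / sqrt(cfg@nNegativeControls)
  expect_lt(max(abs(est - sim$truth@offsets)), tol)
})

test_that("coefficient of variation uses the n-1 convention", {
  expect_equal(coefficientOfVariation(c(5, 5, 5)), 0)
  expect_equal(coefficientOfVariation(c(1, 2, 3)), 0.5)
  expect_error(coefficientOfVariation(c(1)), "at least 2")
  expect_error(coefficientOfVariation(c(-2, 0, 2)), "positive")
  # two-pass oracle on random vectors
  set.seed(42)
  for (i in 1:50) {
    v <- rlnorm(3, 5, 0.4)
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(coefficientOfVariation(v), s / m)
  }
})

test_that("invariant selection takes the k lowest-CV probes deterministically", {
  set.seed(1)
  values <- matrix(rlnorm(30, 5, 0.5), 10, 3)
  values[2, ] <- 100; values[5, ] <- 200; values[9, ] <- 300  # constant probes
  fe <- makeFe(values, c("T", "T", "T"))
  expect_setequal(selectInvariantGenes(fe, "T", 3L),
                  c("P02", "P05", "P09"))
  expect_setequal(selectInvariantGenes(fe, "T", 10L), rownames(fe))
  expect_error(selectInvariantGenes(fe, "T", 11L), "exceeds")
  # ties at the boundary break lexicographically
  tied <- makeFe(matrix(rep(c(7, 7, 3, 9, 5), 2), 5, 2), c("T", "T"))
  expect_identical(selectInvariantGenes(tied, "T", 3L),
                   c("P01", "P02", "P03"))
})

test_that("invariant selection recovers the planted invariant probes", {
  cfg <- smallConfig()  # 144 invariant probes >= 2k for k = 70
  sim <- generateDataset(cfg)
  corr <- backgroundCorrect(sim$experiment)
  for (tp in c("T", "PX")) {
    sel <- selectInvariantGenes(corr, tp, 70L)
    expect_gte(mean(sel %in% sim$truth@invariantProbes), 0.9)
  }
})

test_that("pairing intersects per-type sets and flags emptiness", {
  ps <- pairInvariantSet(c("A", "B", "C"), c("B", "C", "D"), c("PX", "T"))
  expect_identical(ps@intersection, c("B", "C"))
  same <- pairInvariantSet(c("A", "B"), c("B", "A"), c("PX", "T"))
  expect_setequal(same@intersection, c("A", "B"))
  expect_warning(disj <- pairInvariantSet("A", "B", c("PX", "T")), "empty")
  expect_length(disj@intersection, 0L)
  expect_error(fitInvariantRegression(numeric(0), numeric(0)), "at least 2")
})

test_that("the regression minimizes the printed squared loss", {
  f <- fitInvariantRegression(2 * (1:5) + 1, 1:5)
  expect_equal(f@slope, 2)
  expect_equal(f@intercept, 1)
  expect_equal(f@rss, 0)
  expect_equal(f@medianIndependent, 3)
  fConst <- fitInvariantRegression(rep(7, 4), 1:4)
  expect_equal(fConst@slope, 0)
  expect_equal(fConst@intercept, 7)
  expect_error(fitInvariantRegression(1:3, c(2, 2, 2)), "zero variance")
})

test_that("fitted coefficients match a grid-search minimizer of the loss", {
  set.seed(7)
  for (i in 1:100) {
    x <- runif(20, 10, 100)
    y <- runif(1, -3, 3) * x + runif(1, -50, 50) + rnorm(20, 0, 5)
    fit <- fitInvariantRegression(y, x)
    g <- oracleGridOLS(x, y)
    expect_lt(abs(fit@slope - g["a"]), g["resA"] + 1e-9)
    expect_lt(abs(fit@intercept - g["b"]), g["resB"] + 1e-9)
  }
})

test_that("scale equivariance: a common rescaling moves b, not a", {
  set.seed(8)
  x <- runif(30, 50, 500)
  y <- 1.4 * x + 20 + rnorm(30, 0, 10)
  f1 <- fitInvariantRegression(y, x)
  f2 <- fitInvariantRegression(10 * y, 10 * x)
  expect_equal(f2@slope, f1@slope)
  expect_equal(f2@intercept, 10 * f1@intercept)
  expect_equal(f2@medianIndependent, 10 * f1@medianIndependent)
})

test_that("applying the fitted map inverts an exact affine distortion", {
  ind <- matrix(c(10, 20, 30, 40, 11, 21, 31, 41), 4, 2)
  dep <- 2 * ind + 1
  values <- cbind(dep, ind)
  fe <- makeFe(values, c("PX", "PX", "T", "T"))
  fit <- fitInvariantRegression(
    stats::setNames(apply(dep, 1, median), rownames(fe)),
    stats::setNames(apply(ind, 1, median), rownames(fe)),
    pair = c("PX", "T"))
  out <- applyPairNormalization(fe, fit, "PX", floor = 1e-9)
  expect_equal(intensity(out)[, 1:2], intensity(fe)[, 3:4],
               ignore_attr = TRUE)
  expect_equal(intensity(out)[, 3:4], intensity(fe)[, 3:4])  # ref untouched
  # identity fit leaves the matrix unchanged
  idFit <- fitInvariantRegression(
    stats::setNames(apply(ind, 1, median), rownames(fe)),
    stats::setNames(apply(ind, 1, median), rownames(fe)),
    pair = c("PX", "T"))
  feId <- makeFe(cbind(ind, ind), c("PX", "PX", "T", "T"))
  expect_equal(intensity(applyPairNormalization(feId, idFit, "PX",
                                                floor = 1e-9)),
               intensity(feId))
  badFit <- fit; badFit@slope <- -1
  expect_error(applyPairNormalization(fe, badFit, "PX"), "orientation")
})

test_that("pair normalization recovers the planted gain ratio", {
  cfg <- smallConfig()
  sim <- generateDataset(cfg)
  corr <- backgroundCorrect(sim$experiment)
  st <- sampleType(sim$experiment)
  for (pair in list(c("PX", "T"), c("ML", "T"))) {
    norm <- normalizePair(corr, pair[1], pair[2], k = 70L)
    fit <- S4Vectors::metadata(norm)$fits[[1]]
    gRatio <- sim$truth@gains[st == pair[1]][1] /
      sim$truth@gains[st == pair[2]][1]
    expect_lt(abs(fit@slope - gRatio) / gRatio, 0.05)
    # after normalization the invariant-set medians agree
    inv <- S4Vectors::metadata(norm)$invariantSet@intersection
    x <- intensity(norm)[inv, ]
    stn <- sampleType(norm)
    depMed <- median(apply(x[, stn == pair[1]], 1, median))
    indMed <- median(apply(x[, stn == pair[2]], 1, median))
    expect_lt(abs(depMed - indMed) / indMed, 0.01)
  }
})

test_that("normalization shrinks the between-type invariant median gap", {
  for (s in 1:5) {
    cfg <- smallConfig(seed = 20L + s)
    sim <- generateDataset(cfg)
    corr <- backgroundCorrect(sim$experiment)
    norm <- normalizePair(corr, "PX", "T", k = 70L)
    inv <- S4Vectors::metadata(norm)$invariantSet@intersection
    st0 <- sampleType(corr)
    gap <- function(x, st) {
      abs(median(apply(x[inv, st == "PX"], 1, median)) -
          median(apply(x[inv, st == "T"], 1, median)))
    }
    expect_lte(gap(intensity(norm), sampleType(norm)),
               gap(intensity(corr), st0) + 1e-9)
  }
})
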