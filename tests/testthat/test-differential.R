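test_that("strict dominance requires every A value above every B value", {
  expect_true(strictDominance(c(4, 5, 6), c(1, 1, 2)))
  expect_false(strictDominance(c(3, 5, 6), c(1, 3, 2)))  # tie fails
  expect_error(strictDominance(numeric(0), 1), "non-empty")
  # exhaustive pairwise-comparison oracle on random triples
  set.seed(5)
  for (i in 1:200) {
    a <- sample(1:8, 3, replace = TRUE)
    b <- sample(1:8, 3, replace = TRUE)
    oracle <- all(outer(a, b, `>`))
    expect_identical(strictDominance(a, b), oracle)
  }
})

test_that("fold change is the ratio of group medians", {
  expect_equal(foldChange(c(4, 5, 6), c(1, 1, 2)), 5)
  expect_equal(foldChange(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(foldChange(c(2, 8), c(1, 3)), 2.5)  # even-count medians 5, 2
  expect_error(foldChange(c(1, 2), c(-1, 0)), "positive")
})

test_that("calls obey threshold nesting, anti-symmetry and label invariance", {
  cfg <- smallConfig()
  sim <- generateDataset(cfg)
  norm <- normalizePair(backgroundCorrect(sim$experiment), "PX", "T",
                        k = 70L)
  c2 <- callDifferential(norm, "PX", "T", 2)
  c4 <- callDifferential(norm, "PX", "T", 4)
  expect_true(all(c4$probe_id %in% c2$probe_id))
  expect_true(all(c2$fold_change >= 2))
  expect_true(all(c4$fold_change >= 4))
  rev2 <- callDifferential(norm, "T", "PX", 2)
  expect_length(intersect(c2$probe_id, rev2$probe_id), 0L)
  # permuting replicate columns within a type changes nothing
  st <- sampleType(norm)
  perm <- seq_len(ncol(norm))
  px <- which(st == "PX")
  perm[px] <- px[c(2, 3, 1)]
  expect_identical(callDifferential(norm[, perm], "PX", "T", 2), c2)
  expect_error(callDifferential(norm, "PX", "XX", 2), "unknown sample type")
})

test_that("planted fold-change genes are recovered with few false calls", {
  cfg <- smallConfig(plantedEnrichments = data.frame(fraction = "PX",
                                                     size = 50L,
                                                     fold_change = 4))
  sim <- generateDataset(cfg)
  norm <- normalizePair(backgroundCorrect(sim$experiment), "PX", "T",
                        k = 70L)
  calls <- callDifferential(norm, "PX", "T", 2)
  planted <- sim$truth@plantedGenes$probe_id
  sens <- mean(planted %in% calls$probe_id)
  fpr <- sum(!calls$probe_id %in% planted) / (nrow(norm) - length(planted))
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.01)
})

test_that("noise-free planted genes are called exactly at their fold change", {
  cfg <- simulationConfig(nProbes = 300L, nNegativeControls = 30L,
                          noiseLogSd = 0, typeEffectLogSd = 0,
                          gainRange = c(1, 1), offsetRange = c(0, 0),
                          backgroundSd = 0,
                          plantedEnrichments = data.frame(fraction = "PX",
                                                          size = 10L,
                                                          fold_change = 4),
                          plantedTermOverlap = 5L, msOverlapSize = 5L,
                          seed = 9L)
  sim <- generateDataset(cfg)
  # identity distortion: background-corrected data is already on one scale
  calls <- callDifferential(backgroundCorrect(sim$experiment), "PX", "T", 4)
  expect_setequal(calls$probe_id, sim$truth@plantedGenes$probe_id)
})

test_that("gene-symbol collapse keeps the probe with the highest baseline", {
  values <- rbind(P1 = c(40, 44, 42, 10, 9, 11),
                  P2 = c(80, 82, 84, 20, 21, 19),
                  P3 = c(500, 510, 490, 100, 101, 99))
  fe <- FractionExperiment(
    `colnames<-`(values, paste0(rep(c("PX", "T"), each = 3), "_", 1:3)),
    rep(c("PX", "T"), each = 3), rep(1:3, 2),
    c("GENEA", "GENEA", "GENEB"), rep(FALSE, 3))
  calls <- callDifferential(fe, "PX", "T", 2, collapse = TRUE)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$probe_id, c("P2", "P3"))  # P2 beats P1 for GENEA
})

test_that("venn regions partition the union", {
  v <- vennCounts(first = c("A", "B", "C"), second = c("B", "C", "D"))
  counts <- stats::setNames(v$count, paste(v$first, v$second))
  expect_equal(unname(counts["TRUE TRUE"]), 2L)
  expect_equal(unname(counts["TRUE FALSE"]), 1L)
  expect_equal(unname(counts["FALSE TRUE"]), 1L)
  same <- vennCounts(a = c("X", "Y"), b = c("Y", "X"))
  expect_equal(sum(same$count), 2L)
  expect_equal(same$count[same$a & same$b], 2L)
  expect_error(vennCounts(a = "A", b = "B", c = "C", d = "D"), "2 or 3")
  # bit-set oracle on random 3-list instances
  set.seed(12)
  for (i in 1:25) {
    ls <- lapply(1:3, function(j) sample(LETTERS, sample(3:15, 1)))
    names(ls) <- c("x", "y", "z")
    v <- vennCounts(ls)
    universe <- unique(unlist(ls))
    code <- sapply(universe, function(g)
      sum(c(4, 2, 1) * vapply(ls, function(s) g %in% s, logical(1))))
    for (r in seq_len(nrow(v))) {
      want <- sum(c(4, 2, 1) * unlist(v[r, 1:3]))
      expect_equal(v$count[r], sum(code == want))
    }
    expect_equal(sum(v$count), length(universe))
  }
})
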