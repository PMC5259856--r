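test_that("identical configs give bit-identical datasets", {
  cfg <- smallConfig()
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(intensity(a$experiment), intensity(b$experiment))
  expect_identical(a$truth@plantedGenes, b$truth@plantedGenes)
  expect_identical(a$truth@gains, b$truth@gains)
  annA <- generateAnnotation(cfg, a$truth)
  annB <- generateAnnotation(cfg, b$truth)
  expect_identical(geneSets(annA$annotation), geneSets(annB$annotation))
  msA <- generateMSTables(cfg, annA$truth)
  msB <- generateMSTables(cfg, annB$truth)
  expect_identical(msA$speciesA, msB$speciesA)
  expect_identical(msA$speciesB, msB$speciesB)
})

test_that("generated dimensions and control counts match the config", {
  cfg <- smallConfig()
  sim <- generateDataset(cfg)
  fe <- sim$experiment
  expect_equal(nrow(fe), 800L)
  expect_equal(sum(isNegativeControl(fe)), 80L)
  expect_equal(ncol(fe), 4L * 3L)
  expect_true(all(table(sampleType(fe)) == 3L))
  expect_true(all(is.na(geneSymbols(fe)[isNegativeControl(fe)])))
  expect_true(all(sim$truth@plantedGenes$probe_id %in% rownames(fe)))
  expect_true(all(sim$truth@invariantProbes %in% rownames(fe)))
})

test_that("with zero noise and identity distortion the planted fold change is exact", {
  cfg <- simulationConfig(nProbes = 200L, nNegativeControls = 20L,
                          noiseLogSd = 0, typeEffectLogSd = 0,
                          gainRange = c(1, 1), offsetRange = c(0, 0),
                          backgroundSd = 0,
                          plantedEnrichments = data.frame(fraction = "PX",
                                                          size = 1L,
                                                          fold_change = 4),
                          plantedTermOverlap = 1L, msOverlapSize = 1L,
                          seed = 3L)
  sim <- generateDataset(cfg)
  x <- intensity(sim$experiment)
  st <- sampleType(sim$experiment)
  g <- sim$truth@plantedGenes$probe_id
  ratio <- median(x[g, st == "PX"]) / median(x[g, st == "T"])
  expect_identical(ratio, 4)
  # non-planted genes are untouched across types
  other <- setdiff(rownames(x)[!isNegativeControl(sim$experiment)], g)
  expect_equal(max(abs(x[other, st == "PX"][, 1] - x[other, st == "T"][, 1])),
               0)
})

test_that("recorded gains and offsets reproduce the applied distortion", {
  cfg <- smallConfig()
  distorted <- generateDataset(cfg)
  # same seed, identity distortion: gene-level draws come first in the
  # stream, so only gain/offset differ between the two datasets
  cfgId <- smallConfig(gainRange = c(1, 1), offsetRange = c(0, 0))
  clean <- generateDataset(cfgId)
  keep <- !isNegativeControl(distorted$experiment)
  obs <- intensity(distorted$experiment)[keep, ]
  pre <- intensity(clean$experiment)[keep, ]
  undone <- sweep(sweep(obs, 2, distorted$truth@offsets, `-`),
                  2, distorted$truth@gains, `/`)
  expect_equal(undone, pre, tolerance = 1e-12)
})

test_that("planted gene sets obey the config invariants", {
  cfg <- simulationConfig(nProbes = 400L, nNegativeControls = 40L,
                          plantedEnrichments = data.frame(
                            fraction = c("PX", "IP"), size = c(15L, 10L),
                            fold_change = c(4, 2.5)),
                          plantedTermOverlap = 5L, msOverlapSize = 5L,
                          seed = 2L)
  sim <- generateDataset(cfg)
  pg <- sim$truth@plantedGenes
  expect_equal(nrow(pg), 25L)
  expect_false(anyDuplicated(pg$probe_id) > 0)
  expect_length(intersect(pg$probe_id, sim$truth@invariantProbes), 0)
  # invalid configs are rejected
  expect_error(simulationConfig(plantedEnrichments = data.frame(
    fraction = "PX", size = 5L, fold_change = 1)), "exceed 1")
  expect_error(simulationConfig(plantedEnrichments = data.frame(
    fraction = c("PX", "PX"), size = c(5L, 5L), fold_change = c(2, 4))),
    "disjoint")
  expect_error(simulationConfig(nNegativeControls = 5000L), "nNegativeControls")
})

test_that("annotation plants exactly the configured overlap", {
  cfg <- smallConfig()
  sim <- generateDataset(cfg)
  ann <- generateAnnotation(cfg, sim$truth)
  sets <- geneSets(ann$annotation)
  expect_gte(length(sets), 20L)
  planted <- sets[[ann$truth@plantedTerm]]
  expect_length(planted, 50L)
  inPlanted <- intersect(planted, sim$truth@plantedGenes$gene_symbol)
  expect_length(inPlanted, 10L)
  # background terms avoid planted genes entirely
  others <- sets[setdiff(names(sets), ann$truth@plantedTerm)]
  expect_length(intersect(unlist(others),
                          sim$truth@plantedGenes$gene_symbol), 0)
  expect_error(generateAnnotation(
    smallConfig(plantedTermOverlap = 21L), sim$truth), "exceeds")
})

test_that("MS tables hit the configured failure rate and share the overlap", {
  cfg <- smallConfig(msTableSize = 1000L, msFailureRate = 0.3)
  sim <- generateDataset(cfg)
  ms <- generateMSTables(cfg, sim$truth)
  tab <- ms$speciesA
  failed <- tab$n_peptides < 2 | tab$coverage_pct < 10
  nBg <- nrow(tab) - length(ms$truth@msOverlapGenes)
  # binomial 3.5-sigma interval around 0.3 * nBg
  expect_lt(abs(sum(failed) - 0.3 * nBg), 3.5 * sqrt(nBg * 0.3 * 0.7))
  # overlap symbols present and guaranteed to pass in both species
  ov <- ms$truth@msOverlapGenes
  expect_length(ov, 8L)
  expect_true(all(ov %in% tab$gene_symbol))
  passA <- tab[tab$n_peptides >= 2 & tab$coverage_pct >= 10, ]
  expect_true(all(ov %in% passA$gene_symbol))
  expect_true(all(paste0("H", ov) %in% ms$speciesB$gene_symbol))
  # every species-B symbol is resolvable through the emitted map
  expect_true(all(ms$speciesB$gene_symbol %in% ms$orthologMap$symbol_species_B))
  # zero overlap propagates
  cfg0 <- smallConfig(msOverlapSize = 0L)
  ms0 <- generateMSTables(cfg0, generateDataset(cfg0)$truth)
  expect_length(ms0$truth@msOverlapGenes, 0L)
})

test_that("without planted signal the dominance rule fires near chance level", {
  # combinatorial chance for 3 vs 3 replicates is 3!3!/6! = 1/20; the
  # small shared biological drift between types may inflate it, but the
  # rate must stay below twice the chance level
  rates <- vapply(1:20, function(s) {
    cfg <- simulationConfig(nProbes = 1500L, nNegativeControls = 100L,
                            plantedEnrichments = data.frame(
                              fraction = character(), size = integer(),
                              fold_change = numeric()),
                            plantedTermOverlap = 0L, msOverlapSize = 0L,
                            seed = 100L + s)
    sim <- generateDataset(cfg)
    corr <- backgroundCorrect(sim$experiment)
    norm <- normalizePair(corr, "PX", "T", k = 300L)
    x <- intensity(norm)
    st <- sampleType(norm)
    dom <- apply(x[, st == "PX"], 1L, min) > apply(x[, st == "T"], 1L, max)
    mean(dom)
  }, numeric(1))
  expect_lt(mean(rates), 2 / 20)
})
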