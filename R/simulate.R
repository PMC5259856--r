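#' Create a synthetic-data configuration
#'
#' Builds a \linkS4class{SimulationConfig} with defaults emulating the study
#' design: 4 fraction types (T, ML, PX, IP) x 3 technical replicates,
#' log-normal probe abundances, per-array affine distortions, a core of
#' low-variability invariant genes, negative-control probes carrying only
#' additive background, planted fraction-enriched genes at fold change 4,
#' one planted annotation term, and a planted mRNA-protein overlap.
#'
#' @param nProbes,nNegativeControls total probes and how many of them are
#'   negative controls.
#' @param sampleTypes,nReplicates fraction design.
#' @param baselineLogMean,baselineLogSd log-normal abundance model
#'   (natural-log scale).
#' @param noiseLogSd replicate-level multiplicative noise sd (log scale).
#' @param invariantNoiseFactor noise shrinkage on invariant genes.
#' @param typeEffectLogSd per-type biological effect sd on non-invariant
#'   genes (log scale).
#' @param invariantFraction share of gene probes that are invariant.
#' @param gainRange,offsetRange per-array gain and offset ranges.
#' @param backgroundSd sd of negative-control background noise.
#' @param plantedEnrichments data.frame(fraction, size, fold_change).
#' @param nTerms,termSizeRange,plantedTermSize,plantedTermOverlap annotation
#'   generator settings.
#' @param msTableSize,msOverlapSize,msFailureRate MS-table generator
#'   settings.
#' @param seed integer seed; all randomness of the generator flows from it.
#'
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nProbes = 5000L,
                             nNegativeControls = 200L,
                             sampleTypes = c("T", "ML", "PX", "IP"),
                             nReplicates = 3L,
                             baselineLogMean = 7,
                             baselineLogSd = 1,
                             noiseLogSd = 0.05,
                             invariantNoiseFactor = 0.1,
                             typeEffectLogSd = 0.02,
                             invariantFraction = 0.2,
                             gainRange = c(0.5, 2),
                             offsetRange = c(20, 80),
                             backgroundSd = 2,
                             plantedEnrichments = data.frame(
                               fraction = c("PX", "IP"),
                               size = c(50L, 30L),
                               fold_change = c(4, 4)),
                             nTerms = 25L,
                             termSizeRange = c(20L, 100L),
                             plantedTermSize = 50L,
                             plantedTermOverlap = 10L,
                             msTableSize = 300L,
                             msOverlapSize = 12L,
                             msFailureRate = 0.3,
                             seed = 1L) {
  new("SimulationConfig",
      nProbes = as.integer(nProbes),
      nNegativeControls = as.integer(nNegativeControls),
      sampleTypes = as.character(sampleTypes),
      nReplicates = as.integer(nReplicates),
      baselineLogMean = baselineLogMean,
      baselineLogSd = baselineLogSd,
      noiseLogSd = noiseLogSd,
      invariantNoiseFactor = invariantNoiseFactor,
      typeEffectLogSd = typeEffectLogSd,
      invariantFraction = invariantFraction,
      gainRange = gainRange,
      offsetRange = offsetRange,
      backgroundSd = backgroundSd,
      plantedEnrichments = plantedEnrichments,
      nTerms = as.integer(nTerms),
      termSizeRange = as.integer(termSizeRange),
      plantedTermSize = as.integer(plantedTermSize),
      plantedTermOverlap = as.integer(plantedTermOverlap),
      msTableSize = as.integer(msTableSize),
      msOverlapSize = as.integer(msOverlapSize),
      msFailureRate = msFailureRate,
      seed = as.integer(seed))
}

#' Generate a synthetic fraction-array dataset with known ground truth
#'
#' Generative model, drawn in a fixed documented order from one seeded
#' stream (so identical configs give bit-identical output, and two configs
#' differing only in the distortion ranges share all gene-level draws):
#' \enumerate{
#'   \item true baseline abundances per gene probe: log-normal
#'     (\code{baselineLogMean}, \code{baselineLogSd});
#'   \item invariant probes: a random \code{invariantFraction} of gene
#'     probes; they carry no type effect and their replicate noise is
#'     shrunk by \code{invariantNoiseFactor};
#'   \item planted enriched genes: disjoint random sets per fraction,
#'     abundance multiplied by the configured fold change only in that
#'     fraction's samples;
#'   \item per-type biological effects on non-invariant genes
#'     (log-normal, sd \code{typeEffectLogSd});
#'   \item replicate-level multiplicative noise (log-normal, sd
#'     \code{noiseLogSd});
#'   \item per-array gain and offset, uniform on the configured ranges;
#'     a sample type's technical replicates are processed as one batch,
#'     so they share their type's gain and offset (the pairwise affine
#'     normalization model is then exactly well-posed);
#'   \item negative-control background noise (normal, sd
#'     \code{backgroundSd}, truncated at 0 after adding the offset).
#' }
#' Observed gene-probe values are \code{true * noise * gain + offset};
#' negative controls carry only \code{offset + background}, truncated at 0.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{FractionExperiment}) and \code{truth}
#'   (\linkS4class{SimulationTruth}).
#' @examples
#' sim <- generateDataset(simulationConfig(nProbes = 200,
#'                                         nNegativeControls = 20,
#'                                         plantedEnrichments = data.frame(
#'                                           fraction = "PX", size = 5L,
#'                                           fold_change = 4)))
#' sim$experiment
#' @export
generateDataset <- function(config) {
  validObject(config)
  nGene <- config@nProbes - config@nNegativeControls
  nSamp <- length(config@sampleTypes) * config@nReplicates
  probeIds <- sprintf("PR%05d", seq_len(nGene))
  symbols <- sprintf("GENE%05d", seq_len(nGene))
  ctrlIds <- sprintf("NC%04d", seq_len(config@nNegativeControls))
  types <- rep(config@sampleTypes, each = config@nReplicates)
  reps <- rep(seq_len(config@nReplicates), length(config@sampleTypes))
  sampleIds <- paste0(types, "_", reps)

  pe <- config@plantedEnrichments
  res <- withSeed(config@seed, {
    baseline <- exp(stats::rnorm(nGene, config@baselineLogMean,
                                 config@baselineLogSd))
    nInv <- round(config@invariantFraction * config@nProbes)
    nInv <- min(nInv, nGene)
    invIdx <- sort(sample.int(nGene, nInv))
    pool <- setdiff(seq_len(nGene), invIdx)
    planted <- data.frame(probe_id = character(), gene_symbol = character(),
                          fraction = character(), fold_change = numeric(),
                          stringsAsFactors = FALSE)
    if (nrow(pe)) {
      for (r in seq_len(nrow(pe))) {
        if (pe$size[r] > length(pool))
          stop("not enough non-invariant genes left to plant enrichment in ",
               pe$fraction[r])
        idx <- sort(sample(pool, pe$size[r]))
        pool <- setdiff(pool, idx)
        planted <- rbind(planted, data.frame(
          probe_id = probeIds[idx], gene_symbol = symbols[idx],
          fraction = pe$fraction[r], fold_change = pe$fold_change[r],
          stringsAsFactors = FALSE))
      }
    }
    typeEffect <- matrix(stats::rnorm(nGene * length(config@sampleTypes),
                                      0, config@typeEffectLogSd),
                         nGene, length(config@sampleTypes),
                         dimnames = list(probeIds, config@sampleTypes))
    typeEffect[invIdx, ] <- 0
    noiseSd <- rep(config@noiseLogSd, nGene)
    noiseSd[invIdx] <- config@noiseLogSd * config@invariantNoiseFactor
    noise <- matrix(stats::rnorm(nGene * nSamp), nGene, nSamp) * noiseSd
    nType <- length(config@sampleTypes)
    typeGain <- stats::runif(nType, config@gainRange[1], config@gainRange[2])
    typeOffset <- stats::runif(nType, config@offsetRange[1],
                               config@offsetRange[2])
    gains <- rep(typeGain, each = config@nReplicates)
    offsets <- rep(typeOffset, each = config@nReplicates)
    bg <- matrix(stats::rnorm(config@nNegativeControls * nSamp,
                              0, config@backgroundSd),
                 config@nNegativeControls, nSamp)
    list(baseline = baseline, invIdx = invIdx, planted = planted,
         typeEffect = typeEffect, noise = noise, gains = gains,
         offsets = offsets, bg = bg)
  })

  trueAbund <- res$baseline * exp(res$typeEffect[, types, drop = FALSE])
  if (nrow(res$planted)) {
    for (r in seq_len(nrow(res$planted))) {
      i <- match(res$planted$probe_id[r], probeIds)
      j <- types == res$planted$fraction[r]
      trueAbund[i, j] <- trueAbund[i, j] * res$planted$fold_change[r]
    }
  }
  geneValues <- sweep(sweep(trueAbund * exp(res$noise), 2, res$gains, `*`),
                      2, res$offsets, `+`)
  ctrlValues <- pmax(sweep(res$bg, 2, res$offsets, `+`), 0)
  values <- rbind(geneValues, ctrlValues)
  rownames(values) <- c(probeIds, ctrlIds)
  colnames(values) <- sampleIds

  names(res$gains) <- names(res$offsets) <- sampleIds
  fe <- FractionExperiment(values, sampleType = types, replicate = reps,
                           geneSymbol = c(symbols,
                                          rep(NA_character_,
                                              config@nNegativeControls)),
                           isNegativeControl = c(rep(FALSE, nGene),
                                                 rep(TRUE,
                                                     config@nNegativeControls)))
  truth <- new("SimulationTruth",
               gains = res$gains, offsets = res$offsets,
               plantedGenes = res$planted,
               invariantProbes = probeIds[res$invIdx],
               geneSymbols = symbols,
               plantedTerm = "GS0001",
               plantedTermGenes = character(),
               msOverlapGenes = character(),
               seed = config@seed)
  list(experiment = fe, truth = truth)
}

#' Generate a synthetic annotation with one planted enriched term
#'
#' Emits \code{nTerms} gene sets over the simulated gene universe. The
#' planted term (id recorded in \code{truth@plantedTerm}) contains exactly
#' \code{plantedTermOverlap} planted-enriched genes plus background genes up
#' to \code{plantedTermSize}; all remaining terms are drawn uniformly from
#' non-planted genes, with sizes uniform on \code{termSizeRange}.
#' Deterministic given the config seed.
#'
#' @param config the \linkS4class{SimulationConfig} used for the dataset.
#' @param truth the matching \linkS4class{SimulationTruth}; returned updated
#'   with the planted term's genes via the \code{truth} element.
#' @return list with \code{annotation} (an \linkS4class{AnnotationSets}) and
#'   the updated \code{truth}.
#' @export
generateAnnotation <- function(config, truth) {
  validObject(config)
  plantedSyms <- unique(truth@plantedGenes$gene_symbol)
  if (config@plantedTermOverlap > length(plantedSyms))
    stop("plantedTermOverlap exceeds the number of planted genes")
  background <- setdiff(truth@geneSymbols, plantedSyms)
  nTerms <- max(config@nTerms, 20L)
  sets <- withSeed(config@seed + 1L, {
    inTerm <- sample(plantedSyms, config@plantedTermOverlap)
    filler <- sample(background,
                     config@plantedTermSize - config@plantedTermOverlap)
    sets <- vector("list", nTerms)
    sets[[1L]] <- sort(c(inTerm, filler))
    sizes <- sample(seq(config@termSizeRange[1], config@termSizeRange[2]),
                    nTerms - 1L, replace = TRUE)
    for (k in seq_len(nTerms - 1L))
      sets[[k + 1L]] <- sort(sample(background, sizes[k]))
    sets
  })
  names(sets) <- sprintf("GS%04d", seq_len(nTerms))
  ann <- new("AnnotationSets", sets = sets,
             descriptions = stats::setNames(
               sprintf("synthetic gene set %d", seq_len(nTerms)),
               names(sets)))
  truth@plantedTerm <- names(sets)[1L]
  truth@plantedTermGenes <- sets[[1L]][sets[[1L]] %in% plantedSyms]
  list(annotation = ann, truth = truth)
}

#' Generate synthetic mass-spectrometry protein tables
#'
#' Emits two protein tables ("species A" on the array's own symbols,
#' "species B" on foreign symbols related through a generated ortholog map)
#' plus that map. \code{msOverlapSize} symbols planted in the first
#' configured enrichment fraction are placed in both tables with values
#' guaranteed to pass the abundance prefilter (>= 2 peptides, >= 10\%
#' coverage); the remaining entries are drawn from non-planted genes and
#' fail the prefilter independently with probability \code{msFailureRate}.
#' Deterministic given the config seed.
#'
#' @param config the \linkS4class{SimulationConfig}.
#' @param truth the matching \linkS4class{SimulationTruth}; returned updated
#'   with the planted overlap symbols.
#' @return list with \code{speciesA} and \code{speciesB} data.frames
#'   (protein_id, gene_symbol, n_peptides, coverage_pct, species),
#'   \code{orthologMap} (symbol_species_B, symbol_species_A) and the
#'   updated \code{truth}.
#' @export
generateMSTables <- function(config, truth) {
  validObject(config)
  pg <- truth@plantedGenes
  pool <- if (nrow(pg)) unique(pg$gene_symbol[pg$fraction == pg$fraction[1]])
          else character()
  if (config@msOverlapSize > length(pool))
    stop("msOverlapSize exceeds the genes planted in the first fraction")
  background <- setdiff(truth@geneSymbols, unique(pg$gene_symbol))
  nBg <- max(config@msTableSize - config@msOverlapSize, 0L)

  sampleEntries <- function(symbols, forcePass, species) {
    n <- length(symbols)
    fail <- !forcePass & stats::runif(n) < config@msFailureRate
    peptides <- 2L + stats::rpois(n, 8)
    coverage <- stats::runif(n, 10, 80)
    failMode <- stats::runif(n) < 0.5
    peptides[fail & failMode] <- 1L
    coverage[fail & !failMode] <- stats::runif(sum(fail & !failMode), 0, 9.9)
    data.frame(protein_id = sprintf("PROT_%s_%04d", species, seq_len(n)),
               gene_symbol = symbols, n_peptides = peptides,
               coverage_pct = round(coverage, 1), species = species,
               stringsAsFactors = FALSE)
  }

  out <- withSeed(config@seed + 2L, {
    overlap <- if (config@msOverlapSize > 0L)
      sort(sample(pool, config@msOverlapSize)) else character()
    bgA <- sample(background, min(nBg, length(background)))
    bgB <- sample(background, min(nBg, length(background)))
    tabA <- sampleEntries(c(overlap, bgA),
                          forcePass = c(rep(TRUE, length(overlap)),
                                        rep(FALSE, length(bgA))), "A")
    tabB <- sampleEntries(c(overlap, bgB),
                          forcePass = c(rep(TRUE, length(overlap)),
                                        rep(FALSE, length(bgB))), "B")
    list(overlap = overlap, tabA = tabA, tabB = tabB)
  })
  # species-B symbols are foreign-species identifiers resolved by the map
  map <- data.frame(symbol_species_B = paste0("H", out$tabB$gene_symbol),
                    symbol_species_A = out$tabB$gene_symbol,
                    stringsAsFactors = FALSE)
  map <- unique(map)
  out$tabB$gene_symbol <- paste0("H", out$tabB$gene_symbol)
  truth@msOverlapGenes <- out$overlap
  list(speciesA = out$tabA, speciesB = out$tabB, orthologMap = map,
       truth = truth)
}

#' Generate the full synthetic bundle
#'
#' Convenience wrapper running [generateDataset()], [generateAnnotation()]
#' and [generateMSTables()] under one config, returning everything with a
#' consistent \linkS4class{SimulationTruth}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{experiment}, \code{annotation}, \code{speciesA},
#'   \code{speciesB}, \code{orthologMap}, \code{truth}.
#' @export
generateAll <- function(config) {
  sim <- generateDataset(config)
  ann <- generateAnnotation(config, sim$truth)
  ms <- generateMSTables(config, ann$truth)
  list(experiment = sim$experiment, annotation = ann$annotation,
       speciesA = ms$speciesA, speciesB = ms$speciesB,
       orthologMap = ms$orthologMap, truth = ms$truth)
}
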