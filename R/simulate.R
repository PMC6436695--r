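## Synthetic data with ground truth: DDA-style LCO runs and DE tables.
## All randomness sits behind a single seed argument; the previous RNG
## state is restored on exit so simulation does not disturb the caller.

.withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

.C13_SPACING <- 1.0033548  # 13C-12C mass difference, the envelope spacing

.sampleAdduct <- function(weights) {
  sample(names(weights), 1L, prob = weights)
}

.makeEnvelope <- function(pattern, monoMz, intensity, distortionSd) {
  ab <- pattern$abundance
  if (distortionSd > 0)
    ab <- ab * exp(stats::rnorm(length(ab), 0, distortionSd))
  data.frame(mz = monoMz + pattern$offset * .C13_SPACING,
             intensity = intensity * ab / max(ab))
}

.decoyFormula <- function(db, floorPpm, allMz, maxTries = 50L) {
  deltas <- list(ElementalFormula(C = 1L, H = 2L), ElementalFormula(O = 1L))
  for (try in seq_len(maxTries)) {
    i <- sample.int(nrow(db@table), 1L)
    f0 <- parseFormula(db@table$formula[i])
    d <- deltas[[sample.int(2L, 1L)]]
    f <- tryCatch(if (stats::runif(1) < 0.5) f0 + d else f0 - d,
                  error = function(e) NULL)
    if (is.null(f)) next
    mz <- adductMz(f, "M+H")
    if (min(abs(ppmError(mz, allMz))) >= floorPpm)
      return(list(formula = f, mz = mz))
  }
  stop("decoy construction failed after ", maxTries,
       " tries: candidate space too dense for the requested offset floor")
}

#' Simulate a DDA-style LC-MS/MS run of planted LCO structures
#'
#' Emulates a positive-mode data-dependent acquisition (top-N) run at the
#' peak-list level. Every planted structure contributes one precursor at
#' an adduct m/z perturbed by uniform ppm jitter, with its theoretical
#' isotope envelope perturbed multiplicatively (log-normal) by the
#' distortion scale. Decoy compounds are drawn as formula perturbations
#' (plus/minus CH2 or O) of random candidates and kept only if at least
#' `decoyFloorPpm` away from every database m/z; noise precursors with
#' shapeless envelopes are added at a Poisson rate. Precursors are put in
#' a random elution order, grouped into MS1 cycles, and the `topN` most
#' intense precursors of each cycle receive an MS2 spectrum (for planted
#' structures: their jittered B/Y fragment ions plus noise peaks).
#'
#' @param structures List of [LCOStructure-class] objects to plant.
#' @param db A [CandidateDB-class] used for decoy placement.
#' @param condition,sample Run labels.
#' @param jitterPpm Half-width of the uniform precursor/fragment mass
#'   jitter, in ppm (default 2).
#' @param distortionSd Log-normal sigma of the multiplicative envelope
#'   distortion (default 0.05).
#' @param nDecoys Number of decoy precursors (default 0).
#' @param decoyFloorPpm Minimum ppm distance of any decoy from every
#'   database m/z (default 20; must exceed the matching tolerance the run
#'   is meant to test).
#' @param noiseRate Poisson mean of the number of noise precursors.
#' @param topN DDA cycle size: precursors fragmented per MS1 scan
#'   (default 5).
#' @param scanSize Number of co-eluting precursors competing per MS1 scan
#'   (default 8).
#' @param adductWeights Named sampling weights over adducts for planted
#'   precursors.
#' @param envelopePeaks Envelope peaks generated per precursor.
#' @param seed Integer seed; identical seeds give identical runs.
#' @return A list with `run` (a [SpectrumRun-class]) and `truth` (data
#'   frame of planted `label`, `adduct`, `trueMz`, `observedMz`, plus
#'   attributes `decoyMz` and `seed`).
#' @export
simulateRun <- function(structures, db, condition = "condition",
                        sample = condition, jitterPpm = 2,
                        distortionSd = 0.05, nDecoys = 0L,
                        decoyFloorPpm = 20, noiseRate = 0, topN = 5L,
                        scanSize = 8L,
                        adductWeights = c("M+H" = 0.8, "M+Na" = 0.2),
                        envelopePeaks = 4L, seed = NULL) {
  stopifnot(jitterPpm >= 0, distortionSd >= 0, nDecoys >= 0)
  .withSeed(seed, {
    allMz <- unlist(lapply(db@adducts, function(a) db@table[[paste0("mz.", a)]]))
    meta <- list(); precs <- list()
    jit <- function(mz) mz * (1 + stats::runif(length(mz), -jitterPpm, jitterPpm) * 1e-6)
    for (s in structures) {
      f <- elementalFormula(s)
      a <- .sampleAdduct(adductWeights)
      trueMz <- adductMz(f, a)
      obsMz <- jit(trueMz)
      inten <- stats::rlnorm(1, log(1e6), 0.5)
      precs[[length(precs) + 1L]] <- list(
        precursorMz = obsMz, intensity = inten,
        envelope = .makeEnvelope(isotopePattern(f, envelopePeaks), obsMz,
                                 inten, distortionSd),
        ms2 = NULL)
      meta[[length(meta) + 1L]] <- list(kind = "planted",
                                        label = structureLabel(s),
                                        structure = s, adduct = a,
                                        trueMz = trueMz, observedMz = obsMz)
    }
    decoyMz <- numeric(0)
    for (k in seq_len(nDecoys)) {
      dec <- .decoyFormula(db, decoyFloorPpm, allMz)
      inten <- stats::rlnorm(1, log(3e5), 0.5)
      precs[[length(precs) + 1L]] <- list(
        precursorMz = dec$mz, intensity = inten,
        envelope = .makeEnvelope(isotopePattern(dec$formula, envelopePeaks),
                                 dec$mz, inten, distortionSd),
        ms2 = NULL)
      meta[[length(meta) + 1L]] <- list(kind = "decoy")
      decoyMz <- c(decoyMz, dec$mz)
    }
    nNoise <- stats::rpois(1, noiseRate)
    mzRange <- range(allMz)
    for (k in seq_len(nNoise)) {
      mz <- stats::runif(1, mzRange[1L] * 0.9, mzRange[2L] * 1.1)
      inten <- stats::rlnorm(1, log(5e4), 1)
      ab <- sort(stats::runif(3), decreasing = TRUE)
      precs[[length(precs) + 1L]] <- list(
        precursorMz = mz, intensity = inten,
        envelope = data.frame(mz = mz + (0:2) * .C13_SPACING,
                              intensity = inten * ab / ab[1L]),
        ms2 = NULL)
      meta[[length(meta) + 1L]] <- list(kind = "noise")
    }
    ## elution order + top-N selection per MS1 cycle
    ord <- sample.int(length(precs))
    precs <- precs[ord]; meta <- meta[ord]
    intens <- vapply(precs, `[[`, numeric(1), "intensity")
    cycle <- ceiling(seq_along(precs) / max(scanSize, 1L))
    selected <- unlist(lapply(split(seq_along(precs), cycle), function(ix)
      ix[order(intens[ix], decreasing = TRUE)][seq_len(min(topN, length(ix)))]))
    for (i in selected) {
      m <- meta[[i]]
      if (m$kind == "planted") {
        frags <- fragmentIons(m$structure, adduct = m$adduct)
        fmz <- jit(frags$mz)
        fint <- stats::rlnorm(length(fmz), log(1e4), 0.7)
      } else {
        fmz <- numeric(0); fint <- numeric(0)
      }
      nn <- stats::rpois(1, 3)
      fmz <- c(fmz, stats::runif(nn, 150, precs[[i]]$precursorMz))
      fint <- c(fint, stats::rlnorm(nn, log(2e3), 1))
      o <- order(fmz)
      precs[[i]]$ms2 <- data.frame(mz = fmz[o], intensity = fint[o])
    }
    planted <- meta[vapply(meta, `[[`, character(1), "kind") == "planted"]
    truth <- data.frame(
      label = vapply(planted, `[[`, character(1), "label"),
      adduct = vapply(planted, `[[`, character(1), "adduct"),
      trueMz = vapply(planted, `[[`, numeric(1), "trueMz"),
      observedMz = vapply(planted, `[[`, numeric(1), "observedMz"),
      stringsAsFactors = FALSE)
    attr(truth, "decoyMz") <- decoyMz
    attr(truth, "seed") <- seed
    list(run = SpectrumRun(sample = sample, condition = condition,
                           precursors = precs),
         truth = truth)
  })
}

#' Simulate the four condition runs of the detection-table experiment
#'
#' One run per detection column of the structure inventory (wild type and
#' nodD2 mutant, each with and without the osmotic inducer), planting
#' exactly the structures flagged as detected in that column.
#'
#' @param inventory Inventory data frame from [readStructureInventory()].
#' @param db A [CandidateDB-class] object.
#' @param conditions Detection-flag columns to simulate (default all
#'   four).
#' @param seed Integer seed; per-condition seeds are derived from it.
#' @param ... Passed on to [simulateRun()] (jitter, decoys, noise, ...).
#' @return A list with `runs` (named list of [SpectrumRun-class]) and
#'   `truth` (named list of planted-label character vectors).
#' @export
simulateTable3Runs <- function(inventory, db,
                               conditions = c("ciat899_control",
                                              "ciat899_mannitol",
                                              "nodd2_control",
                                              "nodd2_mannitol"),
                               seed = NULL, ...) {
  stopifnot(all(conditions %in% names(inventory)))
  structures <- inventoryStructures(inventory)
  runs <- list(); truth <- list()
  for (k in seq_along(conditions)) {
    cond <- conditions[k]
    planted <- structures[inventory[[cond]] == 1L]
    sim <- simulateRun(planted, db, condition = cond, sample = cond,
                       seed = if (is.null(seed)) NULL else seed + k, ...)
    runs[[cond]] <- sim$run
    truth[[cond]] <- sim$truth$label
  }
  list(runs = runs, truth = truth)
}

#' Default planted DEG composition of the synthetic DE table
#'
#' Per-replicon up/down counts of planted differentially expressed genes,
#' chosen to reproduce the mannitol-induction study conditions: 743 DEGs
#' among 6289 genes, 461 up-regulated, with 468 on the chromosome
#' (333 up / 135 down), 67 on the symbiotic plasmid pRtrCIAT899b
#' (66 up / 1 down) and 36 on pRtrCIAT899c (19 up / 17 down). The
#' remaining 172 DEGs, unallocated in those totals, are planted on
#' pRtrCIAT899a with the split (43 up / 129 down) forced by the overall
#' counts.
#'
#' @return Data frame with `replicon`, `up`, `down`.
#' @export
defaultPlantedDEG <- function() {
  data.frame(
    replicon = c("chromosome", "pRtrCIAT899a", "pRtrCIAT899b", "pRtrCIAT899c"),
    up = c(333L, 43L, 66L, 19L),
    down = c(135L, 129L, 1L, 17L))
}

#' Simulate a differential-expression table with planted effects
#'
#' Genes are allocated to replicons by CDS proportion (exactly, when
#' `nGenes` equals the genome's 6289 genes). Null genes draw expression
#' ratios log-normally around 1 (so their signed fold-changes stay well
#' inside the threshold) and uniform p-values; planted DEGs draw
#' `|fold-change| >= fcThreshold` (threshold plus an exponential excess)
#' with the planted sign and near-zero p-values. The adjusted-p column is
#' filled by [bhAdjust()].
#'
#' @param nGenes Total number of genes (default 6289).
#' @param planted Per-replicon up/down planted counts
#'   (default [defaultPlantedDEG()]).
#' @param fcThreshold Planting threshold for `|fold-change|`.
#' @param nullSdLog SD of the null log-ratio distribution.
#' @param seed Integer seed.
#' @return A list with `table` (data frame `gene`, `replicon`,
#'   `fold_change`, `pvalue`, `padj`) and `truth` (character vector of
#'   planted gene ids).
#' @export
simulateDEGTable <- function(nGenes = 6289L, planted = defaultPlantedDEG(),
                             fcThreshold = 2.5, nullSdLog = 0.1,
                             seed = NULL) {
  stopifnot(sum(planted$up + planted$down) <= nGenes)
  .withSeed(seed, {
    map <- repliconMap()
    alloc <- if (nGenes == sum(map$cds)) map$cds else {
      a <- floor(map$cds / sum(map$cds) * nGenes)
      a[1L] <- a[1L] + nGenes - sum(a)
      a
    }
    replicon <- rep(map$replicon, times = alloc)
    gene <- sprintf("gene_%05d", seq_len(nGenes))
    ratio <- exp(stats::rnorm(nGenes, 0, nullSdLog))
    fc <- signedFoldChange(ratio)
    p <- stats::runif(nGenes)
    plantedGenes <- character(0)
    for (r in seq_len(nrow(planted))) {
      pool <- which(replicon == planted$replicon[r])
      need <- planted$up[r] + planted$down[r]
      if (need > length(pool))
        stop("replicon ", planted$replicon[r], " has fewer genes than planted DEGs")
      pick <- sample(pool, need)
      sgn <- rep(c(1, -1), c(planted$up[r], planted$down[r]))
      fc[pick] <- sgn * (fcThreshold + stats::rexp(need, rate = 0.5))
      p[pick] <- stats::runif(need, 0, 1e-8)
      plantedGenes <- c(plantedGenes, gene[pick])
    }
    tab <- data.frame(gene = gene, replicon = replicon, fold_change = fc,
                      pvalue = p, padj = bhAdjust(p),
                      stringsAsFactors = FALSE)
    list(table = tab, truth = plantedGenes)
  })
}
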