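# Helpers building minimal precursor records directly.
plantedPrecursor <- function(db, label, adduct = "M+H", ppmShift = 0,
                             envelope = c("theoretical", "reversed", "none"),
                             ms2 = NULL) {
  envelope <- match.arg(envelope)
  tab <- candidateTable(db)
  i <- match(label, tab$label)
  stopifnot(!is.na(i))
  mz <- tab[[paste0("mz.", adduct)]][i] * (1 + ppmShift * 1e-6)
  env <- NULL
  if (envelope != "none") {
    p <- isotopePattern(parseFormula(tab$formula[i]))
    ab <- if (envelope == "reversed") rev(p$abundance) else p$abundance
    env <- data.frame(mz = mz + p$offset * 1.0033548, intensity = ab * 1e6)
  }
  list(precursorMz = mz, intensity = 1e6, envelope = env, ms2 = ms2)
}

test_that("precursor matching respects the ppm tolerance exactly", {
  db <- testDB()
  run <- SpectrumRun("s", "c", list(
    plantedPrecursor(db, "V (C18:1)", ppmShift = 0),
    plantedPrecursor(db, "V (C18:1)", ppmShift = 6),
    plantedPrecursor(db, "IV (C18:1)", "M+Na", ppmShift = -3)))
  hits <- matchPrecursor(run, db, MatchParams(tolerancePpm = 5))
  expect_true(any(hits$precursor == 1 & hits$label == "V (C18:1)" &
                    abs(hits$ppm) < 1e-6))
  expect_false(any(hits$precursor == 2 & hits$label == "V (C18:1)"))
  expect_true(any(hits$precursor == 3 & hits$label == "IV (C18:1)" &
                    hits$adduct == "M+Na"))
})

test_that("the indexed matcher equals brute-force all-pairs matching", {
  db <- testDB()
  small <- enumerateCandidates(defaultEnumConfig(backbones = 3:4))
  expect_lte(nrow(candidateTable(small)), 200L)
  params <- MatchParams(tolerancePpm = 5)
  set.seed(101)
  tab <- candidateTable(small)
  for (rep in 1:5) {
    mzs <- c(sample(tab[["mz.M+H"]], 8) * (1 + runif(8, -8, 8) * 1e-6),
             runif(4, 700, 1600))
    run <- SpectrumRun("s", "c", lapply(mzs, function(m)
      list(precursorMz = m, intensity = 1, envelope = NULL, ms2 = NULL)))
    got <- matchPrecursor(run, small, params)
    want <- bruteForceMatch(run, small, params)
    expect_equal(hitKey(got), hitKey(want))
  }
})

test_that("hit evaluation applies the isotope-score and fragment gates", {
  db <- testDB()
  params <- MatchParams()
  # undistorted envelope: score 100, accepted
  run <- SpectrumRun("s", "c", list(plantedPrecursor(db, "V (C18:1)")))
  h <- evaluateHit(matchPrecursor(run, db, params), run, db, params)
  expect_equal(max(h$isotopeScore), 100, tolerance = 1e-6)
  expect_true(any(h$accepted))
  # reversed envelope: cosine far below the 80 percent gate
  run <- SpectrumRun("s", "c", list(
    plantedPrecursor(db, "V (C18:1)", envelope = "reversed")))
  h <- evaluateHit(matchPrecursor(run, db, params), run, db, params)
  expect_true(all(h$isotopeScore < 80))
  expect_false(any(h$accepted))
  # MS2 present but no B/Y match: rejected under the k>=1 policy
  junk <- data.frame(mz = c(200.1, 300.2, 400.3), intensity = rep(1, 3))
  run <- SpectrumRun("s", "c", list(
    plantedPrecursor(db, "V (C18:1)", ms2 = junk)))
  h <- evaluateHit(matchPrecursor(run, db, params), run, db, params)
  expect_false(any(h$accepted[h$label == "V (C18:1)"]))
  # with genuine fragment ions it is accepted again
  fr <- fragmentIons(parseStructure("V (C18:1)"))
  run <- SpectrumRun("s", "c", list(plantedPrecursor(
    db, "V (C18:1)", ms2 = data.frame(mz = fr$mz, intensity = 1))))
  h <- evaluateHit(matchPrecursor(run, db, params), run, db, params)
  expect_true(any(h$accepted & h$label == "V (C18:1)"))
  expect_gte(max(h$matchedFragments, na.rm = TRUE), 8)
})

test_that("accepted hits never violate the gates (randomized runs)", {
  db <- testDB()
  params <- MatchParams()
  inv <- testInventory()
  for (seed in 1:10) {
    sim <- simulateRun(sample(inventoryStructures(inv), 8), db,
                       jitterPpm = 3, nDecoys = 3, noiseRate = 4,
                       seed = seed)
    ann <- annotateRun(sim$run, db, params)
    if (!nrow(ann)) next
    expect_true(all(abs(ann$ppm) <= params@tolerancePpm))
    expect_true(all(ann$isotopeScore >= params@minIsotopeScore))
    ok <- is.na(ann$matchedFragments) |
      ann$matchedFragments >= params@minFragments
    expect_true(all(ok))
  }
})

test_that("annotation deduplicates per isomer group and is idempotent", {
  db <- testDB()
  run <- SpectrumRun("s", "c", list(
    plantedPrecursor(db, "V (C18:1)", ppmShift = 1),
    plantedPrecursor(db, "V (C18:1)", ppmShift = -2),
    plantedPrecursor(db, "V (C18:1)", "M+Na", ppmShift = 0.5)))
  ann <- annotateRun(run, db, MatchParams())
  g <- candidateTable(db)$isomerGroup[
    match("V (C18:1)", candidateTable(db)$label)]
  expect_equal(sum(ann$isomerGroup == g), 1L)
  # kept hit is the minimal |ppm| one
  expect_equal(ann$ppm[ann$isomerGroup == g], 0.5, tolerance = 1e-3)
  # decoy-only run yields nothing
  set.seed(5)
  far <- SpectrumRun("s", "c", list(list(
    precursorMz = 1000.123, intensity = 1, envelope = NULL, ms2 = NULL)))
  expect_equal(nrow(annotateRun(far, db, MatchParams())), 0L)
})

test_that("presence matrix accounting and condition comparison are exact", {
  inv <- testInventory()
  db <- testDB()
  # annotate one planted structure; provenance mode credits only planted rows
  run <- SpectrumRun("s", "ciat899_control", list(
    plantedPrecursor(db, "V (C18:1, NMe) dNAc@3")))
  ann <- annotateRun(run, db, MatchParams())
  pmProv <- buildPresenceMatrix(list(ciat899_control = ann), inv,
                                truth = list(ciat899_control = "V (C18:1, NMe) dNAc@3"))
  expect_equal(sum(detected(pmProv)), 1L)
  expect_equal(presenceMode(pmProv), "provenance")
  # mass-only mode marks the whole isomer group (both dNAc positions)
  pmMass <- buildPresenceMatrix(list(ciat899_control = ann), inv)
  expect_equal(sum(detected(pmMass)), 2L)
  expect_equal(presenceMode(pmMass), "mass-only")
  # row order equals inventory order; empty annotations give all-false
  pm0 <- buildPresenceMatrix(list(a = ann[0, ]), inv)
  expect_equal(rownames(detected(pm0)), inv$label)
  expect_false(any(detected(pm0)))
  # comparison invariants on the fixture's own flags
  flagMat <- as.matrix(inv[, c("ciat899_control", "ciat899_mannitol",
                               "nodd2_control", "nodd2_mannitol")]) == 1L
  rownames(flagMat) <- inv$label
  cmp <- compareConditions(flagMat, flags = inv$also_salt)
  expect_equal(unname(cmp$totals), c(6, 36, 4, 4))
  expect_equal(diag(cmp$intersections), cmp$totals)
  expect_equal(unname(cmp$flagOverlap["ciat899_mannitol"]), 25)
  # a condition intersected with itself is its total; disjoint columns give 0
  disjoint <- cbind(a = c(TRUE, FALSE, FALSE), b = c(FALSE, TRUE, TRUE))
  rownames(disjoint) <- paste0("x", 1:3)
  expect_equal(unname(compareConditions(disjoint)$intersections["a", "b"]), 0)
})
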