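test_that("simulation is reproducible from its seed", {
  db <- testDB()
  inv <- testInventory()
  structures <- inventoryStructures(inv)[1:5]
  a <- simulateRun(structures, db, seed = 99, nDecoys = 3, noiseRate = 4)
  b <- simulateRun(structures, db, seed = 99, nDecoys = 3, noiseRate = 4)
  expect_identical(a$truth, b$truth)
  expect_identical(precursors(a$run), precursors(b$run))
  c_ <- simulateRun(structures, db, seed = 100, nDecoys = 3, noiseRate = 4)
  expect_false(identical(precursors(a$run), precursors(c_$run)))
})

test_that("a noiseless undistorted run is recovered exactly", {
  db <- testDB()
  inv <- testInventory()
  planted <- inventoryStructures(inv)[inv$nodd2_control == 1L]
  sim <- simulateRun(planted, db, jitterPpm = 0, distortionSd = 0,
                     nDecoys = 0, noiseRate = 0, seed = 1)
  ann <- annotateRun(sim$run, db, MatchParams())
  got <- unique(unlist(strsplit(ann$groupLabels, ";", fixed = TRUE)))
  expect_true(all(sim$truth$label %in% got))
  expect_true(all(abs(ann$ppm) < 1e-9))
})

test_that("mass shifts beyond the tolerance suppress all annotations", {
  db <- testDB()
  inv <- testInventory()
  planted <- inventoryStructures(inv)[1:6]
  sim <- simulateRun(planted, db, jitterPpm = 0, distortionSd = 0,
                     nDecoys = 0, noiseRate = 0, seed = 1)
  # force every precursor (and its envelope) 10 ppm off its true m/z
  shifted <- lapply(precursors(sim$run), function(p) {
    p$precursorMz <- p$precursorMz * (1 + 10e-6)
    p$envelope$mz <- p$envelope$mz * (1 + 10e-6)
    p
  })
  run <- SpectrumRun(sampleLabel(sim$run), conditionLabel(sim$run), shifted)
  expect_equal(nrow(annotateRun(run, db, MatchParams(tolerancePpm = 5))), 0L)
})

test_that("increasing jitter never increases accepted annotations (paired seeds)", {
  db <- testDB()
  inv <- testInventory()
  planted <- inventoryStructures(inv)[1:10]
  low <- 0L; high <- 0L
  for (seed in 1:15) {
    simLow <- simulateRun(planted, db, jitterPpm = 2, nDecoys = 0,
                          noiseRate = 0, seed = seed)
    simHigh <- simulateRun(planted, db, jitterPpm = 12, nDecoys = 0,
                           noiseRate = 0, seed = seed)
    low <- low + nrow(annotateRun(simLow$run, db, MatchParams()))
    high <- high + nrow(annotateRun(simHigh$run, db, MatchParams()))
  }
  expect_lte(high, low)
})

test_that("decoys respect the offset floor and the generator errors when it cannot", {
  db <- testDB()
  sim <- simulateRun(inventoryStructures(testInventory())[1:3], db,
                     nDecoys = 10, decoyFloorPpm = 20, seed = 3)
  decoyMz <- attr(sim$truth, "decoyMz")
  expect_length(decoyMz, 10L)
  tab <- candidateTable(db)
  allMz <- c(tab[["mz.M+H"]], tab[["mz.M+Na"]])
  for (mz in decoyMz)
    expect_gte(min(abs(ppmError(mz, allMz))), 20)
  # an absurd floor makes decoy construction impossible
  expect_error(simulateRun(inventoryStructures(testInventory())[1:3], db,
                           nDecoys = 1, decoyFloorPpm = 1e5, seed = 3),
               "too dense")
})

test_that("the four condition runs plant exactly the flagged structures", {
  db <- testDB()
  inv <- testInventory()
  sim <- simulateTable3Runs(inv, db, seed = 7, jitterPpm = 2, nDecoys = 2)
  expect_named(sim$runs, c("ciat899_control", "ciat899_mannitol",
                           "nodd2_control", "nodd2_mannitol"))
  expect_length(sim$truth$ciat899_mannitol, 36L)
  expect_length(sim$truth$ciat899_control, 6L)
  expect_length(sim$truth$nodd2_control, 4L)
  expect_length(sim$truth$nodd2_mannitol, 4L)
  expect_setequal(sim$truth$ciat899_control,
                  inv$label[inv$ciat899_control == 1L])
})

test_that("synthetic DE tables carry their planted truth", {
  sim <- simulateDEGTable(seed = 123)
  expect_equal(nrow(sim$table), 6289L)
  expect_length(sim$truth, 743L)
  expect_identical(sim$table, simulateDEGTable(seed = 123)$table)
  # no planted effects: the joint |FC| and padj filter keeps nothing
  null <- simulateDEGTable(nGenes = 2000,
                           planted = defaultPlantedDEG()[0, ], seed = 5)
  expect_equal(nrow(filterDEG(null$table, quiet = TRUE)), 0L)
})
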