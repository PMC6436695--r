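test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the direct-definition oracle on random vectors", {
  set.seed(42)
  for (k in 1:200) {
    p <- runif(sample(1:60, 1))
    got <- bhAdjust(p)
    expect_equal(got, bhOracle(p), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-12 & got <= 1))
    # monotone with respect to the raw ordering
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-12))
  }
})

test_that("signed fold-change follows the reciprocal convention", {
  expect_equal(signedFoldChange(2), 2)
  expect_equal(signedFoldChange(0.5), -2)
  expect_equal(signedFoldChange(1), 1)
  set.seed(8)
  r <- exp(runif(50, -3, 3))
  r <- r[abs(r - 1) > 1e-6]
  expect_equal(signedFoldChange(1 / r), -signedFoldChange(r), tolerance = 1e-12)
  expect_error(signedFoldChange(-1))
})

test_that("DEG filtering applies the inclusive threshold and is idempotent", {
  tab <- data.frame(gene = c("mtlD", "a", "b", "c"),
                    fold_change = c(3.59, 2.4, 5.0, -2.5),
                    padj = c(0.001, 0.001, 0.2, 0.04))
  kept <- filterDEG(tab, quiet = TRUE)
  expect_setequal(kept$gene, c("mtlD", "c"))
  expect_identical(filterDEG(kept, quiet = TRUE), kept)
  expect_equal(nrow(filterDEG(tab[0, ], quiet = TRUE)), 0L)
  # NA adjusted p is excluded, with a message
  tab$padj[1] <- NA
  expect_message(out <- filterDEG(tab), "NA adjusted p")
  expect_setequal(out$gene, "c")
})

test_that("log2-scale fold-change columns are auto-detected and converted", {
  tab <- data.frame(gene = letters[1:3],
                    fold_change = c(2, -0.5, 1.5),  # values inside (-1,1): log2
                    padj = c(1e-4, 1e-4, 1e-4))
  expect_message(out <- filterDEG(tab, fcThreshold = 2), "log2")
  # log2 FC 2 -> ratio 4; log2 -0.5 -> signed -1.41; log2 1.5 -> 2.83
  expect_setequal(out$gene, c("a", "c"))
  expect_equal(out$fold_change[out$gene == "a"], 4)
  # a pure signed table is left untouched
  tab2 <- data.frame(gene = "x", fold_change = 3, padj = 0.01)
  expect_silent(filterDEG(tab2, quiet = TRUE))
})

test_that("replicon summaries cross-tabulate direction and map accessions", {
  deg <- data.frame(
    gene = paste0("g", 1:6),
    replicon = c("CP004015.1", "chromosome", "CP004017.1",
                 "pRtrCIAT899b", "CP004018.1", "plasmidX"),
    fold_change = c(3, -4, 2.6, 5, -2.8, 3),
    padj = rep(0.01, 6))
  expect_warning(s <- repliconSummary(deg), "unknown")
  chr <- s[s$replicon == "chromosome", ]
  expect_equal(c(chr$up, chr$down), c(1L, 1L))
  pb <- s[s$replicon == "pRtrCIAT899b", ]
  expect_equal(pb$total, 2L)
  expect_equal(s$total[s$replicon == "unknown"], 1L)
  # all-up input has zero down counts
  allUp <- data.frame(gene = "g", replicon = "chromosome",
                      fold_change = 3, padj = 0.01)
  expect_equal(sum(repliconSummary(allUp)$down), 0L)
})

test_that("planted synthetic DEG composition is recovered exactly", {
  sim <- simulateDEGTable(seed = 77)
  deg <- filterDEG(sim$table, quiet = TRUE)
  expect_setequal(deg$gene, sim$truth)
  s <- repliconSummary(deg)
  want <- defaultPlantedDEG()
  for (r in want$replicon) {
    expect_equal(s$up[s$replicon == r], want$up[want$replicon == r])
    expect_equal(s$down[s$replicon == r], want$down[want$replicon == r])
  }
})

test_that("delta-delta-Ct fold-changes evaluate the 2^-ddCt definition", {
  expect_equal(ddctFoldChange(20, 20, 20, 20), 1)
  expect_equal(ddctFoldChange(19, 15, 20, 15), 2)  # ddCt = -1
  expect_equal(ddctFoldChange(20, 15, 23, 15), 8)  # ddCt = -3
  expect_error(ddctFoldChange(NA, 1, 1, 1))
})

test_that("DE tables read from TSV and CSV with dialect detection", {
  tab <- data.frame(Gene = paste0("g", 1:4), Replicon = "CP004015.1",
                    log2FC = c(2, -2, 0.1, 1.5), pvalue = c(1e-5, 1e-5, 0.5, 1e-4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  out <- suppressMessages(readDEGTable(tsv))
  expect_named(out, c("gene", "fold_change", "replicon", "padj"))
  expect_equal(out$padj, bhAdjust(tab$pvalue))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(gene = "g1", fc = 3, padj = 0.01), csv, row.names = FALSE)
  expect_equal(readDEGTable(csv, quiet = TRUE)$fold_change, 3)
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(readDEGTable(bad), "fold-change")
})
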