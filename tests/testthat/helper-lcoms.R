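# Shared fixtures and independent oracles used across the suite.

inventoryPath <- function() {
  system.file("extdata", "table3_inventory.tsv", package = "lcoms")
}

testInventory <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- readStructureInventory(inventoryPath(), quiet = TRUE)
    cache
  }
})

testDB <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- enumerateCandidates(defaultEnumConfig())
    cache
  }
})

# Brute-force isotopologue enumeration: every combination of isotope
# assignments over the individual atoms, aggregated by total nominal
# offset. Independent of the convolution implementation.
isotopePatternOracle <- function(formula, nPeaks = 4L) {
  cnt <- parseFormula(formula)@counts
  iso <- lcoms:::.ISOTOPES
  atoms <- rep(names(cnt), cnt)
  stopifnot(length(atoms) <= 10)
  grid <- expand.grid(lapply(atoms, function(e) seq_len(nrow(iso[[e]]))),
                      KEEP.OUT.ATTRS = FALSE)
  off <- rep(0L, nrow(grid))
  ab <- rep(1, nrow(grid))
  for (j in seq_along(atoms)) {
    e <- iso[[atoms[j]]]
    off <- off + e$offset[grid[[j]]]
    ab <- ab * e$abundance[grid[[j]]]
  }
  agg <- tapply(ab, off, sum)
  offsets <- as.integer(names(agg))
  o <- order(offsets)
  offsets <- offsets[o]; agg <- as.numeric(agg)[o]
  keep <- offsets < nPeaks
  data.frame(offset = offsets[keep], abundance = agg[keep] / sum(agg[keep]))
}

# Direct step-up evaluation of the Benjamini-Hochberg definition,
# independent of stats::p.adjust.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# All-pairs precursor matching, the reference for the indexed matcher.
bruteForceMatch <- function(run, db, params) {
  tab <- candidateTable(db)
  out <- list()
  for (i in seq_along(precursors(run))) {
    mz <- precursors(run)[[i]]$precursorMz
    for (a in intersect(params@adducts, candidateAdducts(db))) {
      theo <- tab[[paste0("mz.", a)]]
      ppm <- ppmError(mz, theo)
      keep <- which(abs(ppm) <= params@tolerancePpm)
      if (length(keep))
        out[[length(out) + 1L]] <- data.frame(
          precursor = i, candidate = keep, adduct = a, ppm = ppm[keep])
    }
  }
  if (!length(out))
    return(data.frame(precursor = integer(0), candidate = integer(0),
                      adduct = character(0), ppm = numeric(0)))
  do.call(rbind, out)
}

hitKey <- function(df) {
  sort(paste(df$precursor, df$candidate, df$adduct, sep = "/"))
}
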