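## Aggregated (unit-mass) isotope envelopes. Fine isotope structure is
## deliberately not modelled: at the quoted orbitrap resolutions the
## isotopologue clusters of an LCO collapse to one peak per nominal mass.

.convolveDist <- function(a, b) {
  ## a, b: numeric vectors of abundances indexed by nominal offset 0,1,...
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

.distPower <- function(base, n) {
  ## base distribution convolved with itself n times (exponentiation by squaring)
  result <- 1
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .convolveDist(result, base)
    base <- .convolveDist(base, base)
    n <- n %/% 2L
  }
  result
}

#' Theoretical aggregated isotope pattern of a formula
#'
#' Computes the nominal-mass isotopologue distribution by per-element
#' multinomial convolution: each element contributes the distribution of
#' total neutron-offset summed over its atoms, and element distributions
#' are convolved together. The result is truncated to the first `nPeaks`
#' nominal offsets and renormalized to sum to 1.
#'
#' @param x Formula-bearing object (see [elementalFormula()]).
#' @param nPeaks Number of envelope peaks to keep (>= 1; default 4, which
#'   covers the visible envelope of an LCO at typical dynamic range).
#' @return A data frame with integer column `offset` (nominal mass shift
#'   in Da from the monoisotopic peak) and numeric column `abundance`
#'   (relative, summing to 1).
#' @examples
#' isotopePattern("C1", nPeaks = 2)  # 0.9893 / 0.0107
#' @export
isotopePattern <- function(x, nPeaks = 4L) {
  nPeaks <- as.integer(nPeaks)
  stopifnot(nPeaks >= 1L)
  cnt <- elementalFormula(x)@counts
  dist <- 1
  for (e in names(cnt)) {
    iso <- .ISOTOPES[[e]]
    base <- numeric(max(iso$offset) + 1L)
    base[iso$offset + 1L] <- iso$abundance
    base <- base / sum(base)
    dist <- .convolveDist(dist, .distPower(base, cnt[[e]]))
  }
  keep <- seq_len(min(nPeaks, length(dist)))
  ab <- dist[keep]
  data.frame(offset = keep - 1L, abundance = ab / sum(ab))
}

#' Isotopic pattern score (cosine similarity, percent)
#'
#' Aligns the two envelopes by nominal offset (peaks absent from one side
#' count as zero abundance) and returns 100 times the cosine of the angle
#' between the abundance vectors. 100 means proportional envelopes; 0
#' means disjoint support. Only the first `nPeaks` offsets of either
#' pattern enter the comparison.
#'
#' @param theoretical,observed Patterns as returned by [isotopePattern()]
#'   or [envelopePattern()]: data frames with `offset` and `abundance`.
#' @param nPeaks Number of leading nominal offsets compared (default 4).
#' @return Score in `[0, 100]`.
#' @examples
#' p <- isotopePattern("C56H97N5O26")
#' isotopeScore(p, p)  # 100
#' @export
isotopeScore <- function(theoretical, observed, nPeaks = 4L) {
  stopifnot(nrow(theoretical) > 0L, nrow(observed) > 0L)
  nPeaks <- as.integer(nPeaks)
  th <- theoretical[theoretical$offset < nPeaks, , drop = FALSE]
  ob <- observed[observed$offset < nPeaks, , drop = FALSE]
  offsets <- sort(union(th$offset, ob$offset))
  a <- numeric(length(offsets))
  a[match(th$offset, offsets)] <- th$abundance
  b <- numeric(length(offsets))
  b[match(ob$offset, offsets)] <- ob$abundance
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  100 * max(0, sum(a * b) / (na * nb))
}

#' Convert a measured isotope envelope to a nominal-offset pattern
#'
#' Takes an envelope peak list (m/z, intensity), anchors the nominal
#' offset scale at the first (lowest-m/z, assumed monoisotopic) peak, and
#' normalizes intensities to relative abundances.
#'
#' @param envelope Data frame with columns `mz` and `intensity`, sorted by
#'   m/z.
#' @param charge Precursor charge (offsets are `round((mz - mz[1]) * charge)`).
#' @return A pattern data frame (`offset`, `abundance`).
#' @export
envelopePattern <- function(envelope, charge = 1L) {
  stopifnot(nrow(envelope) > 0L, all(envelope$intensity >= 0))
  off <- as.integer(round((envelope$mz - envelope$mz[1L]) * charge))
  ab <- tapply(envelope$intensity, off, sum)
  off <- as.integer(names(ab))
  o <- order(off)
  tot <- sum(ab)
  if (tot == 0) tot <- 1
  data.frame(offset = off[o], abundance = as.numeric(ab)[o] / tot)
}
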