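## Glycosidic B/Y fragment ion prediction. For a backbone of n residues
## there are n-1 glycosidic bonds; cleavage at bond i (counting from the
## non-reducing, acylated terminus) yields a B_i ion retaining residues
## 1..i as an oxocarbenium (hydrolyzed-fragment mass - H2O + adduct) and
## the complementary Y_(n-i) ion retaining residues i+1..n
## (hydrolyzed-fragment mass + adduct).
##
## Substituent routing: the acyl chain and NMe sit on residue 1 and the
## carbamoyl is assigned to the non-reducing side, so they travel with B
## fragments; the sulfate sits on the reducing residue and the extra
## hexose is assigned to the reducing side, so they travel with Y
## fragments; a dNAc travels with whichever side contains its residue.

#' Predict B/Y glycosidic fragment ions
#'
#' @param s An [LCOStructure-class] object with `backbone >= 2`.
#' @param adduct Adduct name or [adductSpec()]; must be singly charged.
#' @return A data frame with one row per fragment ion: `series` (`"B"` or
#'   `"Y"`), `index` (fragment size in residues, `1..backbone-1`), `site`
#'   (cleaved bond, counted from the non-reducing terminus) and `mz`.
#' @details For every cleavage site the complementarity identity
#'   `mz(B_i) + mz(Y_(n-i)) = monoisotopic mass of M + 2 * adduct delta`
#'   holds by construction.
#' @examples
#' fragmentIons(parseStructure("V (C18:1)"))
#' @export
fragmentIons <- function(s, adduct = "M+H") {
  stopifnot(is(s, "LCOStructure"))
  validObject(s)
  a <- .asAdduct(adduct)
  if (a$charge != 1L)
    stop("unsupported charge state: fragment prediction is restricted to singly charged adducts")
  n <- s@backbone
  ac <- .acylDelta(s@acylCarbons, s@acylUnsat)
  h2o <- .H2O()
  rows <- vector("list", 2L * (n - 1L))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    ## B_i: residues 1..i (non-reducing side)
    fB <- .chainFormula(i) - ac$minus + ac$plus
    if (s@nMethyl)   fB <- fB + ElementalFormula(C = 1L, H = 2L)
    if (s@carbamoyl) fB <- fB + ElementalFormula(C = 1L, H = 1L, N = 1L, O = 1L)
    if (!is.na(s@deacetylated) && s@deacetylated <= i)
      fB <- fB - ElementalFormula(C = 2L, H = 2L, O = 1L)
    ## Y_(n-i): residues i+1..n (reducing side)
    fY <- .chainFormula(n - i)
    if (s@sulfate) fY <- fY + ElementalFormula(S = 1L, O = 3L)
    if (s@hexose)  fY <- fY + ElementalFormula(C = 6L, H = 10L, O = 5L)
    if (!is.na(s@deacetylated) && s@deacetylated > i)
      fY <- fY - ElementalFormula(C = 2L, H = 2L, O = 1L)
    k <- k + 1L
    rows[[k]] <- data.frame(series = "B", index = i, site = i,
                            mz = monoisotopicMass(fB) - monoisotopicMass(h2o) + a$delta)
    k <- k + 1L
    rows[[k]] <- data.frame(series = "Y", index = n - i, site = i,
                            mz = monoisotopicMass(fY) + a$delta)
  }
  out <- do.call(rbind, rows)
  out[order(out$series, out$index), , drop = FALSE]
}
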