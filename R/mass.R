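#' Monoisotopic mass
#'
#' Sum over elements of atom count times the mass of the lightest isotope
#' (pinned NIST/CIAAW values).
#'
#' @param x An [ElementalFormula-class], [LCOStructure-class], or formula
#'   string.
#' @param ... Passed to methods.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(parseFormula("H2O"))     # 18.010565
#' monoisotopicMass("C6H14O6")               # 182.07904
#' @export
setGeneric("monoisotopicMass", function(x, ...) standardGeneric("monoisotopicMass"))

#' @rdname monoisotopicMass
#' @export
setMethod("monoisotopicMass", "ElementalFormula", function(x, ...) {
  cnt <- x@counts
  if (!length(cnt)) return(0)
  mono <- vapply(names(cnt), function(e) .ISOTOPES[[e]]$mass[1L], numeric(1))
  sum(cnt * mono)
})

#' @rdname monoisotopicMass
#' @export
setMethod("monoisotopicMass", "ANY", function(x, ...)
  monoisotopicMass(elementalFormula(x)))

#' Average (standard atomic weight) mass
#'
#' Sum of atom count times the IUPAC conventional standard atomic weight.
#'
#' @inheritParams monoisotopicMass
#' @return Mass in Da (numerically, g/mol).
#' @examples
#' averageMass("C6H14O6")  # 182.172
#' @export
setGeneric("averageMass", function(x, ...) standardGeneric("averageMass"))

#' @rdname averageMass
#' @export
setMethod("averageMass", "ElementalFormula", function(x, ...) {
  cnt <- x@counts
  if (!length(cnt)) return(0)
  sum(cnt * .ATOMIC_WEIGHTS[names(cnt)])
})

#' @rdname averageMass
#' @export
setMethod("averageMass", "ANY", function(x, ...)
  averageMass(elementalFormula(x)))

#' Adduct m/z of a neutral formula
#'
#' `(monoisotopic mass + delta) / charge` for the given adduct.
#'
#' @param x Formula-bearing object (see [elementalFormula()]).
#' @param adduct An adduct name or [adductSpec()] list.
#' @return m/z in Th.
#' @examples
#' adductMz("C6H14O6", "M+Na")
#' @export
adductMz <- function(x, adduct = "M+H") {
  a <- .asAdduct(adduct)
  (monoisotopicMass(x) + a$delta) / a$charge
}

#' Signed parts-per-million mass error
#'
#' `(observed - theoretical) / theoretical * 1e6`; vectorized.
#'
#' @param observed,theoretical m/z values; `theoretical` must be > 0.
#' @return Signed ppm error.
#' @examples
#' ppmError(1000.005, 1000)  # +5
#' @export
ppmError <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}
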