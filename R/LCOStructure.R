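#' LCOStructure: one Nod factor structure
#'
#' A lipochitooligosaccharide (LCO, Nod factor) is a beta-1,4-linked
#' chitooligosaccharide of N-acetylglucosamine (GlcNAc) residues whose
#' non-reducing terminal nitrogen carries a fatty acyl chain in place of
#' the acetyl group, optionally decorated with an N-methyl group (NMe, on
#' the acylated non-reducing residue), a sulfate ester (S, on the reducing
#' residue), a carbamoyl group (Cb), an additional hexose (Hex), and/or a
#' de-N-acetylation (dNAc) at one internal backbone residue.
#'
#' Residues are numbered from the non-reducing (acylated) terminus:
#' residue 1 is the acylated residue, residue `backbone` the reducing end.
#' A dNAc cannot target residue 1, which carries the acyl chain rather
#' than an acetyl group.
#'
#' @slot backbone Integer number of GlcNAc residues (>= 2; the Roman
#'   numeral of the Spaink name).
#' @slot acylCarbons Integer carbon count of the fatty acyl chain (>= 2).
#' @slot acylUnsat Integer number of C=C double bonds in the acyl chain.
#' @slot nMethyl,sulfate,carbamoyl,hexose Logical substituent flags.
#' @slot deacetylated Integer residue index of the de-N-acetylation, or
#'   `NA` when absent; must lie in `2..backbone`.
#' @aliases LCOStructure-class
#' @export
setClass("LCOStructure", representation(
  backbone = "integer",
  acylCarbons = "integer",
  acylUnsat = "integer",
  nMethyl = "logical",
  sulfate = "logical",
  carbamoyl = "logical",
  hexose = "logical",
  deacetylated = "integer"
))

setValidity("LCOStructure", function(object) {
  n <- object@backbone
  c_ <- object@acylCarbons
  u <- object@acylUnsat
  if (length(n) != 1L || is.na(n) || n < 2L)
    return("backbone must be a single integer >= 2")
  if (length(c_) != 1L || is.na(c_) || c_ < 2L)
    return("acyl chain needs at least 2 carbons")
  if (length(u) != 1L || is.na(u) || u < 0L)
    return("acyl unsaturations must be >= 0")
  if (2L * c_ - 1L - 2L * u < 0L)
    return("acyl chain C", c_, ":", u, " has a negative hydrogen count")
  for (fl in c("nMethyl", "sulfate", "carbamoyl", "hexose")) {
    v <- slot(object, fl)
    if (length(v) != 1L || is.na(v)) return(paste0(fl, " must be TRUE/FALSE"))
  }
  d <- object@deacetylated
  if (length(d) != 1L) return("deacetylated must be length 1 (NA if absent)")
  if (!is.na(d)) {
    if (d < 1L || d > n)
      return("deacetylated residue index out of 1..backbone")
    if (d == 1L)
      return("residue 1 carries the acyl chain, not an acetyl group; it cannot be de-N-acetylated")
  }
  TRUE
})

#' Construct an LCO structure
#'
#' @param backbone Number of GlcNAc residues (>= 2).
#' @param acyl Length-2 numeric `c(carbons, unsaturations)` of the fatty
#'   acyl chain, e.g. `c(18, 1)` for C18:1.
#' @param nMethyl,sulfate,carbamoyl,hexose Substituent flags.
#' @param deacetylated Residue index (from the non-reducing terminus) of a
#'   de-N-acetylation, or `NA` (default) when absent.
#' @return An [LCOStructure-class] object.
#' @examples
#' LCOStructure(5, c(18, 1), nMethyl = TRUE, sulfate = TRUE)
#' @export
LCOStructure <- function(backbone, acyl, nMethyl = FALSE, sulfate = FALSE,
                         carbamoyl = FALSE, hexose = FALSE,
                         deacetylated = NA_integer_) {
  stopifnot(length(acyl) == 2L)
  new("LCOStructure",
      backbone = as.integer(backbone),
      acylCarbons = as.integer(acyl[1L]),
      acylUnsat = as.integer(acyl[2L]),
      nMethyl = isTRUE(nMethyl), sulfate = isTRUE(sulfate),
      carbamoyl = isTRUE(carbamoyl), hexose = isTRUE(hexose),
      deacetylated = as.integer(deacetylated))
}

.parseRoman <- function(tok) {
  n <- suppressWarnings(as.integer(utils::as.roman(tok)))
  if (is.na(n) || !identical(as.character(utils::as.roman(n)), toupper(tok)))
    stop("malformed Roman numeral: '", tok, "'")
  n
}

#' Parse a Spaink-style structure name
#'
#' The grammar is `<Roman>[-Hex] (C<c>:<u>[, NMe][, Cb][, S])[ dNAc]`:
#' Roman numeral backbone length, fatty acyl chain `C<carbons>:<unsat>`,
#' then substituent tokens in any order (each at most once). The `dNAc`
#' suffix marks a de-N-acetylated residue; because the printed name does
#' not carry the position, it must be supplied via `deacetylPosition`
#' exactly when the suffix is present.
#'
#' @param text Structure name, e.g. `"V (C18:1, NMe, S)"`.
#' @param deacetylPosition Integer residue index of the dNAc (numbered
#'   from the non-reducing, acylated terminus), required iff the name ends
#'   in `dNAc`.
#' @return An [LCOStructure-class] object.
#' @examples
#' parseStructure("V (C18:1, NMe, S)")
#' parseStructure("V (C18:1, Cb) dNAc", deacetylPosition = 3)
#' @seealso [formatStructure()] for the inverse, [structureLabel()] for a
#'   position-qualified identifier.
#' @export
parseStructure <- function(text, deacetylPosition = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- "^\\s*([A-Z]+)(-Hex)?\\s*\\(\\s*C(\\d+):(\\d+)((?:\\s*,\\s*[A-Za-z]+)*)\\s*\\)(\\s+dNAc)?\\s*$"
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (!length(m))
    stop("cannot parse structure name: '", text, "'")
  backbone <- .parseRoman(m[2L])
  hexose <- nzchar(m[3L])
  acyl <- c(as.integer(m[4L]), as.integer(m[5L]))
  toks <- strsplit(gsub("\\s", "", m[6L]), ",")[[1]]
  toks <- toks[nzchar(toks)]
  known <- c("NMe", "Cb", "S")
  bad <- setdiff(toks, known)
  if (length(bad))
    stop("unknown substituent token: '", bad[1L], "'")
  if (anyDuplicated(toks))
    stop("duplicated substituent token: '", toks[anyDuplicated(toks)], "'")
  dnac <- nzchar(m[7L])
  if (dnac && is.na(deacetylPosition))
    stop("'dNAc' suffix present but no deacetylPosition supplied")
  if (!dnac && !is.na(deacetylPosition))
    stop("deacetylPosition supplied but name lacks the 'dNAc' suffix")
  LCOStructure(backbone, acyl,
               nMethyl = "NMe" %in% toks,
               sulfate = "S" %in% toks,
               carbamoyl = "Cb" %in% toks,
               hexose = hexose,
               deacetylated = if (dnac) as.integer(deacetylPosition) else NA_integer_)
}

#' Serialize an LCO structure to its canonical name
#'
#' Substituents are printed in the fixed order NMe, Cb, S; `-Hex` attaches
#' to the Roman numeral; a de-N-acetylation appends `dNAc` (the residue
#' position is not part of the printed name; see [structureLabel()]).
#' `parseStructure(formatStructure(s), ...)` reproduces `s`.
#'
#' @param s An [LCOStructure-class] object.
#' @return The canonical name string.
#' @examples
#' formatStructure(LCOStructure(4, c(18, 1), hexose = TRUE))  # "IV-Hex (C18:1)"
#' @export
formatStructure <- function(s) {
  stopifnot(is(s, "LCOStructure"))
  toks <- c(if (s@nMethyl) "NMe", if (s@carbamoyl) "Cb", if (s@sulfate) "S")
  paste0(as.character(utils::as.roman(s@backbone)),
         if (s@hexose) "-Hex",
         " (C", s@acylCarbons, ":", s@acylUnsat,
         if (length(toks)) paste0(", ", paste(toks, collapse = ", ")),
         ")",
         if (!is.na(s@deacetylated)) " dNAc")
}

#' Position-qualified structure identifier
#'
#' The canonical name plus, for de-N-acetylated structures, an `@<pos>`
#' suffix so that positional isomers (identical formula, hence identical
#' printed name) remain distinguishable as inventory keys.
#'
#' @param s An [LCOStructure-class] object.
#' @return A single string, e.g. `"V (C18:1, NMe) dNAc@3"`.
#' @export
structureLabel <- function(s) {
  paste0(formatStructure(s),
         if (!is.na(s@deacetylated)) paste0("@", s@deacetylated))
}

## -- composition rules ------------------------------------------------------
## base(n)   = n x GlcNAc (C8H15NO6) - (n-1) x H2O
## acylation = - acetyl (C2H3O) + fatty acyl CcH(2c-1-2u)O
## NMe +CH2 ; S +SO3 ; Cb +CHNO ; Hex +C6H10O5 ; dNAc -C2H2O

.GLCNAC <- function() ElementalFormula(C = 8L, H = 15L, N = 1L, O = 6L)
.H2O <- function() ElementalFormula(H = 2L, O = 1L)

.chainFormula <- function(n) {
  .GLCNAC() * n - .H2O() * (n - 1L)
}

.acylDelta <- function(carbons, unsat) {
  list(minus = ElementalFormula(C = 2L, H = 3L, O = 1L),
       plus = ElementalFormula(C = carbons, H = 2L * carbons - 1L - 2L * unsat,
                               O = 1L))
}

#' Derive the elemental formula of a structure or formula-bearing object
#'
#' For an [LCOStructure-class], the formula is assembled by fixed
#' composition rules: the chitooligosaccharide backbone of `n` GlcNAc
#' residues is `n` x C8H15NO6 minus `n - 1` waters of condensation;
#' acylation replaces the non-reducing terminal acetyl (C2H3O) with the
#' fatty acyl group CcH(2c-1-2u)O; substituents add NMe +CH2, S +SO3,
#' Cb +CHNO, Hex +C6H10O5; a de-N-acetylation removes C2H2O. The rules
#' commute, and positional dNAc isomers share one formula by construction.
#'
#' @param x The object to derive a formula for.
#' @param ... Passed to methods.
#' @return An [ElementalFormula-class] object.
#' @examples
#' formulaString(elementalFormula(parseStructure("V (C18:1)")))  # C56H97N5O26
#' @export
setGeneric("elementalFormula", function(x, ...) standardGeneric("elementalFormula"))

#' @rdname elementalFormula
#' @export
setMethod("elementalFormula", "LCOStructure", function(x, ...) {
  validObject(x)
  f <- .chainFormula(x@backbone)
  ac <- .acylDelta(x@acylCarbons, x@acylUnsat)
  f <- f - ac$minus + ac$plus
  if (x@nMethyl)  f <- f + ElementalFormula(C = 1L, H = 2L)
  if (x@sulfate)  f <- f + ElementalFormula(S = 1L, O = 3L)
  if (x@carbamoyl) f <- f + ElementalFormula(C = 1L, H = 1L, N = 1L, O = 1L)
  if (x@hexose)   f <- f + ElementalFormula(C = 6L, H = 10L, O = 5L)
  if (!is.na(x@deacetylated))
    f <- f - ElementalFormula(C = 2L, H = 2L, O = 1L)
  f
})

#' @rdname elementalFormula
#' @export
setMethod("elementalFormula", "ElementalFormula", function(x, ...) x)

#' @rdname elementalFormula
#' @export
setMethod("elementalFormula", "character", function(x, ...) parseFormula(x))

setMethod("show", "LCOStructure", function(object) {
  cat("LCOStructure:", structureLabel(object), "\n")
  cat("  formula:", formulaString(elementalFormula(object)), "\n")
})
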