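#' @import methods
NULL

#' ElementalFormula: an element -> count map
#'
#' A minimal container for molecular formulas over the elements the
#' package knows isotope data for (H, C, N, O, S, Na). Supports addition
#' and subtraction (`+`, `-`), with subtraction refusing to underflow
#' below zero atoms, and integer scaling (`*`), which is convenient when
#' assembling oligosaccharide backbones residue by residue.
#'
#' @slot counts Named integer vector of atom counts; all counts >= 0.
#' @aliases ElementalFormula-class
#' @export
setClass("ElementalFormula", representation(counts = "integer"))

setValidity("ElementalFormula", function(object) {
  cnt <- object@counts
  if (!length(cnt)) return(TRUE)
  if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
    return("all counts must be named by element symbol")
  bad <- setdiff(names(cnt), .KNOWN_ELEMENTS)
  if (length(bad))
    return(paste0("unknown element(s): ", paste(bad, collapse = ", ")))
  if (anyNA(cnt) || any(cnt < 0L))
    return("atom counts must be nonnegative integers")
  if (anyDuplicated(names(cnt)))
    return("duplicated element symbols")
  TRUE
})

#' Construct an elemental formula from atom counts
#'
#' @param ... Named integer counts, e.g. `ElementalFormula(C = 6, H = 14, O = 6)`.
#' @return An [ElementalFormula-class] object.
#' @examples
#' ElementalFormula(C = 6, H = 14, O = 6)
#' @export
ElementalFormula <- function(...) {
  cnt <- c(...)
  if (is.null(cnt)) cnt <- structure(integer(0), names = character(0))
  cnt <- cnt[cnt != 0]
  storage.mode(cnt) <- "integer"
  new("ElementalFormula", counts = cnt)
}

#' Parse a formula string such as "C6H14O6"
#'
#' @param text A Hill-style formula string; element symbols followed by an
#'   optional count (default 1). Two-letter symbols (e.g. `Na`) are
#'   recognized.
#' @return An [ElementalFormula-class] object.
#' @examples
#' parseFormula("C56H97N5O26")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s", "", text)
  if (!nzchar(s)) return(ElementalFormula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula string: '", text, "'")
  elems <- sub("[0-9]*$", "", toks)
  nums <- sub("^[A-Z][a-z]?", "", toks)
  cnts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  out <- tapply(cnts, elems, sum)
  cnt <- as.integer(out)
  names(cnt) <- names(out)
  new("ElementalFormula", counts = cnt[cnt != 0L])
}

#' Serialize a formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (the usual Hill convention); counts of one are implicit.
#'
#' @param f An [ElementalFormula-class] object.
#' @return A single string, `""` for the empty formula.
#' @examples
#' formulaString(parseFormula("H14C6O6"))  # "C6H14O6"
#' @export
formulaString <- function(f) {
  cnt <- f@counts
  if (!length(cnt)) return("")
  nm <- names(cnt)
  ord <- c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  cnt <- cnt[ord]
  paste0(ord, ifelse(cnt == 1L, "", cnt), collapse = "")
}

.efCounts <- function(f) f@counts

.efCombine <- function(e1, e2, sign) {
  all <- union(names(e1@counts), names(e2@counts))
  a <- structure(integer(length(all)), names = all)
  a[names(e1@counts)] <- e1@counts
  b <- structure(integer(length(all)), names = all)
  b[names(e2@counts)] <- e2@counts
  r <- a + sign * b
  if (any(r < 0L))
    stop("formula subtraction underflow: ", formulaString(e1), " - ",
         formulaString(e2))
  new("ElementalFormula", counts = r[r != 0L])
}

#' @describeIn ElementalFormula-class formula addition/subtraction;
#'   subtraction stops on negative atom counts.
#' @param e1,e2 Operands.
#' @export
setMethod("Arith", signature("ElementalFormula", "ElementalFormula"),
          function(e1, e2) {
  switch(.Generic,
         "+" = .efCombine(e1, e2, +1L),
         "-" = .efCombine(e1, e2, -1L),
         stop("operation '", .Generic, "' not defined for formulas"))
})

#' @describeIn ElementalFormula-class integer scaling, `f * n`.
#' @export
setMethod("Arith", signature("ElementalFormula", "numeric"),
          function(e1, e2) {
  if (.Generic != "*") stop("only '*' is defined between formula and number")
  stopifnot(length(e2) == 1L, e2 == as.integer(e2), e2 >= 0)
  cnt <- e1@counts * as.integer(e2)
  new("ElementalFormula", counts = cnt[cnt != 0L])
})

#' @describeIn ElementalFormula-class equality of atom counts.
#' @export
setMethod("==", signature("ElementalFormula", "ElementalFormula"),
          function(e1, e2) {
  identical(formulaString(e1), formulaString(e2))
})

setMethod("show", "ElementalFormula", function(object) {
  cat("ElementalFormula:", formulaString(object), "\n")
})
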