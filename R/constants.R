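## Pinned physical constants (CIAAW/NIST compilations).
## Isotope rows are ordered by mass; the first row of each element is the
## lightest (monoisotopic) isotope. `offset` is the nominal mass shift in Da
## relative to that lightest isotope, which is what the aggregated
## (unit-mass) isotope envelope model convolves over.

.ISOTOPES <- list(
  H = data.frame(offset = c(0L, 1L),
                 mass = c(1.00782503207, 2.01410177785),
                 abundance = c(0.999885, 0.000115)),
  C = data.frame(offset = c(0L, 1L),
                 mass = c(12, 13.00335483507),
                 abundance = c(0.9893, 0.0107)),
  N = data.frame(offset = c(0L, 1L),
                 mass = c(14.00307400443, 15.00010889888),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(offset = c(0L, 1L, 2L),
                 mass = c(15.99491461957, 16.99913175650, 17.99915961286),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(offset = c(0L, 1L, 2L, 4L),
                 mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = data.frame(offset = 0L,
                  mass = 22.98976928,
                  abundance = 1)
)

## IUPAC standard atomic weights (conventional values).
.ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, Na = 22.98976928)

.PROTON_MASS   <- 1.007276466
.ELECTRON_MASS <- 0.000548579909

.KNOWN_ELEMENTS <- names(.ISOTOPES)

#' Adduct specifications
#'
#' Look up a built-in positive-mode adduct or construct a custom one. The
#' built-ins are the singly charged protonated and sodiated species,
#' `"M+H"` and `"M+Na"`, the dominant adducts in positive-mode
#' electrospray of lipochitooligosaccharides.
#'
#' @param name Adduct name. One of the built-ins (`"M+H"`, `"M+Na"`), or
#'   any label when `delta` is supplied.
#' @param delta Mass delta in Da added to the neutral monoisotopic mass
#'   (defaults to the built-in value for known names).
#' @param charge Positive integer charge (only 1 is supported downstream).
#' @return A list with elements `name`, `delta` and `charge`.
#' @examples
#' adductSpec("M+H")
#' adductSpec("M+Na")
#' @export
adductSpec <- function(name, delta = NULL, charge = 1L) {
  builtins <- list(
    "M+H"  = .PROTON_MASS,
    "M+Na" = 22.98976928 - .ELECTRON_MASS
  )
  if (is.null(delta)) {
    if (!name %in% names(builtins))
      stop("unknown adduct '", name, "'; supply 'delta' for custom adducts")
    delta <- builtins[[name]]
  }
  charge <- as.integer(charge)
  stopifnot(is.finite(delta), length(delta) == 1L, charge >= 1L)
  list(name = name, delta = delta, charge = charge)
}

.asAdduct <- function(a) {
  if (is.character(a)) adductSpec(a) else a
}
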