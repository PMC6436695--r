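#' CandidateDB: a combinatorial LCO candidate database
#'
#' Holds the enumerated candidate structures together with their derived
#' elemental formulas, monoisotopic masses, per-adduct m/z values and the
#' isomer-group partition (candidates sharing one elemental formula, e.g.
#' dNAc positional isomers, are mass-indistinguishable and fall in one
#' group).
#'
#' @slot structures List of [LCOStructure-class] objects.
#' @slot table Data frame: `label`, `name`, `formula`, `mass`,
#'   `isomerGroup`, plus one `mz.<adduct>` column per adduct.
#' @slot adducts Character vector of adduct names indexed for matching.
#' @aliases CandidateDB-class
#' @export
setClass("CandidateDB", representation(
  structures = "list",
  table = "data.frame",
  adducts = "character"
))

setValidity("CandidateDB", function(object) {
  if (length(object@structures) != nrow(object@table))
    return("structure list and table disagree in length")
  need <- c("label", "name", "formula", "mass", "isomerGroup")
  if (!all(need %in% names(object@table)))
    return("table lacks required columns")
  if (anyDuplicated(object@table$label))
    return("duplicated candidate labels")
  TRUE
})

#' Enumeration configuration for the candidate database
#'
#' Describes the cartesian space of candidate LCOs: backbone lengths,
#' acyl chains, substituent combinations and de-N-acetylation options,
#' minus exclusion constraints. The default configuration spans
#' backbones of 3-5 GlcNAc residues, the common C14-C20 acyl chains,
#' any subset of \{NMe, S, Cb, Hex\} with S and Cb mutually exclusive,
#' and dNAc at internal residues of pentamers only; it covers every
#' structure of the shipped inventory.
#'
#' @param backbones Integer vector of backbone lengths.
#' @param acyls List of `c(carbons, unsaturations)` pairs.
#' @param substituents Character vector of available substituent flags
#'   (subset of `c("NMe", "S", "Cb", "Hex")`); all subsets are formed.
#' @param forbidTogether List of character vectors; any candidate whose
#'   flag set contains one of these vectors entirely is excluded.
#' @param dnacPositions Named list mapping backbone length (as character)
#'   to the integer residue positions at which a dNAc variant is also
#'   enumerated (positions count from the non-reducing terminus; residue
#'   1 is never allowed).
#' @return A list of class `"lco_enum_config"`.
#' @examples
#' cfg <- defaultEnumConfig()
#' length(cfg$acyls)
#' @export
defaultEnumConfig <- function(backbones = 3:5,
                              acyls = list(c(14, 0), c(16, 0), c(16, 1),
                                           c(18, 0), c(18, 1), c(20, 0), c(20, 1)),
                              substituents = c("NMe", "S", "Cb", "Hex"),
                              forbidTogether = list(c("S", "Cb")),
                              dnacPositions = list(`5` = 2:4)) {
  stopifnot(length(backbones) > 0L, length(acyls) > 0L)
  known <- c("NMe", "S", "Cb", "Hex")
  if (!all(substituents %in% known))
    stop("unknown substituent flag in config")
  for (fb in forbidTogether)
    if (!all(fb %in% known)) stop("exclusion constraint references unknown flag")
  structure(list(backbones = as.integer(backbones), acyls = acyls,
                 substituents = substituents, forbidTogether = forbidTogether,
                 dnacPositions = dnacPositions),
            class = "lco_enum_config")
}

.subsetList <- function(flags) {
  ## all subsets of a character vector, deterministic order
  out <- list(character(0))
  for (f in flags)
    out <- c(out, lapply(out, function(s) c(s, f)))
  out
}

#' Enumerate the candidate database
#'
#' Forms the cartesian product backbone x acyl x substituent subset x
#' dNAc option, drops combinations hit by an exclusion constraint, and
#' derives formula, monoisotopic mass and adduct m/z for each candidate.
#' Ordering is deterministic: backbone, then acyl (carbons, then
#' unsaturations), then substituent subset, then dNAc position.
#'
#' @param cfg An enumeration configuration from [defaultEnumConfig()].
#' @param adducts Character vector of adduct names to index (default
#'   `c("M+H", "M+Na")`, the positive-mode species).
#' @return A [CandidateDB-class] object.
#' @examples
#' db <- enumerateCandidates(defaultEnumConfig(backbones = 3,
#'   acyls = list(c(16, 0), c(18, 1)), substituents = "NMe",
#'   dnacPositions = list()))
#' nrow(candidateTable(db))  # 4
#' @export
enumerateCandidates <- function(cfg = defaultEnumConfig(),
                                adducts = c("M+H", "M+Na")) {
  stopifnot(inherits(cfg, "lco_enum_config"))
  subs <- .subsetList(cfg$substituents)
  keep <- vapply(subs, function(s)
    !any(vapply(cfg$forbidTogether, function(fb) all(fb %in% s), logical(1))),
    logical(1))
  subs <- subs[keep]
  acyls <- cfg$acyls[order(vapply(cfg$acyls, `[`, numeric(1), 1L),
                           vapply(cfg$acyls, `[`, numeric(1), 2L))]
  structures <- list()
  for (n in sort(cfg$backbones)) {
    dn <- cfg$dnacPositions[[as.character(n)]]
    positions <- c(NA_integer_, as.integer(dn))
    for (ac in acyls) for (ss in subs) for (p in positions) {
      structures[[length(structures) + 1L]] <- LCOStructure(
        n, ac,
        nMethyl = "NMe" %in% ss, sulfate = "S" %in% ss,
        carbamoyl = "Cb" %in% ss, hexose = "Hex" %in% ss,
        deacetylated = p)
    }
  }
  labels <- vapply(structures, structureLabel, character(1))
  dup <- duplicated(labels)
  structures <- structures[!dup]
  labels <- labels[!dup]
  if (!length(structures))
    warning("enumeration produced an empty candidate database")
  formulas <- lapply(structures, elementalFormula)
  fstr <- vapply(formulas, formulaString, character(1))
  tab <- data.frame(
    label = labels,
    name = vapply(structures, formatStructure, character(1)),
    formula = fstr,
    mass = vapply(formulas, monoisotopicMass, numeric(1)),
    isomerGroup = match(fstr, unique(fstr)),
    stringsAsFactors = FALSE
  )
  for (a in adducts)
    tab[[paste0("mz.", a)]] <- vapply(formulas, adductMz, numeric(1), adduct = a)
  new("CandidateDB", structures = structures, table = tab, adducts = adducts)
}

#' @describeIn CandidateDB-class the candidate table (one row per structure).
#' @param db A [CandidateDB-class] object.
#' @export
candidateTable <- function(db) db@table

#' @describeIn CandidateDB-class the indexed adduct names.
#' @export
candidateAdducts <- function(db) db@adducts

#' @describeIn CandidateDB-class the list of [LCOStructure-class] objects.
#' @export
candidateStructures <- function(db) db@structures

#' Partition a candidate database into isomer groups
#'
#' Candidates sharing an exact elemental formula are indistinguishable by
#' precursor mass; they form one isomer group. Groups partition the
#' candidate list.
#'
#' @param db A [CandidateDB-class] object.
#' @return A named list (by formula string) of character vectors of
#'   candidate labels.
#' @export
groupIsomers <- function(db) {
  split(db@table$label, db@table$formula)
}

#' Membership test against a candidate database
#'
#' @param db A [CandidateDB-class] object.
#' @param s An [LCOStructure-class] object.
#' @return `TRUE` iff an identical structure (same label) was enumerated.
#' @export
containsStructure <- function(db, s) {
  structureLabel(s) %in% db@table$label
}

#' Write / read a candidate database as tab-separated text
#'
#' The serialization keeps the candidate table (name, dNAc position,
#' formula, monoisotopic mass, adduct m/z columns); structures are
#' re-parsed on read, so the round trip is lossless.
#'
#' @param db A [CandidateDB-class] object.
#' @param path File path.
#' @return `readCandidateDB` returns a [CandidateDB-class] object;
#'   `writeCandidateDB` returns `path` invisibly.
#' @export
writeCandidateDB <- function(db, path) {
  tab <- db@table
  tab$dnacPosition <- vapply(db@structures, function(s)
    s@deacetylated, integer(1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidateDB
#' @export
readCandidateDB <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  structures <- Map(parseStructure, tab$name,
                    ifelse(is.na(tab$dnacPosition), NA_integer_, tab$dnacPosition))
  structures <- unname(structures)
  adducts <- sub("^mz\\.", "", grep("^mz\\.", names(tab), value = TRUE))
  tab$dnacPosition <- NULL
  new("CandidateDB", structures = structures, table = tab, adducts = adducts)
}

setMethod("show", "CandidateDB", function(object) {
  cat("CandidateDB with", nrow(object@table), "candidates,",
      length(unique(object@table$isomerGroup)), "isomer groups\n")
  cat("  adducts:", paste(object@adducts, collapse = ", "), "\n")
  cat("  mass range:", round(min(object@table$mass), 4), "-",
      round(max(object@table$mass), 4), "Da\n")
})
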