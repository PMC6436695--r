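#' MatchParams: identification gate parameters
#'
#' Parameter object for precursor matching and hit acceptance, in the
#' style of algorithm-parameter classes used across mass-spectrometry
#' packages. Defaults mirror the study conditions: 5 ppm precursor
#' tolerance, isotopic-pattern score gate at 80 percent, positive-mode
#' M+H / M+Na adducts, and at least one matched B/Y fragment whenever an
#' MS2 spectrum was acquired for the precursor.
#'
#' @slot tolerancePpm Precursor mass tolerance in ppm (> 0).
#' @slot minIsotopeScore Minimum isotopic pattern score in `[0, 100]`.
#' @slot adducts Adduct names searched.
#' @slot minFragments Minimum number of matched B/Y ions when MS2 is
#'   present (0 disables the fragment gate).
#' @slot fragmentTolerancePpm Fragment m/z tolerance in ppm.
#' @slot isotopePeaks Number of envelope peaks scored.
#' @aliases MatchParams-class
#' @export
setClass("MatchParams", representation(
  tolerancePpm = "numeric",
  minIsotopeScore = "numeric",
  adducts = "character",
  minFragments = "integer",
  fragmentTolerancePpm = "numeric",
  isotopePeaks = "integer"
))

setValidity("MatchParams", function(object) {
  if (object@tolerancePpm <= 0) return("tolerancePpm must be > 0")
  if (object@minIsotopeScore < 0 || object@minIsotopeScore > 100)
    return("minIsotopeScore must lie in [0, 100]")
  if (object@minFragments < 0L) return("minFragments must be >= 0")
  if (object@fragmentTolerancePpm <= 0) return("fragmentTolerancePpm must be > 0")
  if (object@isotopePeaks < 1L) return("isotopePeaks must be >= 1")
  TRUE
})

#' @rdname MatchParams-class
#' @param tolerancePpm,minIsotopeScore,adducts,minFragments,fragmentTolerancePpm,isotopePeaks
#'   See the corresponding slots.
#' @return A `MatchParams` object.
#' @examples
#' MatchParams()
#' MatchParams(tolerancePpm = 2)
#' @export
MatchParams <- function(tolerancePpm = 5, minIsotopeScore = 80,
                        adducts = c("M+H", "M+Na"), minFragments = 1L,
                        fragmentTolerancePpm = 10, isotopePeaks = 4L) {
  new("MatchParams", tolerancePpm = tolerancePpm,
      minIsotopeScore = minIsotopeScore, adducts = adducts,
      minFragments = as.integer(minFragments),
      fragmentTolerancePpm = fragmentTolerancePpm,
      isotopePeaks = as.integer(isotopePeaks))
}

setMethod("show", "MatchParams", function(object) {
  cat("MatchParams: |ppm| <=", object@tolerancePpm,
      "| isotope score >=", object@minIsotopeScore,
      "| adducts:", paste(object@adducts, collapse = ", "),
      "| >=", object@minFragments, "B/Y ions when MS2 present\n")
})

.mzIndex <- function(db, adducts) {
  ## long, mass-sorted index of (candidate, adduct, mz) for binary search
  adducts <- intersect(adducts, db@adducts)
  if (!length(adducts))
    stop("none of the requested adducts are indexed in the database")
  idx <- do.call(rbind, lapply(adducts, function(a) {
    data.frame(candidate = seq_len(nrow(db@table)), adduct = a,
               mz = db@table[[paste0("mz.", a)]])
  }))
  idx[order(idx$mz), , drop = FALSE]
}

#' Match precursors against the candidate database
#'
#' For every (precursor, candidate, adduct) combination whose signed ppm
#' error is within the tolerance, emits one provisional hit. Candidates
#' are searched through a mass-sorted index with a binary-search window
#' (`findInterval`), not an all-pairs scan.
#'
#' @param run A [SpectrumRun-class] object.
#' @param db A [CandidateDB-class] object.
#' @param params A [MatchParams-class] object.
#' @return A data frame of provisional hits: `precursor` (index into
#'   `precursors(run)`), `candidate` (index into the candidate table),
#'   `label`, `adduct`, `theoreticalMz`, `observedMz`, `ppm`.
#' @export
matchPrecursor <- function(run, db, params = MatchParams()) {
  stopifnot(is(run, "SpectrumRun"), is(db, "CandidateDB"))
  if (!nrow(db@table)) stop("empty candidate database")
  idx <- .mzIndex(db, params@adducts)
  tol <- params@tolerancePpm * 1e-6
  hits <- vector("list", length(run@precursors))
  for (i in seq_along(run@precursors)) {
    mz <- run@precursors[[i]]$precursorMz
    lo <- findInterval(mz / (1 + tol), idx$mz, left.open = TRUE) + 1L
    hi <- findInterval(mz / (1 - tol), idx$mz)
    if (hi < lo) next
    w <- idx[lo:hi, , drop = FALSE]
    ppm <- ppmError(mz, w$mz)
    keep <- abs(ppm) <= params@tolerancePpm
    if (!any(keep)) next
    hits[[i]] <- data.frame(
      precursor = i, candidate = w$candidate[keep],
      label = db@table$label[w$candidate[keep]],
      adduct = w$adduct[keep], theoreticalMz = w$mz[keep],
      observedMz = mz, ppm = ppm[keep])
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(precursor = integer(0), candidate = integer(0),
                      label = character(0), adduct = character(0),
                      theoreticalMz = numeric(0), observedMz = numeric(0),
                      ppm = numeric(0))
  rownames(out) <- NULL
  out
}

#' Score provisional hits and apply the acceptance gates
#'
#' For each provisional hit, computes the isotopic pattern score of the
#' observed envelope against the candidate's theoretical envelope and,
#' when the precursor carries an MS2 spectrum, counts predicted B/Y
#' fragment ions matched within the fragment tolerance. A hit is accepted
#' iff the ppm tolerance, the score gate and the fragment policy all
#' hold. Precursors without an envelope are treated as unscorable
#' (score 0).
#'
#' @param hits Provisional hits from [matchPrecursor()].
#' @param run,db,params As in [matchPrecursor()].
#' @return The hits data frame extended with `isotopeScore`,
#'   `matchedFragments` (`NA` when no MS2), `isomerGroup`, `accepted`.
#' @export
evaluateHit <- function(hits, run, db, params = MatchParams()) {
  n <- nrow(hits)
  score <- numeric(n)
  nfrag <- rep(NA_integer_, n)
  theoCache <- list()
  for (k in seq_len(n)) {
    p <- run@precursors[[hits$precursor[k]]]
    ci <- hits$candidate[k]
    fs <- db@table$formula[ci]
    th <- theoCache[[fs]]
    if (is.null(th)) {
      th <- isotopePattern(parseFormula(fs), nPeaks = params@isotopePeaks)
      theoCache[[fs]] <- th
    }
    if (!is.null(p$envelope) && nrow(p$envelope))
      score[k] <- isotopeScore(th, envelopePattern(p$envelope),
                               nPeaks = params@isotopePeaks)
    if (!is.null(p$ms2) && nrow(p$ms2)) {
      pred <- fragmentIons(db@structures[[ci]], adduct = hits$adduct[k])
      ftol <- params@fragmentTolerancePpm * 1e-6
      nfrag[k] <- sum(vapply(pred$mz, function(m)
        any(abs(p$ms2$mz - m) <= m * ftol), logical(1)))
    }
  }
  hits$isotopeScore <- score
  hits$matchedFragments <- nfrag
  hits$isomerGroup <- db@table$isomerGroup[hits$candidate]
  hits$accepted <- abs(hits$ppm) <= params@tolerancePpm &
    score >= params@minIsotopeScore &
    (is.na(nfrag) | nfrag >= params@minFragments)
  hits
}

#' Annotate a run: accepted, deduplicated identifications
#'
#' Runs [matchPrecursor()] and [evaluateHit()], keeps accepted hits and
#' deduplicates them per isomer group, retaining the hit with minimal
#' absolute ppm error (ties broken by higher isotope score, then
#' lexicographic candidate label). The returned rows carry the full
#' isomer-group membership in `groupLabels`.
#'
#' @inheritParams matchPrecursor
#' @return A data frame of accepted annotations, one row per isomer
#'   group, ordered by group.
#' @export
annotateRun <- function(run, db, params = MatchParams()) {
  hits <- evaluateHit(matchPrecursor(run, db, params), run, db, params)
  acc <- hits[hits$accepted, , drop = FALSE]
  if (!nrow(acc)) {
    acc$groupLabels <- character(0)
    return(acc)
  }
  o <- order(acc$isomerGroup, abs(acc$ppm), -acc$isotopeScore, acc$label)
  acc <- acc[o, , drop = FALSE]
  acc <- acc[!duplicated(acc$isomerGroup), , drop = FALSE]
  acc$groupLabels <- vapply(acc$isomerGroup, function(g)
    paste(db@table$label[db@table$isomerGroup == g], collapse = ";"),
    character(1))
  rownames(acc) <- NULL
  acc
}

## -- presence matrix --------------------------------------------------------

#' PresenceMatrix: per-condition detection table
#'
#' Boolean matrix with one row per inventory structure (inventory order)
#' and one column per condition; `TRUE` cells are backed by at least one
#' accepted annotation. The accounting mode records whether isomer-group
#' hits were restricted to the structures actually planted by the
#' generator (`"provenance"`) or expanded to every inventory member of
#' the group (`"mass-only"`, the only option for real data, where
#' positional isomers are indistinguishable).
#'
#' @slot detected Logical matrix (structures x conditions).
#' @slot mode `"provenance"` or `"mass-only"`.
#' @aliases PresenceMatrix-class
#' @export
setClass("PresenceMatrix", representation(
  detected = "matrix",
  mode = "character"
))

setValidity("PresenceMatrix", function(object) {
  if (!is.logical(object@detected)) return("detected must be logical")
  if (is.null(rownames(object@detected)) || is.null(colnames(object@detected)))
    return("detected must have structure row names and condition column names")
  if (!object@mode %in% c("provenance", "mass-only"))
    return("mode must be 'provenance' or 'mass-only'")
  TRUE
})

#' @describeIn PresenceMatrix-class the logical detection matrix.
#' @param pm A [PresenceMatrix-class] object.
#' @export
detected <- function(pm) pm@detected

#' @describeIn PresenceMatrix-class the accounting mode.
#' @export
presenceMode <- function(pm) pm@mode

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix (", object@mode, " mode): ",
      nrow(object@detected), " structures x ",
      ncol(object@detected), " conditions\n", sep = "")
  print(colSums(object@detected))
})

#' Build the per-condition presence matrix
#'
#' @param annotations Named list (condition -> annotation data frame from
#'   [annotateRun()], or a list of such data frames from multiple runs of
#'   the same condition; per-condition presence is their union).
#' @param inventory Inventory data frame from [readStructureInventory()]
#'   (its `label` column fixes row order).
#' @param truth Optional named list (condition -> character vector of
#'   planted structure labels). When supplied, accounting runs in
#'   provenance mode: an isomer-group hit marks only the group members
#'   that were actually planted. Without it, mass-only mode marks every
#'   inventory member of the group.
#' @return A [PresenceMatrix-class] object.
#' @export
buildPresenceMatrix <- function(annotations, inventory, truth = NULL) {
  conds <- names(annotations)
  if (is.null(conds) || anyDuplicated(conds))
    stop("annotations must be a named list with distinct condition labels")
  labels <- inventory$label
  mat <- matrix(FALSE, nrow = length(labels), ncol = length(conds),
                dimnames = list(labels, conds))
  for (cond in conds) {
    ann <- annotations[[cond]]
    if (is.data.frame(ann)) ann <- list(ann)
    hitLabels <- unlist(lapply(ann, function(a)
      if (nrow(a)) strsplit(a$groupLabels, ";", fixed = TRUE) else character(0)))
    hitLabels <- unique(unlist(hitLabels))
    if (!is.null(truth)) hitLabels <- intersect(hitLabels, truth[[cond]])
    mat[labels %in% hitLabels, cond] <- TRUE
  }
  new("PresenceMatrix", detected = mat,
      mode = if (is.null(truth)) "mass-only" else "provenance")
}

#' Summarize and compare detection columns
#'
#' Computes per-condition detection totals, all pairwise condition
#' intersections, and (optionally) the overlap of each condition with an
#' external per-structure flag such as the salt-production annotation of
#' the inventory.
#'
#' @param pm A [PresenceMatrix-class] object (or a logical matrix).
#' @param flags Optional logical (or 0/1) vector aligned to the matrix
#'   rows.
#' @return A list with `totals` (named vector), `intersections` (matrix)
#'   and, when `flags` is given, `flagOverlap` (named vector).
#' @export
compareConditions <- function(pm, flags = NULL) {
  mat <- if (is(pm, "PresenceMatrix")) pm@detected else pm
  stopifnot(is.matrix(mat))
  m <- mat * 1L
  out <- list(totals = colSums(mat),
              intersections = t(m) %*% m)
  if (!is.null(flags)) {
    flags <- as.logical(flags)
    stopifnot(length(flags) == nrow(mat))
    out$flagOverlap <- colSums(mat & flags)
  }
  out
}
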