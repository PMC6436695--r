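#' SpectrumRun: precursor + MS2 peak lists for one sample
#'
#' A labeled collection of precursor records from one LC-MS/MS run. Each
#' precursor record is a list with elements `precursorMz` (numeric),
#' `intensity` (numeric, arbitrary units), `envelope` (data frame of
#' `mz`/`intensity` isotope-envelope peaks sorted by m/z) and `ms2`
#' (data frame of fragment peaks, or `NULL` when the precursor was not
#' selected for fragmentation).
#'
#' @slot sample Sample label (nonempty).
#' @slot condition Condition label (nonempty).
#' @slot precursors List of precursor records.
#' @aliases SpectrumRun-class
#' @export
setClass("SpectrumRun", representation(
  sample = "character",
  condition = "character",
  precursors = "list"
))

setValidity("SpectrumRun", function(object) {
  if (length(object@sample) != 1L || !nzchar(object@sample))
    return("sample label must be a nonempty string")
  if (length(object@condition) != 1L || !nzchar(object@condition))
    return("condition label must be a nonempty string")
  for (p in object@precursors) {
    if (!is.list(p) || is.null(p$precursorMz) || p$precursorMz <= 0)
      return("each precursor record needs a positive precursorMz")
    env <- p$envelope
    if (!is.null(env) && nrow(env)) {
      if (is.unsorted(env$mz)) return("envelope peaks must be sorted by m/z")
      if (any(env$intensity < 0)) return("peak intensities must be >= 0")
    }
  }
  TRUE
})

#' Construct a spectrum run
#'
#' @param sample,condition Run labels.
#' @param precursors List of precursor records (see
#'   [SpectrumRun-class]).
#' @return A [SpectrumRun-class] object.
#' @export
SpectrumRun <- function(sample, condition, precursors = list()) {
  new("SpectrumRun", sample = sample, condition = condition,
      precursors = precursors)
}

#' @describeIn SpectrumRun-class sample label accessor.
#' @param run A [SpectrumRun-class] object.
#' @export
sampleLabel <- function(run) run@sample

#' @describeIn SpectrumRun-class condition label accessor.
#' @export
conditionLabel <- function(run) run@condition

#' @describeIn SpectrumRun-class precursor record list accessor.
#' @export
precursors <- function(run) run@precursors

setMethod("show", "SpectrumRun", function(object) {
  nms2 <- sum(vapply(object@precursors,
                     function(p) !is.null(p$ms2) && nrow(p$ms2) > 0, logical(1)))
  cat("SpectrumRun '", object@sample, "' (condition: ", object@condition,
      ")\n", sep = "")
  cat(" ", length(object@precursors), "precursors,", nms2, "with MS2\n")
})

## -- MGF --------------------------------------------------------------------
## Standard Mascot Generic Format blocks carry one MS2 spectrum per
## BEGIN IONS/END IONS pair. The run's MS1 context (isotope envelope) has
## no standard MGF slot, so it is carried in a custom ENVELOPE= header of
## semicolon-separated mz:intensity pairs; readers that ignore unknown
## headers still read the blocks as plain MGF.

#' Write a spectrum run to an MGF file
#'
#' One `BEGIN IONS` block per precursor with `PEPMASS`, `CHARGE=1+`,
#' `SCANS`, run labels in `TITLE`, the isotope envelope in a custom
#' `ENVELOPE=` header, and the MS2 peaks (if any) as peak rows.
#'
#' @param run A [SpectrumRun-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readMGF()]
#' @export
writeMGF <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) formatC(x, format = "fg", digits = 12)
  for (i in seq_along(run@precursors)) {
    p <- run@precursors[[i]]
    lines <- c("BEGIN IONS",
               sprintf("TITLE=scan=%d sample=%s condition=%s", i,
                       run@sample, run@condition),
               sprintf("PEPMASS=%s %s", fmt(p$precursorMz),
                       fmt(if (is.null(p$intensity)) 0 else p$intensity)),
               "CHARGE=1+",
               sprintf("SCANS=%d", i))
    env <- p$envelope
    if (!is.null(env) && nrow(env))
      lines <- c(lines, paste0("ENVELOPE=", paste(
        sprintf("%s:%s", fmt(env$mz), fmt(env$intensity)), collapse = ";")))
    if (!is.null(p$ms2) && nrow(p$ms2))
      lines <- c(lines, sprintf("%s %s", fmt(p$ms2$mz), fmt(p$ms2$intensity)))
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a spectrum run from an MGF file
#'
#' Parses `BEGIN IONS` blocks; `PEPMASS` gives the precursor m/z and
#' intensity, peak rows give MS2 peaks, and the optional `ENVELOPE=`
#' header (written by [writeMGF()]) restores the isotope envelope. Run
#' labels default to those embedded in the `TITLE` headers.
#'
#' @param path MGF file path.
#' @param sample,condition Optional label overrides.
#' @return A [SpectrumRun-class] object.
#' @export
readMGF <- function(path, sample = NULL, condition = NULL) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  precs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE) & grepl("^[A-Z]", block)
    headers <- block[hdr]
    peaks <- block[!hdr & nzchar(block)]
    getH <- function(key) {
      v <- headers[startsWith(headers, paste0(key, "="))]
      if (!length(v)) return(NA_character_)
      sub(paste0("^", key, "="), "", v[1L])
    }
    pm <- strsplit(trimws(getH("PEPMASS")), "\\s+")[[1]]
    env <- NULL
    eh <- getH("ENVELOPE")
    if (!is.na(eh)) {
      pairs <- strsplit(strsplit(eh, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      env <- data.frame(mz = as.numeric(vapply(pairs, `[`, "", 1L)),
                        intensity = as.numeric(vapply(pairs, `[`, "", 2L)))
    }
    ms2 <- NULL
    if (length(peaks)) {
      sp <- strsplit(trimws(peaks), "\\s+")
      ms2 <- data.frame(mz = as.numeric(vapply(sp, `[`, "", 1L)),
                        intensity = as.numeric(vapply(sp, `[`, "", 2L)))
    }
    title <- getH("TITLE")
    precs[[k]] <- list(precursorMz = as.numeric(pm[1L]),
                       intensity = if (length(pm) > 1L) as.numeric(pm[2L]) else 0,
                       envelope = env, ms2 = ms2, title = title)
  }
  title1 <- if (length(precs)) precs[[1L]]$title else NA_character_
  fromTitle <- function(key) {
    m <- regmatches(title1, regexec(paste0(key, "=(\\S+)"), title1))[[1]]
    if (length(m) == 2L) m[2L] else "unknown"
  }
  SpectrumRun(sample = if (is.null(sample)) fromTitle("sample") else sample,
              condition = if (is.null(condition)) fromTitle("condition") else condition,
              precursors = precs)
}

## -- CSV dialect ------------------------------------------------------------

#' Write / read a spectrum run in the long CSV peak-list dialect
#'
#' Columns `scan, level, precursor_mz, mz, intensity`: level-1 rows are
#' isotope-envelope peaks of the scan's precursor, level-2 rows its MS2
#' fragment peaks. Scans group rows into precursor records.
#'
#' @param run A [SpectrumRun-class] object.
#' @param path File path.
#' @param sample,condition Label overrides for `readPeakCSV` (the CSV
#'   itself carries no labels; defaults `"unknown"`).
#' @return `readPeakCSV` returns a [SpectrumRun-class]; `writePeakCSV`
#'   returns `path` invisibly.
#' @export
writePeakCSV <- function(run, path) {
  rows <- list()
  for (i in seq_along(run@precursors)) {
    p <- run@precursors[[i]]
    if (!is.null(p$envelope) && nrow(p$envelope))
      rows[[length(rows) + 1L]] <- data.frame(
        scan = i, level = 1L, precursor_mz = p$precursorMz,
        mz = p$envelope$mz, intensity = p$envelope$intensity)
    if (!is.null(p$ms2) && nrow(p$ms2))
      rows[[length(rows) + 1L]] <- data.frame(
        scan = i, level = 2L, precursor_mz = p$precursorMz,
        mz = p$ms2$mz, intensity = p$ms2$intensity)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scan = integer(0), level = integer(0),
               precursor_mz = numeric(0), mz = numeric(0),
               intensity = numeric(0))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePeakCSV
#' @export
readPeakCSV <- function(path, sample = "unknown", condition = "unknown") {
  tab <- utils::read.csv(path)
  need <- c("scan", "level", "precursor_mz", "mz", "intensity")
  if (!all(need %in% names(tab)))
    stop("peak CSV lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  precs <- lapply(split(tab, tab$scan), function(d) {
    env <- d[d$level == 1L, c("mz", "intensity"), drop = FALSE]
    ms2 <- d[d$level == 2L, c("mz", "intensity"), drop = FALSE]
    env <- env[order(env$mz), , drop = FALSE]
    rownames(env) <- rownames(ms2) <- NULL
    list(precursorMz = d$precursor_mz[1L],
         intensity = if (nrow(env)) max(env$intensity) else 0,
         envelope = if (nrow(env)) env else NULL,
         ms2 = if (nrow(ms2)) ms2 else NULL)
  })
  precs <- precs[order(as.integer(names(precs)))]
  SpectrumRun(sample = sample, condition = condition,
              precursors = unname(precs))
}
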