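#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort p-values ascending, take `p_(i) * m / i`,
#' enforce monotone non-decreasing from the largest rank down, cap at 1,
#' and return values in the input order. Delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input;
#' `NA` values are carried through.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhAdjust <- function(p) {
  stopifnot(is.numeric(p))
  ok <- p[!is.na(p)]
  if (any(ok < 0 | ok > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed fold-change convention
#'
#' Maps an expression ratio to the signed convention used in
#' differential-expression tables: ratios of at least 1 are reported as
#' is, ratios below 1 as the negative reciprocal, so down-regulation is
#' negative and `|FC| >= 1` always.
#'
#' @param ratio Positive expression ratio(s).
#' @return Signed fold-change(s).
#' @examples
#' signedFoldChange(c(2, 0.5, 1))  # 2 -2 1
#' @export
signedFoldChange <- function(ratio) {
  stopifnot(all(ratio > 0, na.rm = TRUE))
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

.log2ToSigned <- function(l) signedFoldChange(2^l)

#' Filter a differential-expression table
#'
#' Keeps records with `|signed fold-change| >= fcThreshold` (inclusive)
#' and adjusted p-value `<= alpha`, in stable input order. Tables whose
#' fold-change column is on the log2 scale are auto-detected (presence of
#' finite nonzero values inside (-1, 1), impossible under the signed
#' convention) and converted, with a message. Records with `NA` adjusted
#' p are excluded, with a message reporting the count.
#'
#' @param records Data frame with at least a fold-change column and an
#'   adjusted-p column.
#' @param fcThreshold Absolute signed fold-change cut (default 2.5).
#' @param alpha Adjusted-p cut (default 0.05).
#' @param fcColumn,padjColumn Column names (defaults `"fold_change"`,
#'   `"padj"`).
#' @param quiet Suppress messages.
#' @return The filtered data frame; its `fold_change` column is on the
#'   signed scale. Idempotent: filtering a filtered table is a no-op.
#' @export
filterDEG <- function(records, fcThreshold = 2.5, alpha = 0.05,
                      fcColumn = "fold_change", padjColumn = "padj",
                      quiet = FALSE) {
  stopifnot(is.data.frame(records), fcThreshold >= 1, alpha >= 0, alpha <= 1)
  if (!nrow(records)) return(records)
  if (!all(c(fcColumn, padjColumn) %in% names(records)))
    stop("records lack column(s): ",
         paste(setdiff(c(fcColumn, padjColumn), names(records)), collapse = ", "))
  fc <- records[[fcColumn]]
  fin <- fc[is.finite(fc)]
  if (any(abs(fin) < 1 & fin != 0)) {
    if (!quiet) message("fold-change column detected as log2; converting to the signed convention")
    fc <- .log2ToSigned(fc)
    records[[fcColumn]] <- fc
  }
  padj <- records[[padjColumn]]
  nNA <- sum(is.na(padj))
  if (nNA && !quiet)
    message("excluding ", nNA, " record(s) with NA adjusted p")
  keep <- !is.na(padj) & !is.na(fc) & abs(fc) >= fcThreshold & padj <= alpha
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicon accession map of R. tropici CIAT 899
#'
#' The strain's four replicons: the chromosome and plasmids a-c, with
#' their RefSeq accessions and CDS counts (used as the default gene
#' allocation weights of the synthetic DEG generator).
#'
#' @return Data frame with `accession`, `replicon`, `cds`.
#' @examples
#' repliconMap()
#' @export
repliconMap <- function() {
  data.frame(
    accession = c("CP004015.1", "CP004016.1", "CP004017.1", "CP004018.1"),
    replicon = c("chromosome", "pRtrCIAT899a", "pRtrCIAT899b", "pRtrCIAT899c"),
    cds = c(3672L, 212L, 500L, 1905L))
}

#' Cross-tabulate DEGs by replicon and direction
#'
#' @param deg Filtered DEG data frame with a signed `fold_change` column
#'   and a `replicon` column (accessions are translated through
#'   [repliconMap()]; unmapped values are counted under `"unknown"` with
#'   a warning).
#' @return Data frame with `replicon`, `up`, `down`, `total`.
#' @export
repliconSummary <- function(deg) {
  stopifnot(is.data.frame(deg))
  map <- repliconMap()
  rep <- deg$replicon
  if (is.null(rep)) stop("deg table lacks a 'replicon' column")
  acc <- match(rep, map$accession)
  rep[!is.na(acc)] <- map$replicon[acc[!is.na(acc)]]
  unknown <- !rep %in% map$replicon
  if (any(unknown)) {
    warning(sum(unknown), " gene(s) on unrecognized replicon(s); counted as 'unknown'")
    rep[unknown] <- "unknown"
  }
  lv <- c(map$replicon, if (any(unknown)) "unknown")
  up <- table(factor(rep[deg$fold_change > 0], levels = lv))
  dn <- table(factor(rep[deg$fold_change < 0], levels = lv))
  data.frame(replicon = lv, up = as.integer(up), down = as.integer(dn),
             total = as.integer(up + dn))
}

#' Delta-delta-Ct relative fold-change
#'
#' qPCR relative quantification against a reference gene:
#' `ddCt = (Ct_target,cond - Ct_ref,cond) - (Ct_target,ctrl - Ct_ref,ctrl)`
#' and the fold-change is `2^-ddCt`.
#'
#' @param ctTargetCond,ctRefCond Ct values of target and reference gene
#'   under the induced condition.
#' @param ctTargetCtrl,ctRefCtrl Ct values under the control condition.
#' @return Fold-change (vectorized).
#' @examples
#' ddctFoldChange(20, 15, 23, 15)  # 8
#' @export
ddctFoldChange <- function(ctTargetCond, ctRefCond, ctTargetCtrl, ctRefCtrl) {
  stopifnot(all(is.finite(c(ctTargetCond, ctRefCond, ctTargetCtrl, ctRefCtrl))))
  ddct <- (ctTargetCond - ctRefCond) - (ctTargetCtrl - ctRefCtrl)
  2^(-ddct)
}

#' Read a differential-expression table
#'
#' Reads tab- or comma-separated DE tables (and, when the readxl package
#' is installed, spreadsheet exports) with at least a gene identifier, a
#' fold-change column and a p-value column. Column names are matched
#' case-insensitively against common dialects (`gene`/`id`,
#' `fold_change`/`foldchange`/`fc`/`log2fc`/`log2foldchange`,
#' `padj`/`adj_p`/`fdr`/`qvalue`, `pvalue`/`p`). When only raw p-values
#' are present, [bhAdjust()] fills in `padj`.
#'
#' @param path File path (`.tsv`/`.txt`, `.csv`, or `.xlsx`).
#' @param quiet Suppress messages.
#' @return Data frame with normalized columns `gene`, `replicon` (if
#'   present), `fold_change`, `padj`.
#' @export
readDEGTable <- function(path, quiet = FALSE) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading .xlsx requires the 'readxl' package; export to TSV instead")
      as.data.frame(readxl::read_excel(path))
    },
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    utils::read.delim(path, stringsAsFactors = FALSE))
  nm <- tolower(names(tab))
  pick <- function(...) {
    i <- match(c(...), nm)
    i <- i[!is.na(i)]
    if (length(i)) i[1L] else NA_integer_
  }
  gi <- pick("gene", "gene_id", "id", "accession")
  fi <- pick("fold_change", "foldchange", "fc", "log2fc", "log2foldchange")
  qi <- pick("padj", "adj_p", "adj_pvalue", "fdr", "qvalue")
  pi_ <- pick("pvalue", "p_value", "p")
  if (is.na(gi) || is.na(fi))
    stop("DE table needs a gene and a fold-change column")
  out <- data.frame(gene = as.character(tab[[gi]]),
                    fold_change = as.numeric(tab[[fi]]),
                    stringsAsFactors = FALSE)
  ri <- pick("replicon", "chromosome", "molecule")
  if (!is.na(ri)) out$replicon <- as.character(tab[[ri]])
  if (!is.na(qi)) {
    out$padj <- as.numeric(tab[[qi]])
  } else if (!is.na(pi_)) {
    if (!quiet) message("no adjusted-p column; applying Benjamini-Hochberg to raw p-values")
    out$padj <- bhAdjust(as.numeric(tab[[pi_]]))
  } else {
    stop("DE table needs an adjusted or raw p-value column")
  }
  out
}
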