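#' Read a structure inventory (digitized detection table)
#'
#' The inventory is tab-separated with columns `name` (Spaink structure
#' name), `dnac_position` (empty or the de-N-acetylated residue index,
#' counted from the non-reducing terminus), four 0/1 detection flags
#' (`ciat899_control`, `ciat899_mannitol`, `nodd2_control`,
#' `nodd2_mannitol`) and the 0/1 `also_salt` flag marking structures also
#' produced under saline stress. The digitized inventory of the
#' mannitol-induction study ships with the package (see the example).
#'
#' @param path Path to the TSV file.
#' @param quiet Suppress the row/flag summary message.
#' @return A data frame with the file's columns plus `label` (the
#'   position-qualified structure identifier); the parsed
#'   [LCOStructure-class] objects are attached as attribute
#'   `"structures"` (see [inventoryStructures()]).
#' @examples
#' inv <- readStructureInventory(
#'   system.file("extdata", "table3_inventory.tsv", package = "lcoms"))
#' nrow(inv)       # 36
#' sum(inv$also_salt)  # 25
#' @export
readStructureInventory <- function(path, quiet = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "dnac_position", "ciat899_control", "ciat899_mannitol",
            "nodd2_control", "nodd2_mannitol", "also_salt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("inventory lacks required column(s): ", paste(miss, collapse = ", "))
  if (!nrow(tab)) stop("inventory file is empty")
  flagCols <- setdiff(need, c("name", "dnac_position"))
  for (fc in flagCols)
    if (!all(tab[[fc]] %in% c(0L, 1L)))
      stop("inventory column '", fc, "' must be 0/1")
  structures <- Map(parseStructure, tab$name,
                    ifelse(is.na(tab$dnac_position), NA_integer_,
                           tab$dnac_position))
  structures <- unname(structures)
  tab$label <- vapply(structures, structureLabel, character(1))
  if (anyDuplicated(tab$label))
    stop("duplicate inventory structure: '",
         tab$label[duplicated(tab$label)][1L], "'")
  attr(tab, "structures") <- structures
  if (!quiet)
    message("inventory: ", nrow(tab), " structures; detection totals: ",
            paste(flagCols, colSums(tab[flagCols]), sep = "=", collapse = ", "))
  tab
}

#' Parsed structures of an inventory
#'
#' @param inventory Data frame from [readStructureInventory()].
#' @return List of [LCOStructure-class] objects, in row order.
#' @export
inventoryStructures <- function(inventory) {
  s <- attr(inventory, "structures")
  if (is.null(s))
    s <- unname(Map(parseStructure, inventory$name,
                    ifelse(is.na(inventory$dnac_position), NA_integer_,
                           inventory$dnac_position)))
  s
}
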