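#' Canonical prey groups
#'
#' The 38 ecologically informative prey groups used throughout the package.
#' Most groups correspond to a phylum or class of the prey; crustaceans are
#' resolved to order/superorder because gut-content descriptions of
#' crustaceans tend to be detailed, and three groups are ecological rather
#' than taxonomic ("detritus", "inorganic", "zooplankton" - the latter
#' gathering all eggs and larvae regardless of taxonomy).  "benthic
#' autotroph" covers macroalgae, turf, and seagrass; "phytoplankton" is the
#' pelagic autotroph group.
#'
#' User crosswalks may map arbitrary raw prey labels onto these groups but
#' may not extend the group list itself.
#'
#' @return character vector of 38 group names.
#' @export
prey_groups <- function() {
  c("Actinopterygii", "Annelida", "Anthozoa", "Arachnida", "Asteroidea",
    "benthic autotroph", "Bivalvia", "Bryozoa", "Cephalopoda", "Cirripedia",
    "Crinoidea", "Cyanobacteria", "Decapoda", "detritus", "Echinoidea",
    "Foraminifera", "Gastropoda", "Harpacticoida", "Hemichordata",
    "Holothuroidea", "inorganic", "Insecta", "Medusozoa", "Nematoda",
    "Nemertea", "Ophiuroidea", "Ostracoda", "Peracarida", "phytoplankton",
    "Platyhelminthes", "Polyplacophora", "Porifera", "Pycnogonida",
    "Scaphopoda", "Sipuncula", "Stomatopoda", "Tunicata", "zooplankton")
}

#' Build a prey-item crosswalk
#'
#' A crosswalk maps raw gut-content prey labels onto the canonical prey
#' groups ([prey_groups()]).  A raw label may map to one group, be split
#' across two groups with weights summing to 1 (e.g. the classic
#' "Algae & Detritus" item split equally between "benthic autotroph" and
#' "detritus"), or be flagged for discard (non-informative or redundant
#' items such as "unidentified fragments").
#'
#' @param table data.frame with columns `label`, `group`, `weight`
#'   (optional, default 1) and `discard` (optional logical, default FALSE).
#'   Split labels occupy several rows whose weights must sum to 1.
#' @return object of class `prey_crosswalk`.
#' @export
prey_crosswalk <- function(table) {
  stopifnot(is.data.frame(table))
  assert_columns(table, c("label", "group"), "crosswalk")
  if (is.null(table$weight)) table$weight <- 1
  if (is.null(table$discard)) table$discard <- FALSE
  table$discard <- as.logical(table$discard)
  table$weight <- as.numeric(table$weight)
  bad <- !table$discard & !(table$group %in% prey_groups())
  if (any(bad)) {
    stop("crosswalk targets outside the canonical 38 prey groups: ",
         paste(unique(table$group[bad]), collapse = ", "), call. = FALSE)
  }
  w <- tapply(table$weight[!table$discard], table$label[!table$discard], sum)
  off <- names(w)[abs(w - 1) > 1e-6]
  if (length(off)) {
    stop("crosswalk split weights do not sum to 1 for label(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  structure(table, class = c("prey_crosswalk", "data.frame"))
}

#' Read a crosswalk from a delimited file
#'
#' @param path CSV/TSV file with columns `label,group,weight,discard`
#'   (weight and discard optional).
#' @param sep field separator; `NULL` autodetects between "," and tab.
#' @return object of class `prey_crosswalk`.
#' @export
read_crosswalk <- function(path, sep = NULL) {
  df <- read_delim_auto(path, sep)
  prey_crosswalk(df)
}
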