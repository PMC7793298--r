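# Gut-content record tables, diet matrices, and tree I/O.
#
# A gut_records table holds one row per (individual, prey item) with the
# fraction of gut volume/frequency that item contributed.  Standardization
# proceeds: read -> crosswalk to canonical prey groups -> drop species with
# too few guts -> average per-individual renormalized proportions into a
# consumer x prey-group diet matrix.

read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("no data rows in file: ", path, call. = FALSE)
  df
}

#' Construct a gut-content record table
#'
#' @param df data.frame with columns `individual_id`, `species`, `location`,
#'   `prey_item`, `value` (fraction of the gut in \[0,1\]).
#' @param tol tolerance on the per-individual sum of values (must be
#'   <= 1 + tol).
#' @return object of class `gut_records` (a data.frame).
#' @export
gut_records <- function(df, tol = 1e-6) {
  assert_columns(df, c("individual_id", "species", "location",
                       "prey_item", "value"), "gut records")
  df$value <- as.numeric(df$value)
  neg <- which(df$value < 0)
  if (length(neg)) {
    stop("negative prey value at row(s): ",
         paste(head(neg, 5), collapse = ", "), call. = FALSE)
  }
  sums <- tapply(df$value, df$individual_id, sum)
  over <- names(sums)[sums > 1 + tol]
  if (length(over)) {
    stop("per-individual prey fractions exceed 1 for individual(s): ",
         paste(head(over, 5), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("gut_records", "data.frame"))
}

#' Read gut-content records from a delimited file
#'
#' @param path CSV or TSV file.
#' @param dialect list of reader options: `sep` (autodetected when NULL),
#'   `percent` (logical; values are 0-100 percentages to be rescaled to
#'   0-1), and `columns` (named character vector renaming file columns to
#'   the canonical `individual_id`, `species`, `location`, `prey_item`,
#'   `value`).
#' @return a `gut_records` table.
#' @export
read_gut_contents <- function(path, dialect = list()) {
  df <- read_delim_auto(path, dialect$sep %||% NULL)
  cols <- dialect$columns %||% NULL
  if (!is.null(cols)) {
    # cols maps canonical name -> file column name
    for (canon in names(cols)) {
      if (!cols[[canon]] %in% names(df)) {
        stop("dialect column not found in file: ", cols[[canon]],
             call. = FALSE)
      }
      names(df)[names(df) == cols[[canon]]] <- canon
    }
  }
  assert_columns(df, c("individual_id", "species", "location",
                       "prey_item", "value"), basename(path))
  df$value <- as.numeric(df$value)
  if (isTRUE(dialect$percent)) df$value <- df$value / 100
  gut_records(df)
}

#' Write gut-content records to CSV (round-trips with [read_gut_contents()])
#' @param records a `gut_records` table.
#' @param path output file.
#' @export
write_gut_contents <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Map raw prey labels to canonical prey groups
#'
#' Applies a [prey_crosswalk()]: one-to-one labels are renamed, split labels
#' are expanded into several rows with the value multiplied by the split
#' weight, and labels flagged for discard are removed (their mass is *not*
#' redistributed here; renormalization happens in [build_diet_matrix()]).
#'
#' @param records a `gut_records` table with raw prey labels.
#' @param xwalk a `prey_crosswalk`.
#' @return a `gut_records` table whose `prey_item` values are canonical
#'   prey groups.
#' @export
apply_crosswalk <- function(records, xwalk) {
  stopifnot(inherits(xwalk, "prey_crosswalk"))
  known <- unique(xwalk$label)
  unmapped <- setdiff(unique(records$prey_item), known)
  if (length(unmapped)) {
    stop("prey label(s) neither mapped nor discarded: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  keep <- xwalk[!xwalk$discard, , drop = FALSE]
  n_discard <- sum(!(records$prey_item %in% keep$label))
  if (n_discard) tg_log(n_discard, " record(s) dropped as non-informative")
  idx <- which(records$prey_item %in% keep$label)
  rec <- as.data.frame(records)[idx, , drop = FALSE]
  # expand split labels: one output row per (record, target group)
  m <- merge(rec, as.data.frame(keep)[, c("label", "group", "weight")],
             by.x = "prey_item", by.y = "label", sort = FALSE)
  m$value <- m$value * m$weight
  out <- m[, c("individual_id", "species", "location", "group", "value")]
  names(out)[names(out) == "group"] <- "prey_item"
  out <- out[order(match(out$individual_id, records$individual_id)), ]
  gut_records(out)
}

#' Drop species with too few sampled guts
#'
#' Retains only species represented by at least `min_guts` distinct
#' (non-empty) individuals.
#'
#' @param records a `gut_records` table.
#' @param min_guts minimum number of distinct individuals per species
#'   (default 10).
#' @return filtered `gut_records` table (possibly empty, with a warning).
#' @export
filter_min_guts <- function(records, min_guts = 10) {
  stopifnot(min_guts >= 1)
  n_ind <- tapply(records$individual_id, records$species,
                  function(x) length(unique(x)))
  keep_sp <- names(n_ind)[n_ind >= min_guts]
  dropped <- setdiff(names(n_ind), keep_sp)
  if (length(dropped)) {
    tg_log("dropped ", length(dropped), " species with < ", min_guts,
           " guts: ", paste(head(dropped, 10), collapse = ", "))
  }
  out <- records[records$species %in% keep_sp, , drop = FALSE]
  if (nrow(out) == 0) warning("no species passed the min-guts filter")
  rownames(out) <- NULL
  structure(as.data.frame(out), class = c("gut_records", "data.frame"))
}

#' Build the consumer x prey-group diet matrix
#'
#' Each individual's prey fractions are renormalized to sum to 1 (so that
#' discarded items do not deflate the remaining ones), then averaged with
#' equal weight per individual within each consumer node.  Consumer nodes
#' are species (`by_location = FALSE`, pooling individuals globally) or
#' species-x-location pairs (`by_location = TRUE`).
#'
#' @param records a crosswalked, filtered `gut_records` table.
#' @param by_location key consumers by species x location?
#' @param groups column set of the matrix; defaults to [prey_groups()].
#' @return a `diet_matrix`: numeric matrix with consumer rows summing to 1,
#'   with attributes `n_guts` (individuals per row), `species` and
#'   `location` (per-row metadata; location is `NA` for pooled rows).
#' @export
build_diet_matrix <- function(records, by_location = FALSE,
                              groups = prey_groups()) {
  df <- as.data.frame(records)
  extra <- setdiff(unique(df$prey_item), groups)
  if (length(extra)) {
    stop("prey items outside the group set (crosswalk not applied?): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ind_tot <- tapply(df$value, df$individual_id, sum)
  empty <- names(ind_tot)[ind_tot <= 0]
  if (length(empty)) {
    tg_log(length(empty), " empty gut(s) excluded")
    df <- df[!(df$individual_id %in% empty), , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no non-empty guts to aggregate", call. = FALSE)
  df$norm <- df$value / as.numeric(ind_tot[df$individual_id])
  key <- if (by_location) paste(df$species, df$location, sep = "@@")
         else df$species
  df$key <- key
  # per-individual profile summed over duplicate items, then averaged
  agg <- aggregate(norm ~ key + individual_id + prey_item, data = df,
                   FUN = sum)
  n_guts <- tapply(agg$individual_id, agg$key,
                   function(x) length(unique(x)))
  keys <- sort(unique(agg$key))
  M <- matrix(0, nrow = length(keys), ncol = length(groups),
              dimnames = list(keys, groups))
  cell <- tapply(agg$norm, list(agg$key, agg$prey_item), sum)
  M[rownames(cell), colnames(cell)] <- ifelse(is.na(cell), 0, cell)
  M <- M / as.numeric(n_guts[keys])
  stopifnot(all(abs(rowSums(M) - 1) < 1e-9))
  sp <- if (by_location) sub("@@.*$", "", keys) else keys
  loc <- if (by_location) sub("^.*@@", "", keys) else rep(NA_character_,
                                                          length(keys))
  structure(M, class = c("diet_matrix", "matrix"),
            n_guts = as.integer(n_guts[keys]), species = sp, location = loc)
}

#' Write / read a diet matrix as CSV
#'
#' The CSV stores one consumer per row with its metadata columns
#' (`consumer`, `species`, `location`, `n_guts`) followed by the 38 prey
#' group columns; [read_diet_matrix()] round-trips it.
#'
#' @param diet a `diet_matrix`.
#' @param path output CSV path.
#' @export
write_diet_matrix <- function(diet, path) {
  df <- data.frame(consumer = rownames(diet),
                   species = attr(diet, "species"),
                   location = attr(diet, "location"),
                   n_guts = attr(diet, "n_guts"),
                   as.data.frame(unclass(diet), check.names = FALSE),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_diet_matrix
#' @return [read_diet_matrix()] returns the `diet_matrix`.
#' @export
read_diet_matrix <- function(path) {
  df <- read_delim_auto(path, ",")
  meta <- c("consumer", "species", "location", "n_guts")
  assert_columns(df, meta, "diet matrix")
  M <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(M) <- df$consumer
  structure(M, class = c("diet_matrix", "matrix"),
            n_guts = as.integer(df$n_guts),
            species = as.character(df$species),
            location = as.character(df$location))
}

#' Read phylogenies and prune them to an analysis species set
#'
#' Thin wrappers around \pkg{ape}: `read_tree()` parses a single Newick
#' tree, `read_trees()` a multi-tree Newick file (always returning a list),
#' and `prune_to()` drops all tips outside `species`, preserving branch
#' lengths and hence patristic distances among the retained tips.
#'
#' @param path Newick file.
#' @return `read_tree()`: an [ape::read.tree()] `phylo`; `read_trees()`: a
#'   list of `phylo`.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  validate_tree(tr)
  tr
}

#' @rdname read_tree
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("Newick parse error in ", path, call. = FALSE)
  if (inherits(tr, "phylo")) tr <- list(tr)
  lapply(tr, validate_tree)
  unclass(tr)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths in tree", call. = FALSE)
  }
  invisible(tree)
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @param species tips to keep (must all be present in the tree).
#' @export
prune_to <- function(tree, species) {
  miss <- setdiff(species, tree$tip.label)
  if (length(miss)) {
    stop("species missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ape::keep.tip(tree, species)
}
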