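# Agreement between independent trophic classification schemes.
#
# Schemes are standardized onto a common broad-guild vocabulary (by default
# the five broad guilds: herbivores and detritivores, invertivores,
# omnivores, planktivores, piscivores) and compared pairwise over shared
# species with confusion matrices.  Schemes lacking a category are compared
# only across the categories both schemes define.

#' The five broad trophic guilds used to standardize expert schemes
#' @return character vector of length 5.
#' @export
broad_guilds <- function() {
  c("herbivores and detritivores", "invertivores", "omnivores",
    "planktivores", "piscivores")
}

#' Construct a classification scheme
#'
#' @param labels named character vector: species -> guild label.
#' @param scheme_id identifier.
#' @param vocabulary guild vocabulary the scheme draws from; defaults to
#'   the labels present.
#' @return object of class `classification_scheme`.
#' @export
classification_scheme <- function(labels, scheme_id = "scheme",
                                  vocabulary = NULL) {
  stopifnot(!is.null(names(labels)), all(nzchar(names(labels))))
  if (anyDuplicated(names(labels))) {
    warning("duplicated species in scheme '", scheme_id,
            "'; last entry wins")
    labels <- labels[!duplicated(names(labels), fromLast = TRUE)]
  }
  vocabulary <- vocabulary %||% sort(unique(unname(labels)))
  bad <- setdiff(unique(labels), vocabulary)
  if (length(bad)) {
    stop("labels outside declared vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(scheme_id = scheme_id, labels = labels,
                 vocabulary = vocabulary),
            class = "classification_scheme")
}

#' Standardize a raw scheme onto broad guilds
#'
#' Converts a scheme's original trophic categories into the broad-guild
#' vocabulary through a label crosswalk.  The scheme's vocabulary is set to
#' the broad guilds it actually defines, so that downstream comparisons are
#' restricted to categories both schemes share.
#'
#' @param raw named character vector species -> original label, or a
#'   `classification_scheme`.
#' @param crosswalk named character vector original label -> broad guild.
#' @param scheme_id identifier for the standardized scheme.
#' @param guilds target vocabulary (default [broad_guilds()]).
#' @return a `classification_scheme` in the broad-guild vocabulary.
#' @export
standardize_scheme <- function(raw, crosswalk, scheme_id = "scheme",
                               guilds = broad_guilds()) {
  labels <- if (inherits(raw, "classification_scheme")) raw$labels else raw
  if (inherits(raw, "classification_scheme")) scheme_id <- raw$scheme_id
  unmapped <- setdiff(unique(unname(labels)), names(crosswalk))
  if (length(unmapped)) {
    stop("unmapped label(s) in scheme '", scheme_id, "': ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(crosswalk), guilds)
  if (length(bad)) {
    stop("crosswalk targets outside the broad guilds: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mapped <- setNames(unname(crosswalk[unname(labels)]), names(labels))
  classification_scheme(mapped, scheme_id = scheme_id,
                        vocabulary = sort(unique(unname(mapped))))
}

#' Pairwise agreement between two schemes
#'
#' Builds a confusion matrix over species shared by both schemes,
#' restricted to guild categories both schemes define, and measures
#' agreement as the proportion of shared species with matching labels.
#' Pairs sharing fewer than `min_shared` species are skipped (returns
#' `NULL` with a message).
#'
#' @param s1,s2 `classification_scheme` objects.
#' @param min_shared minimum number of shared species (default 50).
#' @return object of class `confusion_matrix` (list: `table` with s1 in
#'   rows and s2 in columns, `n_shared`, `agreement`, `schemes`), or
#'   `NULL` when the pair is skipped.
#' @export
pairwise_agreement <- function(s1, s2, min_shared = 50) {
  common_cats <- intersect(s1$vocabulary, s2$vocabulary)
  sp <- intersect(names(s1$labels), names(s2$labels))
  # restrict to species both schemes place in a shared category
  sp <- sp[s1$labels[sp] %in% common_cats & s2$labels[sp] %in% common_cats]
  if (length(sp) < min_shared) {
    tg_log("pair (", s1$scheme_id, ", ", s2$scheme_id, ") skipped: ",
           length(sp), " shared species < ", min_shared)
    return(NULL)
  }
  a <- factor(s1$labels[sp], levels = common_cats)
  b <- factor(s2$labels[sp], levels = common_cats)
  tab <- table(a, b, dnn = c(s1$scheme_id, s2$scheme_id))
  structure(list(table = tab, n_shared = length(sp),
                 agreement = sum(diag(tab)) / length(sp),
                 schemes = c(s1$scheme_id, s2$scheme_id)),
            class = "confusion_matrix")
}

#' Summarize agreement across a set of schemes
#'
#' Computes all pairwise agreements (pairs sharing at least `min_shared`
#' species) and per-guild agreement: for each retained ordered pair (A, B)
#' and each guild g that both define, the fraction of A's g-species that B
#' also labels g; directions are pooled, then averaged over pairs without
#' weighting by shared-species count.
#'
#' @param schemes list of `classification_scheme` objects (>= 2).
#' @param min_shared minimum shared species per pair.
#' @return list: `pairs` (data.frame scheme1, scheme2, n_shared,
#'   agreement), `median_agreement`, `per_guild` (named mean per-guild
#'   agreement), `confusions` (list of `confusion_matrix`).
#' @export
agreement_summary <- function(schemes, min_shared = 50) {
  stopifnot(length(schemes) >= 2)
  pairs <- utils::combn(length(schemes), 2)
  rows <- list(); confs <- list(); pg <- list()
  for (j in seq_len(ncol(pairs))) {
    cm <- pairwise_agreement(schemes[[pairs[1, j]]], schemes[[pairs[2, j]]],
                             min_shared = min_shared)
    if (is.null(cm)) next
    rows[[length(rows) + 1L]] <- data.frame(
      scheme1 = cm$schemes[1], scheme2 = cm$schemes[2],
      n_shared = cm$n_shared, agreement = cm$agreement,
      stringsAsFactors = FALSE)
    confs[[length(confs) + 1L]] <- cm
    tab <- cm$table
    for (dir in 1:2) {
      t2 <- if (dir == 1) tab else t(tab)
      rs <- rowSums(t2)
      ok <- rs > 0
      pg[[length(pg) + 1L]] <- setNames(diag(t2)[ok] / rs[ok],
                                        rownames(t2)[ok])
    }
  }
  if (!length(rows)) stop("no scheme pair shares >= ", min_shared,
                          " species", call. = FALSE)
  pair_df <- do.call(rbind, rows)
  allg <- unique(unlist(lapply(pg, names)))
  per_guild <- vapply(allg, function(g) {
    vals <- unlist(lapply(pg, function(x) x[g]))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  list(pairs = pair_df, median_agreement = median(pair_df$agreement),
       per_guild = per_guild, confusions = confs)
}
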