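#' Canonical taxonomy ranks used by scaffold classification
#' @return Character vector of the seven ranks, highest first.
#' @export
taxonomy_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Majority-vote lineage for one scaffold
#'
#' Proceeds rank by rank from superkingdom downward. At each rank the label
#' carried by strictly more than 50% of the scaffold's proteins wins; the
#' vote stops at the first rank without such a winner, and the returned
#' lineage is the path of winning labels. An exact 50% split never wins.
#' By default unannotated proteins (NA at a rank) still count toward the
#' denominator — the conservative reading of "more than half of the
#' proteins agree"; set `count_unannotated = FALSE` to take the denominator
#' as the proteins annotated at that rank.
#'
#' @param protein_lineages data.frame with one row per protein and the
#'   columns of [taxonomy_ranks()] (missing columns treated as all-NA;
#'   empty strings treated as NA).
#' @param count_unannotated Include unannotated proteins in the denominator.
#' @return List with `lineage` (named character vector over all ranks, NA
#'   below the stop rank) and `support` (winning fraction per assigned
#'   rank, NA elsewhere).
#' @export
vote_lineage <- function(protein_lineages, count_unannotated = TRUE) {
  ranks <- taxonomy_ranks()
  lineage <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
  support <- stats::setNames(rep(NA_real_, length(ranks)), ranks)
  n <- nrow(protein_lineages) %||% 0L
  if (is.null(n) || n == 0L) {
    return(list(lineage = lineage, support = support))
  }
  for (r in ranks) {
    labels <- if (r %in% names(protein_lineages)) {
      as.character(protein_lineages[[r]])
    } else rep(NA_character_, n)
    labels[!is.na(labels) & labels == ""] <- NA_character_
    tab <- table(labels, useNA = "no")
    if (length(tab) == 0L) break
    denom <- if (count_unannotated) n else sum(tab)
    top <- which.max(tab)
    if (tab[top] > denom / 2) {
      lineage[r] <- names(tab)[top]
      support[r] <- as.numeric(tab[top]) / denom
    } else break
  }
  list(lineage = lineage, support = support)
}

#' Classify every scaffold of an assembly by protein-taxonomy majority vote
#'
#' Applies [vote_lineage()] independently to each scaffold's proteins.
#' Scaffolds listed in `scaffolds` but carrying no proteins come back
#' unclassified; proteins referencing a scaffold absent from `scaffolds`
#' raise an error naming the offenders.
#'
#' @param lineage_table data.frame with `protein_id`, `scaffold_id` and the
#'   rank columns (blank/NA = unannotated). Every protein maps to exactly
#'   one scaffold.
#' @param scaffolds Optional character vector of all scaffold ids (defaults
#'   to those present in the table).
#' @param count_unannotated Passed to [vote_lineage()].
#' @return data.frame: one row per scaffold, assigned rank labels plus a
#'   `support_<rank>` fraction per rank.
#' @export
classify_assembly <- function(lineage_table, scaffolds = NULL,
                              count_unannotated = TRUE) {
  stopifnot(is.data.frame(lineage_table),
            all(c("protein_id", "scaffold_id") %in% names(lineage_table)))
  if (anyDuplicated(lineage_table$protein_id)) {
    stop("proteins must map to exactly one scaffold; duplicated: ",
         paste(unique(lineage_table$protein_id[
           duplicated(lineage_table$protein_id)]), collapse = ", "),
         call. = FALSE)
  }
  scaffolds <- scaffolds %||% sort(unique(lineage_table$scaffold_id))
  unknown <- setdiff(lineage_table$scaffold_id, scaffolds)
  if (length(unknown) > 0) {
    stop("proteins reference unknown scaffolds: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ranks <- taxonomy_ranks()
  rows <- lapply(scaffolds, function(sc) {
    sub <- lineage_table[lineage_table$scaffold_id == sc, , drop = FALSE]
    v <- vote_lineage(sub, count_unannotated = count_unannotated)
    out <- data.frame(scaffold_id = sc, n_proteins = nrow(sub),
                      stringsAsFactors = FALSE)
    for (r in ranks) out[[r]] <- v$lineage[[r]]
    for (r in ranks) out[[paste0("support_", r)]] <- v$support[[r]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
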