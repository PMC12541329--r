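#' Read a gene table from TSV
#'
#' Gene identifiers are opaque strings matched exactly and case-sensitively.
#'
#' @param path TSV file with a header row; `#` lines are comments.
#' @param id_column Name of the identifier column. Default `"gene_id"`.
#' @param duplicates `"error"` (default) rejects duplicated ids naming the
#'   offender; `"first"` keeps the first occurrence.
#' @return A tibble with at least the id column.
#' @export
read_gene_table <- function(path, id_column = "gene_id",
                            duplicates = c("error", "first")) {
  duplicates <- match.arg(duplicates)
  tbl <- read_tsv_strict(path)
  if (nrow(tbl) == 0) abort(paste0("empty gene table: ", path))
  if (!id_column %in% names(tbl)) {
    abort(paste0("missing id column '", id_column, "' in ", path))
  }
  tbl[[id_column]] <- as.character(tbl[[id_column]])
  dup <- tbl[[id_column]][duplicated(tbl[[id_column]])]
  if (length(dup) > 0) {
    if (duplicates == "error") {
      abort(paste0("duplicated gene ids in ", path, ": ",
                   paste(unique(dup), collapse = ", ")))
    }
    tbl <- tbl[!duplicated(tbl[[id_column]]), ]
  }
  tbl
}

#' Assemble the Sfp catalog from two candidate lists
#'
#' The catalog is the union of both lists with per-gene source flags; the
#' intersection is the "conservative set" (retrievable with
#' [conservative_set()]).
#'
#' @param list_a,list_b Character vectors of gene ids (or single-column data
#'   frames with a `gene_id` column).
#' @return A tibble with columns `gene_id`, `in_list_a`, `in_list_b`,
#'   `age_class` (initialised to `"UNASSIGNED"`), carrying a `provenance`
#'   attribute with the input sizes.
#' @export
assemble_catalog <- function(list_a, list_b) {
  ids_a <- unique(as.character(if (is.data.frame(list_a)) list_a$gene_id else list_a))
  ids_b <- unique(as.character(if (is.data.frame(list_b)) list_b$gene_id else list_b))
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    abort("both candidate lists must be non-empty")
  }
  ids <- sort(union(ids_a, ids_b))
  cat_tbl <- tibble(
    gene_id = ids,
    in_list_a = ids %in% ids_a,
    in_list_b = ids %in% ids_b,
    age_class = "UNASSIGNED"
  )
  attr(cat_tbl, "provenance") <- list(n_list_a = length(ids_a),
                                      n_list_b = length(ids_b),
                                      n_union = length(ids),
                                      n_intersection = sum(cat_tbl$in_list_a &
                                                             cat_tbl$in_list_b))
  cat_tbl
}

#' Conservative subset of a catalog
#'
#' Genes flagged as high-confidence by both source studies.
#'
#' @param catalog A catalog tibble from [assemble_catalog()].
#' @return The subset of rows with both source flags set.
#' @export
conservative_set <- function(catalog) {
  dplyr::filter(catalog, .data$in_list_a & .data$in_list_b)
}

#' Attach phylostratigraphic age classes to a catalog
#'
#' Genes missing from the age table and not in `exceptions` stay `UNASSIGNED`
#' with a warning (not fatal); declared exceptions stay `UNASSIGNED` silently.
#' `UNASSIGNED` genes are excluded from all age-stratified statistics
#' downstream.
#'
#' @param catalog Catalog tibble.
#' @param age_table Data frame with columns `gene_id`, `age_class` (A..E), or a
#'   named character vector.
#' @param exceptions Character vector of gene ids allowed to stay unassigned.
#' @return The catalog with `age_class` filled in.
#' @export
assign_ages <- function(catalog, age_table, exceptions = character()) {
  if (!is.data.frame(age_table)) {
    age_table <- tibble(gene_id = names(age_table),
                        age_class = unname(age_table))
  }
  .check_classes(age_table$age_class)
  map <- setNames(as.character(age_table$age_class),
                  as.character(age_table$gene_id))
  cls <- unname(map[catalog$gene_id])
  cls[is.na(cls)] <- "UNASSIGNED"
  missing_ids <- catalog$gene_id[cls == "UNASSIGNED"]
  unexplained <- setdiff(missing_ids, exceptions)
  if (length(unexplained) > 0) {
    warn(paste0(length(unexplained), " gene(s) absent from the age table and ",
                "not in the exception list: ",
                paste(head(unexplained, 5), collapse = ", "),
                if (length(unexplained) > 5) ", ..." else ""))
  }
  prov <- attr(catalog, "provenance")
  catalog$age_class <- cls
  attr(catalog, "provenance") <- prov
  catalog
}

#' Cross-validate age classes against independent deep-ortholog calls
#'
#' A gene with an independent 1-to-1 ortholog call in a distant lineage should
#' carry an old age class; a discrepancy is a checked gene whose assigned class
#' is not in `old_classes`.
#'
#' @param catalog Catalog with assigned ages.
#' @param ortholog_ids Gene ids with independent deep ortholog support.
#' @param old_classes Classes regarded as consistent with deep orthology.
#'   Default `c("A", "B", "C")`.
#' @return An `sfp_validation` object with `n_checked`, `n_discrepant`,
#'   `discrepant_ids`, `rate_percent`.
#' @export
cross_validate_ages <- function(catalog, ortholog_ids,
                                old_classes = c("A", "B", "C")) {
  ortholog_ids <- unique(as.character(ortholog_ids))
  members <- catalog[catalog$gene_id %in% ortholog_ids &
                       catalog$age_class != "UNASSIGNED", ]
  non_members <- setdiff(ortholog_ids, catalog$gene_id)
  if (nrow(members) == 0) abort("no ortholog ids overlap the catalog")
  discrepant <- members$gene_id[!members$age_class %in% old_classes]
  structure(list(
    n_checked = nrow(members),
    n_discrepant = length(discrepant),
    discrepant_ids = sort(discrepant),
    excluded_ids = sort(non_members),
    rate_percent = 100 * length(discrepant) / nrow(members)
  ), class = "sfp_validation")
}

#' @export
print.sfp_validation <- function(x, ...) {
  cat(sprintf("Age cross-validation: %d/%d discrepant (%.2f%%)\n",
              x$n_discrepant, x$n_checked, x$rate_percent))
  if (x$n_discrepant > 0) {
    cat("  discrepant:", paste(x$discrepant_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Collapse paralog groups to one representative gene each
#'
#' Ungrouped genes pass through as singletons. The default representative is
#' the member with the most non-missing attached attributes, ties broken
#' lexicographically by gene id; `"first"` takes the lexicographically smallest
#' id outright. If group members disagree on age class the representative is
#' given the oldest class in the group, with a warning. Idempotent.
#'
#' @param catalog Catalog tibble.
#' @param groups Data frame with columns `gene_id`, `paralog_group`, or a named
#'   vector mapping gene id to group id. May be `NULL` (no-op).
#' @param strategy `"most_complete"` (default) or `"first"`.
#' @return The collapsed catalog with a `paralog_group` column.
#' @export
collapse_paralogs <- function(catalog, groups,
                              strategy = c("most_complete", "first")) {
  strategy <- match.arg(strategy)
  if (is.null(groups)) return(catalog)
  if (!is.data.frame(groups)) {
    groups <- tibble(gene_id = names(groups), paralog_group = unname(groups))
  }
  gmap <- setNames(as.character(groups$paralog_group),
                   as.character(groups$gene_id))
  grp <- unname(gmap[catalog$gene_id])
  # singletons get their own group keyed by gene id
  grp[is.na(grp)] <- paste0(".singleton.", catalog$gene_id[is.na(grp)])
  cat2 <- catalog
  cat2$paralog_group <- grp

  attr_cols <- setdiff(names(cat2), c("gene_id", "paralog_group"))
  completeness <- rowSums(!is.na(as.data.frame(cat2[attr_cols])) &
                            as.data.frame(cat2[attr_cols]) != "UNASSIGNED")

  keep <- unlist(lapply(split(seq_len(nrow(cat2)), cat2$paralog_group),
                        function(idx) {
    if (length(idx) == 1) return(idx)
    if (strategy == "most_complete") {
      best <- completeness[idx] == max(completeness[idx])
      idx <- idx[best]
    }
    idx[order(cat2$gene_id[idx])][1]
  }), use.names = FALSE)

  out <- cat2[sort(keep), ]
  # oldest class within each multi-member group wins
  if ("age_class" %in% names(cat2)) {
    multi <- names(which(table(cat2$paralog_group) > 1))
    for (g in multi) {
      cls <- cat2$age_class[cat2$paralog_group == g]
      cls <- cls[cls != "UNASSIGNED"]
      if (length(unique(cls)) > 1) {
        oldest <- AGE_CLASSES[min(match(cls, AGE_CLASSES))]
        warn(paste0("paralog group ", g, " mixes age classes; keeping ", oldest))
        out$age_class[out$paralog_group == g] <- oldest
      }
    }
  }
  out$paralog_group[startsWith(out$paralog_group, ".singleton.")] <- NA_character_
  attr(out, "provenance") <- attr(catalog, "provenance")
  out
}
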