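#' Tau tissue-specificity index
#'
#' `tau = sum(1 - x_i/max(x)) / (N - 1)` over N tissues: 0 for uniform
#' expression, 1 for single-tissue expression. Expression is transformed with
#' `log2(x + 1)` by default to stop the maximum tissue saturating the index on
#' FPKM-scale data; pass `transform = "identity"` for the raw scale.
#'
#' @param x Non-negative expression vector over at least two tissues.
#' @param transform `"log2"` (default, `log2(x + 1)`) or `"identity"`.
#' @return Tau in \[0, 1\], or `NA` when all values are zero (undefined).
#' @export
tau <- function(x, transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  if (length(x) < 2) abort("tau needs at least two tissues")
  if (any(!is.finite(x)) || any(x < 0)) abort("expression must be finite and non-negative")
  if (transform == "log2") x <- log2(x + 1)
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Per-gene tau and tissue-specificity calls
#'
#' A gene is tissue-specific when `tau >= threshold`; it is target-specific
#' when additionally its maximum expression falls in `target_tissues` (e.g. the
#' male reproductive glands). All-zero genes get `NA` tau and no calls. Argmax
#' ties resolve to the first tissue in column order and are recorded.
#'
#' @param expression Data frame with a `gene_id` column and one numeric column
#'   per tissue, or a numeric matrix with gene ids as row names.
#' @param threshold Specificity cutoff on tau. Default 0.9.
#' @param target_tissues Character vector of tissue labels; must be a subset of
#'   the matrix tissues. May be empty (no target-specific calls).
#' @param transform Passed to [tau()].
#' @return Tibble: `gene_id`, `tau`, `argmax_tissue`, `argmax_tied`,
#'   `is_specific`, `is_target_specific`.
#' @export
specificity_calls <- function(expression, threshold = 0.9,
                              target_tissues = character(),
                              transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  if (is.data.frame(expression)) {
    if (!"gene_id" %in% names(expression)) abort("expression needs a gene_id column")
    ids <- as.character(expression$gene_id)
    mat <- as.matrix(expression[setdiff(names(expression), "gene_id")])
  } else {
    mat <- as.matrix(expression)
    ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  tissues <- colnames(mat)
  if (is.null(tissues) || anyDuplicated(tissues)) {
    abort("tissue labels must be present and unique")
  }
  if (ncol(mat) < 2) abort("need at least two tissues")
  unknown <- setdiff(target_tissues, tissues)
  if (length(unknown) > 0) {
    abort(paste("unknown target tissue(s):", paste(unknown, collapse = ", ")))
  }
  storage.mode(mat) <- "double"
  taus <- apply(mat, 1, tau, transform = transform)
  amax_i <- apply(mat, 1, which.max)
  tied <- apply(mat, 1, function(r) sum(r == max(r)) > 1 && max(r) > 0)
  out <- tibble(
    gene_id = ids,
    tau = as.numeric(taus),
    argmax_tissue = if_else(is.na(taus), NA_character_, tissues[amax_i]),
    argmax_tied = if_else(is.na(taus), NA, tied),
    is_specific = !is.na(taus) & taus >= threshold
  )
  out$is_target_specific <- out$is_specific &
    !is.na(out$argmax_tissue) & out$argmax_tissue %in% target_tissues
  out
}

#' Compare tau across gene age classes
#'
#' Joins tau results to catalog age classes and runs the nonparametric group
#' comparison: Kruskal-Wallis across the five classes, or Wilcoxon rank-sum for
#' the pre- vs during-radiation contrast (class A vs classes B-E), with
#' BH-adjusted pairwise post hoc tests.
#'
#' @param tau_results Output of [specificity_calls()].
#' @param catalog Catalog with assigned `age_class`.
#' @param grouping `"five_class"` (default) or `"pre_vs_during"`.
#' @return An `sfp_group_comparison`.
#' @export
compare_tau_by_age <- function(tau_results, catalog,
                               grouping = c("five_class", "pre_vs_during")) {
  grouping <- match.arg(grouping)
  df <- dplyr::inner_join(tau_results,
                          dplyr::select(catalog, "gene_id", "age_class"),
                          by = "gene_id")
  df <- df[!is.na(df$tau) & df$age_class != "UNASSIGNED", ]
  if (grouping == "pre_vs_during") {
    df$group <- if_else(df$age_class == "A", "pre_radiation", "during_radiation")
  } else {
    df$group <- df$age_class
  }
  compare_groups(df, "tau", "group")
}
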