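#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_violin geom_boxplot
#'   geom_point geom_hline position_dodge facet_wrap labs scale_y_log10
#' @export
ggplot2::autoplot

#' Observed vs expected age-class composition
#'
#' @param object An `sfp_gof` from [age_composition_test()].
#' @param ... Unused.
#' @return A ggplot: clustered columns of observed (solid) and expected counts
#'   per age class.
#' @export
autoplot.sfp_gof <- function(object, ...) {
  df <- tidyr::pivot_longer(object$residuals,
                            c("observed", "expected"),
                            names_to = "kind", values_to = "count")
  ggplot(df, aes(x = .data$age_class, y = .data$count, fill = .data$kind)) +
    geom_col(position = position_dodge()) +
    labs(x = "age class", y = "genes",
         title = sprintf("%s: chi2 = %.2f, p = %.2g",
                         object$method, object$chi2, object$p),
         fill = NULL)
}

#' Group comparison violin/box plot
#'
#' @param object An `sfp_group_comparison`.
#' @param data The data frame the comparison was run on, with `value` and
#'   `group` columns as used by [compare_groups()] (stored values are not kept
#'   in the result object).
#' @param value,group Column names.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_group_comparison <- function(object, data, value, group, ...) {
  df <- tibble(value = data[[value]], group = as.character(data[[group]]))
  df <- df[is.finite(df$value), ]
  ggplot(df, aes(x = .data$group, y = .data$value)) +
    geom_violin() +
    geom_boxplot(width = 0.15, outlier.shape = NA) +
    labs(x = NULL, y = value,
         title = sprintf("%s: p = %.2g", object$omnibus$method,
                         object$omnibus$p))
}

#' Tau distribution across age classes
#'
#' @param tau_results Output of [specificity_calls()].
#' @param catalog Catalog with `age_class`.
#' @param threshold Specificity threshold drawn as a reference line.
#' @return A ggplot of tau violins per age class.
#' @export
plot_tau_by_age <- function(tau_results, catalog, threshold = 0.9) {
  df <- dplyr::inner_join(tau_results,
                          dplyr::select(catalog, "gene_id", "age_class"),
                          by = "gene_id")
  df <- df[!is.na(df$tau) & df$age_class != "UNASSIGNED", ]
  ggplot(df, aes(x = .data$age_class, y = .data$tau)) +
    geom_violin() +
    geom_boxplot(width = 0.15, outlier.shape = NA) +
    geom_hline(yintercept = threshold, linetype = "dashed") +
    labs(x = "age class", y = "tau tissue-specificity index")
}

#' Subnetwork enrichment dot plot
#'
#' @param object Enrichment tibble from [mc_age_enrichment()].
#' @param direction Which direction to show. Default `"enrichment"`.
#' @param ... Unused.
#' @return A ggplot of observed vs expected counts per subnetwork and class,
#'   sized by -log10 adjusted p.
#' @export
plot_enrichment <- function(object, direction = "enrichment", ...) {
  df <- object[object$direction == direction, ]
  ggplot(df, aes(x = .data$age_class, y = .data$observed)) +
    geom_col(fill = "grey70") +
    geom_point(aes(y = .data$expected), shape = 4, size = 2) +
    facet_wrap(~subnetwork, scales = "free_y") +
    labs(x = "age class", y = "members (bar: observed, x: expected)",
         title = paste("Subnetwork age-class", direction))
}
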