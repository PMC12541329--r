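# build a catalog tibble directly from ids and classes
make_catalog <- function(ids, classes, in_a = TRUE, in_b = TRUE) {
  tibble::tibble(gene_id = ids, in_list_a = in_a, in_list_b = in_b,
                 age_class = classes)
}

# exact hypergeometric tails for subnetwork class enrichment/depletion:
# the independent oracle the Monte Carlo resampling p is checked against
hyper_enrich_p <- function(obs, m_class, n_universe, k_sub) {
  stats::phyper(obs - 1, m_class, n_universe - m_class, k_sub,
                lower.tail = FALSE)
}
hyper_deplete_p <- function(obs, m_class, n_universe, k_sub) {
  stats::phyper(obs, m_class, n_universe - m_class, k_sub)
}

# brute-force degree recount from an edge data frame (independent of igraph)
recount_degrees <- function(edges, sfp_ids) {
  nodes <- union(unique(c(edges$gene_a, edges$gene_b)), sfp_ids)
  k_total <- k_within <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    k_total[a] <- k_total[a] + 1L
    k_total[b] <- k_total[b] + 1L
    if (a %in% sfp_ids && b %in% sfp_ids) {
      k_within[a] <- k_within[a] + 1L
      k_within[b] <- k_within[b] + 1L
    }
  }
  tibble::tibble(gene_id = nodes, k_total = unname(k_total),
                 k_within = unname(k_within))[nodes %in% sfp_ids, ]
}
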