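STRING_CHANNELS <- c("neighborhood", "fusion", "cooccurrence", "coexpression",
                     "experiments", "database", "textmining")

#' Combine per-channel interaction confidence scores
#'
#' STRING-convention recombination: the prior is removed from each channel
#' (`s' = max(0, (s - prior)/(1 - prior))`), channels combine as
#' `1 - prod(1 - s')`, and the prior is added back. Edges with no evidence
#' above the prior get a combined score of 0 (the prior floor is reported as
#' 0). Channel columns may be on the 0-1 scale or the STRING export 0-999
#' integer scale (auto-detected).
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and any subset of
#'   the channel columns `neighborhood`, `fusion`, `cooccurrence`,
#'   `coexpression`, `experiments`, `database`, `textmining`.
#' @param exclude Channels to drop before combining. Default `"textmining"`.
#' @param prior Evidence prior. Default 0.041 (the STRING convention).
#' @return `edges` with a `combined_score` column appended.
#' @export
combine_scores <- function(edges, exclude = "textmining", prior = 0.041) {
  stopifnot(is.data.frame(edges))
  bad <- setdiff(exclude, STRING_CHANNELS)
  if (length(bad) > 0) abort(paste("unknown channel(s):", paste(bad, collapse = ", ")))
  chans <- intersect(setdiff(STRING_CHANNELS, exclude), names(edges))
  if (length(chans) == 0) abort("no usable channel columns found")
  m <- as.matrix(edges[chans])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("channel scores must be finite")
  # STRING integer export dialect (0-999); real scores cannot exceed 1
  if (max(m) > 2) m <- m / 1000
  if (any(m < 0) || any(m > 1)) abort("channel scores must lie in [0, 1]")
  snop <- (m - prior) / (1 - prior)
  snop[snop < 0] <- 0
  comb_nop <- 1 - apply(1 - snop, 1, prod)
  combined <- ifelse(comb_nop > 0, comb_nop * (1 - prior) + prior, 0)
  edges$combined_score <- combined
  edges
}

#' Build a high-confidence interaction network
#'
#' Retains edges with combined score at or above the threshold; flags nodes by
#' Sfp membership; keeps isolated Sfp nodes with degree zero. Self-loops are
#' dropped with a warning and duplicate pairs (in either orientation) are
#' collapsed to the first occurrence.
#'
#' @param edges Data frame with `gene_a`, `gene_b` and either a
#'   `combined_score` column or per-channel score columns (then recombined via
#'   [combine_scores()] with the given `exclude`/`prior`).
#' @param sfp_ids Character vector of Sfp gene ids.
#' @param threshold High-confidence cutoff. Default 0.7.
#' @param exclude,prior Passed to [combine_scores()] when recombining.
#' @return An `sfp_network`: an igraph graph with vertex attribute `sfp`, plus
#'   the threshold and Sfp id set.
#' @export
build_network <- function(edges, sfp_ids, threshold = 0.7,
                          exclude = "textmining", prior = 0.041) {
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort("edges need gene_a and gene_b columns")
  }
  if (!"combined_score" %in% names(edges)) {
    edges <- combine_scores(edges, exclude = exclude, prior = prior)
  }
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, ]
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    warn(sprintf("collapsing %d duplicate edge row(s)", sum(duplicated(key))))
  }
  keep_first <- !duplicated(key)
  canon <- tibble(gene_a = a[keep_first], gene_b = b[keep_first],
                  combined_score = edges$combined_score[keep_first])
  retained <- canon[canon$combined_score >= threshold, ]
  sfp_ids <- unique(as.character(sfp_ids))
  nodes <- sort(union(unique(c(canon$gene_a, canon$gene_b)), sfp_ids))
  g <- igraph::graph_from_data_frame(retained, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$sfp <- nodes %in% sfp_ids
  structure(list(graph = g, threshold = threshold, sfp_ids = sfp_ids),
            class = "sfp_network")
}

#' @export
print.sfp_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Sfp interaction network: %d nodes (%d Sfp), %d edges >= %.3g\n",
              igraph::vcount(g), sum(igraph::V(g)$sfp), igraph::ecount(g),
              x$threshold))
  invisible(x)
}

# induced subgraph over Sfp nodes only
.sfp_subgraph <- function(network) {
  igraph::induced_subgraph(network$graph,
                           igraph::V(network$graph)[igraph::V(network$graph)$sfp])
}

#' Partition each Sfp's interaction degree
#'
#' For every Sfp node: total degree, degree within the Sfp set, and degree to
#' non-Sfp partners. `k_total = k_within + k_outside` by construction.
#'
#' @param network An `sfp_network`.
#' @return Tibble: `gene_id`, `k_total`, `k_within`, `k_outside`.
#' @export
degree_partition <- function(network) {
  g <- network$graph
  sfp_v <- igraph::V(g)[igraph::V(g)$sfp]
  k_total <- igraph::degree(g, v = sfp_v)
  gs <- .sfp_subgraph(network)
  k_within_all <- igraph::degree(gs)
  k_within <- k_within_all[names(k_total)]
  tibble(gene_id = names(k_total),
         k_total = as.integer(k_total),
         k_within = as.integer(k_within),
         k_outside = as.integer(k_total - k_within))
}

#' Extract size-filtered Sfp subnetworks
#'
#' Connected components of the Sfp-induced subgraph (interactions through
#' non-Sfp intermediates do not merge components) with at least `min_size`
#' members, sorted by size descending; the largest is flagged as the core
#' (ties broken by the smallest lexicographic member id).
#'
#' @param network An `sfp_network`.
#' @param min_size Minimum component size. Default 4.
#' @return Tibble with one row per member gene: `subnetwork` (integer rank),
#'   `gene_id`, `size`, `is_core`. Zero rows (with a warning) when no
#'   component reaches `min_size`.
#' @export
extract_subnetworks <- function(network, min_size = 4) {
  gs <- .sfp_subgraph(network)
  comp <- igraph::components(gs)
  sizes <- comp$csize
  ids <- which(sizes >= min_size)
  if (length(ids) == 0) {
    warn(sprintf("no connected component reaches min_size = %d", min_size))
    return(tibble(subnetwork = integer(0), gene_id = character(0),
                  size = integer(0), is_core = logical(0)))
  }
  members <- lapply(ids, function(i) {
    sort(names(comp$membership)[comp$membership == i])
  })
  ord <- order(-sizes[ids], vapply(members, `[`, character(1), 1))
  ids <- ids[ord]; members <- members[ord]
  purrr::map_dfr(seq_along(ids), function(r) {
    tibble(subnetwork = r, gene_id = members[[r]],
           size = length(members[[r]]), is_core = r == 1L)
  })
}

#' Monte Carlo age-class enrichment of subnetworks
#'
#' For each (subnetwork, class) cell, `n_resamples` subsets of the subnetwork's
#' size are drawn from the universe without replacement; the enrichment p-value
#' is `(1 + #resamples with count >= observed)/(n_resamples + 1)` and the
#' depletion p-value uses `<=`. BH adjustment is applied per direction across
#' all subnetwork-by-class cells. Expected counts are `size * class frequency
#' in the universe`. Each subnetwork draws from its own seed-keyed stream, so
#' results are independent of execution order.
#'
#' @param subnetworks Tibble from [extract_subnetworks()].
#' @param age_labels Named character vector `gene_id -> class`, or a data frame
#'   with `gene_id` and `age_class` columns.
#' @param universe Character vector of gene ids to resample from. Default: the
#'   genes belonging to the reported subnetworks. Every universe gene must have
#'   an age class.
#' @param n_resamples Number of resamples. Default 100000.
#' @param seed Master seed (required).
#' @return Tibble: `subnetwork`, `size`, `age_class`, `observed`, `expected`,
#'   `direction`, `p_raw`, `p_adj`, `n_resamples`.
#' @export
mc_age_enrichment <- function(subnetworks, age_labels, universe = NULL,
                              n_resamples = 100000, seed) {
  if (missing(seed)) abort("seed is required")
  if (is.data.frame(age_labels)) {
    age_labels <- setNames(as.character(age_labels$age_class),
                           as.character(age_labels$gene_id))
  }
  if (is.null(universe)) universe <- unique(subnetworks$gene_id)
  universe <- unique(as.character(universe))
  cls <- unname(age_labels[universe])
  if (any(is.na(cls)) || any(!cls %in% AGE_CLASSES)) {
    abort("every universe gene needs an age class in A..E")
  }
  if (!all(subnetworks$gene_id %in% universe)) {
    abort("subnetwork members must be contained in the universe")
  }
  cls_code <- match(cls, AGE_CLASSES)
  n_univ <- length(universe)
  freq <- tabulate(cls_code, nbins = 5) / n_univ

  subs <- split(subnetworks$gene_id, subnetworks$subnetwork)
  rows <- purrr::map_dfr(names(subs), function(sn) {
    members <- subs[[sn]]
    k <- length(members)
    if (k > n_univ) abort("subnetwork larger than the universe")
    obs <- tabulate(match(unname(age_labels[members]), AGE_CLASSES), nbins = 5)
    ge <- integer(5); le <- integer(5)
    with_seed(child_seed(seed, "mc_age_enrichment", sn), {
      for (r in seq_len(n_resamples)) {
        cnt <- tabulate(cls_code[sample.int(n_univ, k)], nbins = 5)
        ge <- ge + (cnt >= obs)
        le <- le + (cnt <= obs)
      }
    })
    tibble(subnetwork = as.integer(sn), size = k,
           age_class = rep(AGE_CLASSES, 2),
           observed = rep(obs, 2),
           expected = rep(k * freq, 2),
           direction = rep(c("enrichment", "depletion"), each = 5),
           p_raw = c((1 + ge) / (n_resamples + 1),
                     (1 + le) / (n_resamples + 1)),
           n_resamples = as.integer(n_resamples))
  })
  rows %>%
    group_by(.data$direction) %>%
    mutate(p_adj = bh_adjust(.data$p_raw)) %>%
    ungroup() %>%
    arrange(.data$direction, .data$subnetwork, .data$age_class)
}

#' Association between subnetwork membership and reproductive function
#'
#' Chi-square test of independence on the subnetworks-by-{reproductive,
#' non-reproductive} contingency table, with the p-value from margin-preserving
#' Monte Carlo simulation, plus per-cell post hoc adjusted standardized
#' residuals with BH correction.
#'
#' @param subnetworks Tibble from [extract_subnetworks()].
#' @param repro_flags Named logical vector `gene_id -> flag`, or data frame
#'   with `gene_id` and `reproductive_flag`.
#' @param n_sim Number of simulated tables. Default 2000.
#' @param seed Master seed (required).
#' @return List of class `sfp_assoc`: `test` (an `sfp_test`), `table`, and a
#'   `posthoc` tibble.
#' @export
reproductive_association <- function(subnetworks, repro_flags, n_sim = 2000,
                                     seed) {
  if (missing(seed)) abort("seed is required")
  if (is.data.frame(repro_flags)) {
    repro_flags <- setNames(as.logical(repro_flags$reproductive_flag),
                            as.character(repro_flags$gene_id))
  }
  flags <- repro_flags[subnetworks$gene_id]
  if (any(is.na(flags))) abort("every subnetwork member needs a reproductive flag")
  tab <- table(subnetwork = subnetworks$subnetwork,
               reproductive = factor(if_else(flags, "reproductive",
                                             "non_reproductive"),
                                     levels = c("reproductive",
                                                "non_reproductive")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate contingency table (zero margin)")
  }
  test <- chi_square_independence(tab, monte_carlo_n = n_sim,
                                  seed = child_seed(seed,
                                                    "reproductive_association"))
  z <- test$stdres
  p_raw <- 2 * pnorm(-abs(as.numeric(z)))
  posthoc <- tibble(
    subnetwork = rep(rownames(z), times = ncol(z)),
    category = rep(colnames(z), each = nrow(z)),
    z = as.numeric(z),
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    direction = if_else(as.numeric(z) >= 0, "over", "under")
  )
  structure(list(test = test, table = tab, posthoc = posthoc),
            class = "sfp_assoc")
}

#' @export
print.sfp_assoc <- function(x, ...) {
  print(x$test)
  print(x$table)
  cat("Post hoc adjusted residuals:\n")
  print(as.data.frame(x$posthoc), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export a network with node annotations
#'
#' Writes GraphML (via igraph) and/or an edge-list TSV plus a node-attribute
#' TSV (age class, reproductive flag, subnetwork id, core membership).
#'
#' @param network An `sfp_network`.
#' @param path Output path prefix (extensions are appended).
#' @param subnetworks Optional tibble from [extract_subnetworks()].
#' @param catalog Optional catalog supplying `age_class` and
#'   `reproductive_flag` node attributes.
#' @param format `"graphml"`, `"tsv"`, or `"both"`.
#' @return Character vector of files written, invisibly.
#' @export
export_network <- function(network, path, subnetworks = NULL, catalog = NULL,
                           format = c("graphml", "tsv", "both")) {
  format <- match.arg(format)
  g <- network$graph
  nodes <- igraph::V(g)$name
  if (!is.null(catalog)) {
    idx <- match(nodes, catalog$gene_id)
    if ("age_class" %in% names(catalog)) {
      igraph::V(g)$age_class <- if_else(is.na(idx), "UNASSIGNED",
                                        catalog$age_class[idx])
    }
    if ("reproductive_flag" %in% names(catalog)) {
      igraph::V(g)$reproductive <- !is.na(idx) & catalog$reproductive_flag[idx]
    }
  }
  if (!is.null(subnetworks) && nrow(subnetworks) > 0) {
    idx <- match(nodes, subnetworks$gene_id)
    igraph::V(g)$subnetwork <- if_else(is.na(idx), NA_integer_,
                                       subnetworks$subnetwork[idx])
    igraph::V(g)$is_core <- !is.na(idx) & subnetworks$is_core[idx]
  }
  written <- character(0)
  if (format %in% c("graphml", "both")) {
    f <- paste0(path, ".graphml")
    igraph::write_graph(g, f, format = "graphml")
    written <- c(written, f)
  }
  if (format %in% c("tsv", "both")) {
    fe <- paste0(path, "_edges.tsv")
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("gene_a", "gene_b")
    write_tsv_strict(as_tibble(el), fe)
    fn <- paste0(path, "_nodes.tsv")
    nd <- igraph::as_data_frame(g, what = "vertices")
    names(nd)[1] <- "gene_id"
    write_tsv_strict(as_tibble(nd), fn)
    written <- c(written, fe, fn)
  }
  invisible(written)
}
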