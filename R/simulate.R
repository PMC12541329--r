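#' Generate a synthetic Sfp catalog with age labels
#'
#' Emits two overlapping candidate gene lists and a gene-to-age-class table
#' with known ground truth. The intersection has exactly `round(overlap * n)`
#' genes; the remaining genes are split equally between the two lists (the
#' first list gets the odd gene). Classes are assigned multinomially from
#' `class_props`.
#'
#' @param n Number of catalog genes (>= 2).
#' @param class_props Named proportions over A..E. Default
#'   `c(A = .62, B = .10, C = .10, D = .08, E = .10)`, the marginal structure
#'   of a 357-gene catalog with 220 pre-radiation genes.
#' @param overlap Fraction of genes present in both lists. Default `228/357`.
#' @param seed Integer seed.
#' @return List: `list_a`, `list_b` (tibbles with `gene_id`), `age_table`,
#'   `truth`, `params`.
#' @export
gen_catalog <- function(n = 357,
                        class_props = c(A = 0.62, B = 0.10, C = 0.10,
                                        D = 0.08, E = 0.10),
                        overlap = 228 / 357, seed) {
  if (n < 2) abort("n must be at least 2")
  if (overlap < 0 || overlap > 1) abort("overlap must be in [0, 1]")
  .check_props(class_props[AGE_CLASSES])
  with_seed(child_seed(seed, "gen_catalog"), {
    ids <- sprintf("g%05d", seq_len(n))
    cls <- sample(AGE_CLASSES, n, replace = TRUE,
                  prob = class_props[AGE_CLASSES])
    n_int <- round(overlap * n)
    n_only <- n - n_int
    a_only <- ceiling(n_only / 2)
    perm <- sample(ids)
    both <- perm[seq_len(n_int)]
    only_a <- perm[n_int + seq_len(a_only)]
    only_b <- setdiff(perm, c(both, only_a))
    truth <- tibble(gene_id = ids, age_class = cls,
                    in_list_a = ids %in% c(both, only_a),
                    in_list_b = ids %in% c(both, only_b))
  })
  list(list_a = tibble(gene_id = sort(truth$gene_id[truth$in_list_a])),
       list_b = tibble(gene_id = sort(truth$gene_id[truth$in_list_b])),
       age_table = tibble(gene_id = truth$gene_id,
                          age_class = truth$age_class),
       truth = truth,
       params = list(n = n, class_props = class_props, overlap = overlap,
                     seed = seed))
}

#' Generate independent deep-ortholog calls for age validation
#'
#' Samples `n_checked - n_discrepant` genes from old classes (A-C) and plants
#' `n_discrepant` genes from young classes (D-E) among them, so the validation
#' report should recover exactly `n_discrepant / n_checked`.
#'
#' @param age_table Tibble with `gene_id`, `age_class`.
#' @param n_checked Number of genes with ortholog calls.
#' @param n_discrepant Number of planted discrepancies.
#' @param seed Integer seed.
#' @return List: `ortholog_ids` (character), `truth`.
#' @export
gen_ortholog_calls <- function(age_table, n_checked, n_discrepant, seed) {
  old <- age_table$gene_id[age_table$age_class %in% c("A", "B", "C")]
  young <- age_table$gene_id[age_table$age_class %in% c("D", "E")]
  if (length(old) < n_checked - n_discrepant || length(young) < n_discrepant) {
    abort("not enough genes of the required classes to plant the calls")
  }
  with_seed(child_seed(seed, "gen_ortholog_calls"), {
    consistent <- sample(old, n_checked - n_discrepant)
    planted <- sample(young, n_discrepant)
  })
  list(ortholog_ids = sort(c(consistent, planted)),
       truth = tibble(gene_id = c(consistent, planted),
                      planted_discrepant = c(rep(FALSE, length(consistent)),
                                             rep(TRUE, length(planted)))))
}

#' Generate a genes-by-tissues expression matrix with planted specificity
#'
#' Specific genes express at `fg_level` in one target tissue and `bg_level`
#' elsewhere; nonspecific genes express at `bg_level` everywhere. Multiplicative
#' lognormal noise with coefficient of variation `noise_cv` (mean 1) is applied
#' throughout.
#'
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues. Default 31, the adult tissue panel size
#'   the pipeline emulates.
#' @param frac_specific Fraction of genes with a planted specific profile.
#' @param fg_level,bg_level Foreground/background expression (must satisfy
#'   `fg_level >= bg_level >= 0`).
#' @param noise_cv Lognormal noise CV (0 disables noise).
#' @param target_tissue Optional tissue label all planted genes point to;
#'   default: a random tissue per gene.
#' @param gene_ids Optional gene ids (default `g00001...`).
#' @param seed Integer seed.
#' @return List: `expression` (tibble, `gene_id` + one column per tissue),
#'   `truth`, `params`.
#' @export
gen_expression <- function(n_genes, n_tissues = 31, frac_specific = 0.5,
                           fg_level = 500, bg_level = 5, noise_cv = 0.2,
                           target_tissue = NULL, gene_ids = NULL, seed) {
  if (fg_level < bg_level || bg_level < 0) {
    abort("need fg_level >= bg_level >= 0")
  }
  tissues <- sprintf("tissue_%02d", seq_len(n_tissues))
  if (!is.null(target_tissue) && !target_tissue %in% tissues) {
    tissues[1] <- target_tissue
  }
  ids <- gene_ids %||% sprintf("g%05d", seq_len(n_genes))
  with_seed(child_seed(seed, "gen_expression"), {
    specific <- seq_len(n_genes) <= round(frac_specific * n_genes)
    specific <- sample(specific)
    tgt <- ifelse(specific,
                  if (is.null(target_tissue)) sample(tissues, n_genes,
                                                     replace = TRUE)
                  else target_tissue,
                  NA_character_)
    base <- matrix(bg_level, n_genes, n_tissues,
                   dimnames = list(ids, tissues))
    for (i in which(specific)) base[i, tgt[i]] <- fg_level
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      noise <- matrix(rlnorm(n_genes * n_tissues, meanlog = -sdlog^2 / 2,
                             sdlog = sdlog), n_genes, n_tissues)
      base <- base * noise
    }
  })
  expr <- as_tibble(base)
  expr <- dplyr::bind_cols(tibble(gene_id = ids), expr)
  list(expression = expr,
       truth = tibble(gene_id = ids, planted_specific = specific,
                      planted_tissue = tgt),
       params = list(n_genes = n_genes, n_tissues = n_tissues,
                     frac_specific = frac_specific, fg_level = fg_level,
                     bg_level = bg_level, noise_cv = noise_cv, seed = seed))
}

#' Generate a planted-partition interaction network with channel scores
#'
#' Sfp genes are organised into dense blocks (a random spanning cycle plus
#' Bernoulli(`p_in`) extras keeps every block connected); between-block Sfp
#' edges appear with probability `p_out`, edges to/among non-Sfp genes with
#' `p_cross`. Intended edges carry an `experiments` channel score drawn above
#' the confidence threshold; `n_decoy` decoy edges carry only a high
#' `textmining` score, so they must vanish once text mining is excluded.
#'
#' @param block_sizes Integer vector of Sfp block sizes. Default
#'   `c(64, 13, 6, 5, 5, 5)`, the size structure the pipeline emulates.
#' @param block_class_counts Optional list of named class-count vectors, one
#'   per block (exact composition); otherwise classes are multinomial from
#'   `class_props`.
#' @param class_props Named age-class proportions for genes without exact
#'   counts. Default the catalog-like `c(.62, .10, .10, .08, .10)`.
#' @param p_in Within-block edge probability (> `p_out`). Default 0.35.
#' @param p_out Between-block Sfp edge probability. Default 0.
#' @param n_nonsfp Number of non-Sfp genes. Default 100.
#' @param p_cross Probability of each Sfp/non-Sfp and non-Sfp pair edge.
#'   Default 0.02.
#' @param n_sfp_isolated Sfp genes outside any block (only cross edges).
#'   Default 0.
#' @param block_repro_props Optional per-block probability that a member is
#'   flagged reproductive; scalar recycled. Default 0.5.
#' @param score_range Range the `experiments` channel score of intended edges
#'   is drawn from. Default `c(0.75, 0.99)`.
#' @param n_decoy Number of text-mining-only decoy edges. Default 0.
#' @param sfp_gene_ids Optional externally supplied Sfp gene ids; block members
#'   are drawn from them at random and any surplus becomes isolated Sfp nodes
#'   (overriding `n_sfp_isolated`).
#' @param age_classes Optional named vector `gene_id -> class` fixing the age
#'   classes of supplied ids (overrides `block_class_counts`/`class_props`).
#' @param seed Integer seed.
#' @return List: `edges` (tibble with channel columns), `sfp_ids`, `age_table`,
#'   `truth`, `params`.
#' @export
gen_network <- function(block_sizes = c(64, 13, 6, 5, 5, 5),
                        block_class_counts = NULL,
                        class_props = c(A = 0.62, B = 0.10, C = 0.10,
                                        D = 0.08, E = 0.10),
                        p_in = 0.35, p_out = 0, n_nonsfp = 100, p_cross = 0.02,
                        n_sfp_isolated = 0, block_repro_props = 0.5,
                        score_range = c(0.75, 0.99), n_decoy = 0,
                        sfp_gene_ids = NULL, age_classes = NULL, seed) {
  if (!(p_in > p_out) || p_out < 0) abort("need p_in > p_out >= 0")
  n_blocked <- sum(block_sizes)
  if (!is.null(sfp_gene_ids)) {
    sfp_gene_ids <- unique(as.character(sfp_gene_ids))
    if (length(sfp_gene_ids) < n_blocked) {
      abort("fewer sfp_gene_ids than block members needed")
    }
    n_sfp_isolated <- length(sfp_gene_ids) - n_blocked
  }
  n_sfp <- n_blocked + n_sfp_isolated
  sfp_ids <- if (is.null(sfp_gene_ids)) {
    sprintf("sfp%04d", seq_len(n_sfp))
  } else {
    with_seed(child_seed(seed, "gen_network", "assign"), sample(sfp_gene_ids))
  }
  nonsfp_ids <- if (n_nonsfp > 0) sprintf("x%04d", seq_len(n_nonsfp)) else character(0)
  block <- c(rep(seq_along(block_sizes), block_sizes),
             rep(NA_integer_, n_sfp_isolated))
  if (length(block_repro_props) == 1) {
    block_repro_props <- rep(block_repro_props, length(block_sizes))
  }

  with_seed(child_seed(seed, "gen_network"), {
    # age classes
    if (!is.null(age_classes)) {
      cls <- unname(age_classes[sfp_ids])
      if (any(is.na(cls))) abort("age_classes must cover every supplied id")
    } else if (!is.null(block_class_counts)) {
      cls <- character(n_sfp)
      for (b in seq_along(block_sizes)) {
        cc <- block_class_counts[[b]]
        if (sum(cc) != block_sizes[b]) {
          abort(sprintf("block %d class counts sum to %d, size is %d",
                        b, sum(cc), block_sizes[b]))
        }
        cls[which(block == b)] <- sample(rep(names(cc), cc))
      }
      if (n_sfp_isolated > 0) {
        cls[is.na(block)] <- sample(AGE_CLASSES, n_sfp_isolated, replace = TRUE,
                                    prob = class_props[AGE_CLASSES])
      }
    } else {
      cls <- sample(AGE_CLASSES, n_sfp, replace = TRUE,
                    prob = class_props[AGE_CLASSES])
    }
    repro <- logical(n_sfp)
    for (b in seq_along(block_sizes)) {
      idx <- which(block == b)
      repro[idx] <- runif(length(idx)) < block_repro_props[b]
    }
    if (n_sfp_isolated > 0) {
      idx <- which(is.na(block))
      repro[idx] <- runif(length(idx)) < 0.5
    }

    pairs <- function(ids_a, ids_b = NULL, p) {
      if (is.null(ids_b)) {
        if (length(ids_a) < 2 || p <= 0) return(NULL)
        cmb <- utils::combn(ids_a, 2)
        on <- runif(ncol(cmb)) < p
        if (!any(on)) return(NULL)
        tibble(gene_a = cmb[1, on], gene_b = cmb[2, on])
      } else {
        if (length(ids_a) == 0 || length(ids_b) == 0 || p <= 0) return(NULL)
        grid <- expand.grid(gene_a = ids_a, gene_b = ids_b,
                            stringsAsFactors = FALSE)
        on <- runif(nrow(grid)) < p
        if (!any(on)) return(NULL)
        as_tibble(grid[on, ])
      }
    }

    edge_list <- list()
    for (b in seq_along(block_sizes)) {
      ids_b <- sfp_ids[which(block == b)]
      if (length(ids_b) >= 2) {
        ring <- sample(ids_b)   # spanning cycle keeps the block connected
        edge_list[[length(edge_list) + 1]] <-
          tibble(gene_a = ring, gene_b = c(ring[-1], ring[1]))
        edge_list[[length(edge_list) + 1]] <- pairs(ids_b, p = p_in)
      }
    }
    if (p_out > 0 && length(block_sizes) > 1) {
      for (b1 in seq_along(block_sizes)) for (b2 in seq_along(block_sizes)) {
        if (b1 < b2) {
          edge_list[[length(edge_list) + 1]] <-
            pairs(sfp_ids[which(block == b1)], sfp_ids[which(block == b2)],
                  p_out)
        }
      }
    }
    edge_list[[length(edge_list) + 1]] <- pairs(sfp_ids, nonsfp_ids, p_cross)
    edge_list[[length(edge_list) + 1]] <- pairs(nonsfp_ids, p = p_cross)
    edges <- dplyr::bind_rows(edge_list)
    # canonicalise and dedupe (ring edges can coincide with Bernoulli draws)
    a <- pmin(edges$gene_a, edges$gene_b); b <- pmax(edges$gene_a, edges$gene_b)
    edges <- tibble(gene_a = a, gene_b = b)
    edges <- edges[edges$gene_a != edges$gene_b, ]
    edges <- dplyr::distinct(edges)
    n_e <- nrow(edges)
    edges$neighborhood <- 0
    edges$fusion <- 0
    edges$cooccurrence <- 0
    edges$coexpression <- round(runif(n_e, 0, 0.15), 3)
    edges$experiments <- round(runif(n_e, score_range[1], score_range[2]), 3)
    edges$database <- 0
    edges$textmining <- round(runif(n_e, 0, 0.4), 3)
    if (n_decoy > 0) {
      all_ids <- c(sfp_ids, nonsfp_ids)
      da <- sample(all_ids, n_decoy, replace = TRUE)
      db <- sample(all_ids, n_decoy, replace = TRUE)
      keep <- da != db
      decoys <- tibble(gene_a = pmin(da[keep], db[keep]),
                       gene_b = pmax(da[keep], db[keep]),
                       neighborhood = 0, fusion = 0, cooccurrence = 0,
                       coexpression = 0,
                       experiments = 0, database = 0,
                       textmining = round(runif(sum(keep), 0.9, 0.99), 3))
      decoys <- dplyr::anti_join(decoys, edges, by = c("gene_a", "gene_b"))
      edges <- dplyr::bind_rows(edges, decoys)
    }
  })

  truth <- tibble(gene_id = c(sfp_ids, nonsfp_ids),
                  is_sfp = c(rep(TRUE, n_sfp), rep(FALSE, length(nonsfp_ids))),
                  block = c(block, rep(NA_integer_, length(nonsfp_ids))),
                  age_class = c(cls, rep(NA_character_, length(nonsfp_ids))),
                  reproductive_flag = c(repro, rep(NA, length(nonsfp_ids))))
  list(edges = edges, sfp_ids = sfp_ids,
       age_table = tibble(gene_id = sfp_ids, age_class = cls),
       truth = truth,
       params = list(block_sizes = block_sizes, p_in = p_in, p_out = p_out,
                     n_nonsfp = n_nonsfp, p_cross = p_cross, seed = seed))
}

#' Generate polymorphism/divergence counts with known true alpha
#'
#' Per gene: `Ps ~ Poisson(theta_s)`, `Ds ~ Poisson(d_s)`; neutral
#' nonsynonymous divergence scaled so its per-site ratio to synonymous
#' divergence is `omega0`; adaptive substitutions added so the expected
#' fraction of nonsynonymous substitutions fixed by selection is `true_alpha`;
#' neutral nonsynonymous polymorphism scaled by `omega0` with SFS bins
#' proportional to `1/i` (the standard neutral shape); a deleterious fraction
#' `frac_deleterious` of nonsynonymous polymorphism confined to bins at or
#' below `del_freq_max`.
#'
#' @param n_genes Number of genes.
#' @param Ln,Ls Nonsynonymous/synonymous site counts per gene.
#' @param theta_s Expected synonymous segregating sites per gene.
#' @param d_s Expected synonymous substitutions per gene.
#' @param omega0 Nonadaptive (neutral-scaled) omega stratum.
#' @param true_alpha True proportion of adaptive nonsynonymous substitutions,
#'   in `[0, 1)`.
#' @param frac_deleterious Fraction of nonsynonymous polymorphism that is
#'   deleterious (low-frequency), in `[0, 1)`.
#' @param del_freq_max Maximum derived-allele frequency of deleterious
#'   variants. Default 0.05.
#' @param sample_size Number of sampled chromosomes.
#' @param population Population label. Default `"SYN"`.
#' @param gene_ids Optional gene ids (default `g00001...`); overrides
#'   `n_genes`.
#' @param seed Integer seed.
#' @return List: `counts` (tibble), `sfs` (tibble `gene_id`, `derived_count`,
#'   `n_sites`), `truth`, `params`.
#' @export
gen_mkt_counts <- function(n_genes = 100, Ln = 1500, Ls = 500, theta_s = 20,
                           d_s = 40, omega0 = 0.2, true_alpha = 0,
                           frac_deleterious = 0, del_freq_max = 0.05,
                           sample_size = 160, population = "SYN",
                           gene_ids = NULL, seed) {
  if (!is.null(gene_ids)) n_genes <- length(gene_ids)
  if (true_alpha < 0 || true_alpha >= 1) abort("true_alpha must be in [0, 1)")
  if (frac_deleterious < 0 || frac_deleterious >= 1) {
    abort("frac_deleterious must be in [0, 1)")
  }
  i <- seq_len(sample_size - 1)
  w_neut <- (1 / i) / sum(1 / i)
  del_bins <- which(i / sample_size <= del_freq_max)
  if (frac_deleterious > 0 && length(del_bins) == 0) {
    abort("del_freq_max leaves no SFS bin for deleterious variants")
  }
  w_del <- numeric(sample_size - 1)
  if (length(del_bins) > 0) {
    w_del[del_bins] <- (1 / i[del_bins]) / sum(1 / i[del_bins])
  }
  mu_dn_neut <- omega0 * (d_s / Ls) * Ln
  mu_dn_adapt <- mu_dn_neut * true_alpha / (1 - true_alpha)
  mu_pn_neut <- omega0 * (theta_s / Ls) * Ln
  mu_pn_del <- mu_pn_neut * frac_deleterious / (1 - frac_deleterious)

  ids <- gene_ids %||% sprintf("g%05d", seq_len(n_genes))
  with_seed(child_seed(seed, "gen_mkt_counts", population), {
    Ps <- rpois(n_genes, theta_s)
    Ds <- rpois(n_genes, d_s)
    Dn_neut <- rpois(n_genes, mu_dn_neut)
    Dn_adapt <- rpois(n_genes, mu_dn_adapt)
    Pn_neut <- rpois(n_genes, mu_pn_neut)
    Pn_del <- rpois(n_genes, mu_pn_del)
    sfs_rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
      neut <- if (Pn_neut[g] > 0) {
        as.integer(rmultinom(1, Pn_neut[g], w_neut))
      } else integer(sample_size - 1)
      del <- if (Pn_del[g] > 0) {
        as.integer(rmultinom(1, Pn_del[g], w_del))
      } else integer(sample_size - 1)
      tot <- neut + del
      nz <- which(tot > 0)
      if (length(nz) == 0) return(NULL)
      tibble(gene_id = ids[g], derived_count = nz, n_sites = tot[nz])
    })
  })
  counts <- tibble(gene_id = ids, Pn = Pn_neut + Pn_del, Ps = Ps,
                   Dn = Dn_neut + Dn_adapt, Ds = Ds, Ln = Ln, Ls = Ls,
                   sample_size = sample_size, population = population)
  truth <- tibble(gene_id = ids, Pn_neutral = Pn_neut, Pn_deleterious = Pn_del,
                  Dn_neutral = Dn_neut, Dn_adaptive = Dn_adapt)
  list(counts = counts, sfs = sfs_rows, truth = truth,
       params = list(n_genes = n_genes, Ln = Ln, Ls = Ls, theta_s = theta_s,
                     d_s = d_s, omega0 = omega0, true_alpha = true_alpha,
                     frac_deleterious = frac_deleterious,
                     del_freq_max = del_freq_max, sample_size = sample_size,
                     seed = seed))
}

#' Generate paralog groups over a gene set
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_groups Number of groups.
#' @param group_size Members per group.
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `paralog_group`.
#' @export
gen_paralog_groups <- function(gene_ids, n_groups, group_size, seed) {
  if (n_groups * group_size > length(gene_ids)) {
    abort("not enough genes for the requested groups")
  }
  with_seed(child_seed(seed, "gen_paralog_groups"), {
    members <- sample(gene_ids, n_groups * group_size)
  })
  tibble(gene_id = members,
         paralog_group = rep(sprintf("pg%03d", seq_len(n_groups)),
                             each = group_size))
}
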