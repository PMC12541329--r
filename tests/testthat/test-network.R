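test_that("channel score recombination follows the prior-removal convention", {
  one <- data.frame(gene_a = "a", gene_b = "b", experiments = 0.9,
                    neighborhood = 0, fusion = 0)
  expect_equal(combine_scores(one)$combined_score, 0.9, tolerance = 1e-12)

  zero <- data.frame(gene_a = "a", gene_b = "b", experiments = 0,
                     coexpression = 0)
  expect_equal(combine_scores(zero)$combined_score, 0)

  # independent step-by-step evaluation of the prior-removal formula
  prior <- 0.041
  s1 <- (0.6 - prior) / (1 - prior); s2 <- (0.6 - prior) / (1 - prior)
  nop <- 1 - (1 - s1) * (1 - s2)
  expected <- nop * (1 - prior) + prior
  two <- data.frame(gene_a = "a", gene_b = "b", experiments = 0.6,
                    database = 0.6)
  expect_equal(combine_scores(two)$combined_score, expected, tolerance = 1e-12)

  # excluding text mining removes its evidence entirely
  tm <- data.frame(gene_a = "a", gene_b = "b", experiments = 0.2,
                   textmining = 0.95)
  expect_equal(combine_scores(tm)$combined_score,
               combine_scores(dplyr::select(tm, -textmining))$combined_score)

  # STRING integer export dialect is auto-detected
  int_scale <- data.frame(gene_a = "a", gene_b = "b", experiments = 900L)
  expect_equal(combine_scores(int_scale)$combined_score, 0.9,
               tolerance = 1e-12)

  expect_error(combine_scores(data.frame(gene_a = "a", gene_b = "b",
                                         experiments = 1.2,
                                         database = 0.5)), "\\[0, 1\\]")
})

test_that("network construction thresholds, dedupes, and keeps isolated Sfps", {
  low <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                    combined_score = c(0.2, 0.3))
  net <- build_network(low, sfp_ids = c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(net$graph), 0)
  expect_equal(igraph::vcount(net$graph), 4)

  dup <- data.frame(gene_a = c("a", "b", "a"), gene_b = c("b", "a", "a"),
                    combined_score = 0.9)
  expect_warning(expect_warning(net2 <- build_network(dup, "a"), "self-loop"),
                 "duplicate")
  expect_equal(igraph::ecount(net2$graph), 1)

  sim <- gen_network(block_sizes = c(6, 5), p_in = 0.4, n_nonsfp = 30,
                     p_cross = 0.05, n_decoy = 15, seed = 44)
  net3 <- build_network(sim$edges, sim$sfp_ids)
  # every intended edge clears the threshold via the experiments channel;
  # text-mining-only decoys must all be dropped
  intended <- sim$edges[sim$edges$experiments > 0, ]
  expect_equal(igraph::ecount(net3$graph), nrow(intended))
})

test_that("degree partition matches a brute-force recount and conserves edges", {
  tri <- data.frame(gene_a = c("s1", "s1", "s2", "s1"),
                    gene_b = c("s2", "s3", "s3", "x1"),
                    combined_score = 0.9)
  net <- build_network(tri, sfp_ids = c("s1", "s2", "s3", "s4"))
  dp <- degree_partition(net)
  expect_equal(dp$k_outside[dp$gene_id == "s2"], 0)
  expect_equal(unlist(dp[dp$gene_id == "s4", -1]), c(k_total = 0, k_within = 0,
                                                     k_outside = 0))
  expect_equal(dp$k_total, dp$k_within + dp$k_outside)

  set.seed(55)
  for (i in 1:5) {
    sim <- gen_network(block_sizes = sample(3:8, 2), p_in = 0.5,
                       n_nonsfp = 25, p_cross = 0.08, seed = 100 + i)
    net_i <- build_network(sim$edges, sim$sfp_ids)
    dp_i <- degree_partition(net_i)
    oracle <- recount_degrees(sim$edges, sim$sfp_ids)
    merged <- merge(dp_i, oracle, by = "gene_id")
    expect_equal(merged$k_total.x, merged$k_total.y)
    expect_equal(merged$k_within.x, merged$k_within.y)
    # sum of within-degrees is twice the Sfp-Sfp edge count
    n_ss <- sum(sim$edges$gene_a %in% sim$sfp_ids &
                  sim$edges$gene_b %in% sim$sfp_ids)
    expect_equal(sum(dp_i$k_within), 2 * n_ss)
  }
})

test_that("subnetwork extraction filters by size and flags the core", {
  tri2 <- data.frame(
    gene_a = c("a1", "a2", "a3", "b1", "b2", "b3"),
    gene_b = c("a2", "a3", "a1", "b2", "b3", "b1"),
    combined_score = 0.9)
  net <- build_network(tri2, sfp_ids = unique(unlist(tri2[1:2])))
  expect_warning(sn <- extract_subnetworks(net, min_size = 4), "min_size")
  expect_equal(nrow(sn), 0)

  chain <- function(ids) data.frame(gene_a = ids[-length(ids)],
                                    gene_b = ids[-1], combined_score = 0.9)
  edges <- rbind(chain(paste0("p", 1:5)), chain(paste0("q", 1:4)))
  net2 <- build_network(edges, sfp_ids = unique(unlist(edges[1:2])))
  sn2 <- extract_subnetworks(net2)
  expect_equal(unique(sn2$size[sn2$is_core]), 5)
  expect_equal(max(sn2$subnetwork), 2)

  # non-Sfp intermediates do not merge components
  bridged <- rbind(chain(paste0("p", 1:4)), chain(paste0("q", 1:4)),
                   data.frame(gene_a = c("p1", "x1"), gene_b = c("x1", "q1"),
                              combined_score = 0.9))
  net3 <- build_network(bridged, sfp_ids = c(paste0("p", 1:4),
                                             paste0("q", 1:4)))
  expect_equal(max(extract_subnetworks(net3)$subnetwork), 2)
})

test_that("planted blocks are recovered exactly when disconnected", {
  sim <- gen_network(block_sizes = c(64, 13, 6, 5, 5, 5), p_in = 0.35,
                     p_out = 0, n_nonsfp = 80, p_cross = 0.02, seed = 7)
  net <- build_network(sim$edges, sim$sfp_ids)
  sn <- extract_subnetworks(net)
  sizes <- unique(sn[c("subnetwork", "size")])$size
  expect_equal(sort(sizes, decreasing = TRUE), c(64, 13, 6, 5, 5, 5))
  expect_equal(max(sn$subnetwork), 6)
  expect_equal(unique(sn$size[sn$is_core]), 64)
  # membership matches the generator's planted blocks
  truth <- sim$truth[!is.na(sim$truth$block), ]
  joined <- merge(sn, truth, by = "gene_id")
  tab <- table(joined$subnetwork, joined$block)
  expect_equal(sum(tab > 0), 6)  # one-to-one block/subnetwork correspondence
})

test_that("Monte Carlo enrichment matches the exact tail and is reproducible", {
  # degenerate case: resampling the whole universe leaves p = 1 everywhere
  sn_all <- tibble::tibble(subnetwork = 1L, gene_id = paste0("g", 1:8),
                           size = 8L, is_core = TRUE)
  ages_all <- setNames(rep(c("A", "E"), 4), paste0("g", 1:8))
  en_all <- mc_age_enrichment(sn_all, ages_all, n_resamples = 500, seed = 1)
  expect_true(all(en_all$p_raw == 1))

  # universe of 10 with 5 class-A genes; subnetwork of 4, all class A
  ages10 <- setNames(rep(c("A", "B"), each = 5), paste0("g", 1:10))
  sn4 <- tibble::tibble(subnetwork = 1L, gene_id = paste0("g", 1:4),
                        size = 4L, is_core = TRUE)
  en <- mc_age_enrichment(sn4, ages10, universe = paste0("g", 1:10),
                          n_resamples = 20000, seed = 2)
  pa <- en$p_raw[en$age_class == "A" & en$direction == "enrichment"]
  p_exact <- hyper_enrich_p(4, 5, 10, 4)   # 5/210
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(pa - p_exact), 3 * se + 1 / 20001)

  # fixed seed: bit-reproducible; order of subnetworks does not matter
  en2 <- mc_age_enrichment(sn4, ages10, universe = paste0("g", 1:10),
                           n_resamples = 20000, seed = 2)
  expect_identical(en$p_raw, en2$p_raw)

  two <- dplyr::bind_rows(sn4,
                          tibble::tibble(subnetwork = 2L,
                                         gene_id = paste0("g", 7:10),
                                         size = 4L, is_core = FALSE))
  en_fwd <- mc_age_enrichment(two, ages10, universe = paste0("g", 1:10),
                              n_resamples = 2000, seed = 5)
  en_rev <- mc_age_enrichment(two[rev(seq_len(nrow(two))), ], ages10,
                              universe = paste0("g", 1:10),
                              n_resamples = 2000, seed = 5)
  expect_equal(dplyr::arrange(en_fwd, direction, subnetwork, age_class),
               dplyr::arrange(en_rev, direction, subnetwork, age_class))

  expect_error(mc_age_enrichment(sn4, ages10[1:4], universe = paste0("g", 1:4),
                                 n_resamples = 10, seed = 1), NA)
  expect_error(mc_age_enrichment(sn4, setNames("Z", "g1"), seed = 1), "A..E")
})

test_that("reproductive association detects planted block structure", {
  # planted: block 1 almost all reproductive, block 2 almost none
  sn <- tibble::tibble(
    subnetwork = rep(1:2, c(20, 20)),
    gene_id = paste0("g", 1:40),
    size = 20L, is_core = rep(c(TRUE, FALSE), c(20, 20)))
  flags <- setNames(c(rep(TRUE, 18), FALSE, FALSE,
                      rep(FALSE, 18), TRUE, TRUE), paste0("g", 1:40))
  assoc <- reproductive_association(sn, flags, n_sim = 2000, seed = 3)
  expect_lt(assoc$test$p, 0.01)
  ph <- assoc$posthoc
  over1 <- ph[ph$subnetwork == "1" & ph$category == "reproductive", ]
  expect_equal(over1$direction, "over")
  expect_lt(over1$p_adj, 0.05)
  expect_equal(glance(assoc)$n_sim, 2000L)

  # a uniform table is not significant
  flags_u <- setNames(rep(c(TRUE, FALSE), 20), paste0("g", 1:40))
  assoc_u <- reproductive_association(sn, flags_u, n_sim = 500, seed = 3)
  expect_gt(assoc_u$test$p, 0.5)

  # all-reproductive input degenerates to a zero margin
  expect_error(reproductive_association(sn, setNames(rep(TRUE, 40),
                                                     paste0("g", 1:40)),
                                        n_sim = 10, seed = 1), "margin")
})

test_that("network export round-trips through GraphML and TSV", {
  sim <- gen_network(block_sizes = c(5, 4), p_in = 0.6, n_nonsfp = 10,
                     p_cross = 0.05, seed = 31)
  net <- build_network(sim$edges, sim$sfp_ids)
  sn <- extract_subnetworks(net)
  cat1 <- make_catalog(sim$truth$gene_id,
                       ifelse(is.na(sim$truth$age_class), "UNASSIGNED",
                              sim$truth$age_class))
  d <- withr::local_tempdir()
  files <- export_network(net, file.path(d, "net"), subnetworks = sn,
                          catalog = cat1, format = "both")
  g2 <- igraph::read_graph(file.path(d, "net.graphml"), format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(net$graph)$name)
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  nodes <- read_tsv_strict(file.path(d, "net_nodes.tsv"))
  expect_true(all(c("gene_id", "sfp", "age_class", "subnetwork") %in%
                    names(nodes)))

  # empty edge set still yields valid GraphML with nodes only
  empty <- build_network(data.frame(gene_a = "a", gene_b = "b",
                                    combined_score = 0.1), c("a", "b"))
  export_network(empty, file.path(d, "empty"), format = "graphml")
  ge <- igraph::read_graph(file.path(d, "empty.graphml"), format = "graphml")
  expect_equal(igraph::vcount(ge), 2)
  expect_equal(igraph::ecount(ge), 0)
})
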