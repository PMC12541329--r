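test_that("gene tables read, reject duplicates in strict mode, and round-trip", {
  d <- withr::local_tempdir()
  f <- file.path(d, "genes.tsv")
  writeLines(c("# comment", "gene_id\tsymbol", "g1\ts1", "g2\ts2", "g3\ts3"), f)
  tbl <- read_gene_table(f)
  expect_equal(nrow(tbl), 3)

  fdup <- file.path(d, "dup.tsv")
  writeLines(c("gene_id", "g1", "g2", "g1"), fdup)
  expect_error(read_gene_table(fdup), "g1")
  expect_equal(nrow(read_gene_table(fdup, duplicates = "first")), 2)

  fmiss <- file.path(d, "miss.tsv")
  writeLines(c("other\tcol", "a\tb"), fmiss)
  expect_error(read_gene_table(fmiss), "id column")

  # write -> read -> write round-trips byte-identically
  sim <- gen_catalog(n = 10, overlap = 0.5, seed = 2)
  f1 <- file.path(d, "rt1.tsv"); f2 <- file.path(d, "rt2.tsv")
  write_tsv_strict(sim$age_table, f1)
  write_tsv_strict(read_gene_table(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("catalog assembly does the set algebra with source flags", {
  cat1 <- assemble_catalog(c("g1", "g2"), c("g2", "g3"))
  expect_equal(nrow(cat1), 3)
  expect_equal(sum(cat1$in_list_a & cat1$in_list_b), 1)

  same <- assemble_catalog(c("g1", "g2"), c("g1", "g2"))
  expect_equal(nrow(same), nrow(conservative_set(same)))

  # symmetric up to flag labels; intersection bounded by the smaller list
  a <- sprintf("a%d", 1:20); b <- c(sprintf("a%d", 1:7), sprintf("b%d", 1:5))
  ab <- assemble_catalog(a, b); ba <- assemble_catalog(b, a)
  expect_identical(ab$gene_id, ba$gene_id)
  expect_identical(ab$in_list_a, ba$in_list_b)
  expect_lte(sum(ab$in_list_a & ab$in_list_b), min(length(a), length(b)))

  expect_error(assemble_catalog(character(0), "g1"), "non-empty")
})

test_that("study-scale synthetic lists recover the 357/228 union/intersection", {
  sim <- gen_catalog(n = 357, overlap = 228 / 357, seed = 99)
  cat1 <- assemble_catalog(sim$list_a, sim$list_b)
  prov <- attr(cat1, "provenance")
  expect_equal(prov$n_union, 357)
  expect_equal(prov$n_intersection, 228)
  # the 129 single-study genes split 65/64
  expect_equal(sort(c(sum(cat1$in_list_a & !cat1$in_list_b),
                      sum(cat1$in_list_b & !cat1$in_list_a))), c(64, 65))
})

test_that("age assignment honours exceptions and recovers generator truth", {
  cat5 <- make_catalog(paste0("g", 1:5), rep("UNASSIGNED", 5))
  ages <- tibble::tibble(gene_id = paste0("g", 1:5),
                         age_class = c("A", "B", "C", "D", "E"))
  full <- assign_ages(cat5, ages)
  expect_equal(sum(full$age_class == "UNASSIGNED"), 0)

  expect_silent(part <- assign_ages(cat5, ages[1:4, ], exceptions = "g5"))
  expect_equal(sum(part$age_class == "UNASSIGNED"), 1)
  expect_warning(assign_ages(cat5, ages[1:4, ]), "absent")

  sim <- gen_catalog(n = 300, seed = 13)
  cat_sim <- assign_ages(assemble_catalog(sim$list_a, sim$list_b),
                         sim$age_table)
  truth_counts <- table(factor(sim$truth$age_class, levels = c("A", "B", "C",
                                                               "D", "E")))
  expect_equal(unname(class_counts(cat_sim)), as.integer(truth_counts))
})

test_that("age cross-validation reproduces rates and is order-invariant", {
  classes <- c(rep("A", 100), rep("B", 50), rep("C", 23), rep("D", 3),
               rep("E", 2))
  cat178 <- make_catalog(sprintf("g%03d", 1:178), classes)
  rep1 <- cross_validate_ages(cat178, cat178$gene_id)
  expect_equal(rep1$n_checked, 178)
  expect_equal(rep1$n_discrepant, 5)
  expect_equal(round(rep1$rate_percent, 2), 2.81)

  allA <- make_catalog(paste0("g", 1:10), rep("A", 10))
  expect_equal(cross_validate_ages(allA, allA$gene_id)$rate_percent, 0)

  # permutation of the input id order changes nothing
  set.seed(3)
  rep2 <- cross_validate_ages(cat178, sample(cat178$gene_id))
  expect_equal(rep2$rate_percent, rep1$rate_percent)
  expect_identical(rep2$discrepant_ids, rep1$discrepant_ids)

  # planted discrepancies are recovered from generator truth
  sim <- gen_catalog(n = 357, seed = 8)
  cat_sim <- assign_ages(assemble_catalog(sim$list_a, sim$list_b),
                         sim$age_table)
  orth <- gen_ortholog_calls(sim$age_table, n_checked = 120, n_discrepant = 7,
                             seed = 8)
  repv <- cross_validate_ages(cat_sim, orth$ortholog_ids)
  expect_equal(repv$n_discrepant, 7)
  expect_setequal(repv$discrepant_ids,
                  orth$truth$gene_id[orth$truth$planted_discrepant])

  expect_error(cross_validate_ages(allA, "not_present"), "overlap")
})

test_that("paralog collapse picks deterministic representatives, is idempotent", {
  cat4 <- make_catalog(c("g1", "g2", "g3", "g4"), c("E", "E", "A", "B"))
  grp <- tibble::tibble(gene_id = c("g1", "g2"), paralog_group = "p1")
  col <- collapse_paralogs(cat4, grp)
  expect_equal(nrow(col), 3)
  expect_equal(col$age_class[col$paralog_group %in% "p1"], "E")
  # equal completeness: lexicographic tie-break keeps g1
  expect_true("g1" %in% col$gene_id && !"g2" %in% col$gene_id)

  expect_identical(collapse_paralogs(cat4, NULL), cat4)

  # mixed ages keep the oldest class with a warning
  mixed <- make_catalog(c("g1", "g2"), c("E", "B"))
  expect_warning(colm <- collapse_paralogs(mixed, grp), "oldest|keeping")
  expect_equal(colm$age_class, "B")

  # 10 groups of 3 shrink the catalog by 20; collapsing again is a no-op
  sim <- gen_catalog(n = 200, seed = 4)
  cat_sim <- assign_ages(assemble_catalog(sim$list_a, sim$list_b),
                         sim$age_table)
  groups <- gen_paralog_groups(cat_sim$gene_id, 10, 3, seed = 4)
  c1 <- suppressWarnings(collapse_paralogs(cat_sim, groups))
  expect_equal(nrow(c1), nrow(cat_sim) - 20)
  c2 <- suppressWarnings(collapse_paralogs(c1, groups))
  expect_identical(c1$gene_id, c2$gene_id)
  expect_identical(c1$age_class, c2$age_class)
})
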