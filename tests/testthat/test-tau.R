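test_that("tau closed forms and error handling", {
  expect_equal(tau(c(5, 5, 5, 5), "identity"), 0)
  expect_equal(tau(c(9, 0, 0, 0), "identity"), 1)
  expect_equal(tau(c(10, 5, 0, 0), "identity"), 5 / 6)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(c(-1, 2)), "non-negative")
  expect_error(tau(5), "two tissues")
})

test_that("tau is scale- and permutation-invariant and monotone", {
  set.seed(71)
  for (i in 1:50) {
    x <- rexp(sample(3:31, 1))
    expect_equal(tau(3.7 * x, "identity"), tau(x, "identity"),
                 tolerance = 1e-12)
    perm <- sample(length(x))
    expect_equal(tau(x[perm]), tau(x), tolerance = 1e-12)
    # moving mass from a non-max tissue to the max never decreases tau
    xm <- x
    i_max <- which.max(xm); i_min <- which.min(replace(xm, i_max, Inf))
    shift <- xm[i_min] / 2
    xm[i_max] <- xm[i_max] + shift; xm[i_min] <- xm[i_min] - shift
    expect_gte(tau(xm, "identity"), tau(x, "identity") - 1e-12)
  }
})

test_that("specificity calls flag planted target genes and reject bad labels", {
  m <- rbind(onehot = c(100, 0, 0), uniform = c(7, 7, 7), zero = c(0, 0, 0))
  colnames(m) <- c("mrg", "head", "gut")
  calls <- specificity_calls(m, target_tissues = "mrg")
  expect_true(calls$is_specific[1] && calls$is_target_specific[1])
  expect_false(calls$is_specific[2] || calls$is_target_specific[2])
  expect_true(is.na(calls$tau[3]) && !calls$is_specific[3])
  # target-specific implies specific
  expect_true(all(!calls$is_target_specific | calls$is_specific))
  expect_error(specificity_calls(m, target_tissues = "wing"), "unknown")
})

test_that("planted specific genes are recalled at high contrast", {
  # raw scale: a 100-fold contrast pushes tau to ~0.99
  sim <- gen_expression(n_genes = 200, frac_specific = 0.4, fg_level = 500,
                        bg_level = 5, noise_cv = 0.2,
                        target_tissue = "mrg", seed = 12)
  calls <- specificity_calls(sim$expression, target_tissues = "mrg",
                             transform = "identity")
  planted <- sim$truth$planted_specific
  expect_gte(mean(calls$is_target_specific[planted]), 0.95)
  # log scale needs a near-zero background for tau >= 0.9
  sim_l <- gen_expression(n_genes = 200, frac_specific = 0.4, fg_level = 500,
                          bg_level = 0.3, noise_cv = 0.2,
                          target_tissue = "mrg", seed = 12)
  calls_l <- specificity_calls(sim_l$expression, target_tissues = "mrg")
  expect_gte(mean(calls_l$is_target_specific[sim_l$truth$planted_specific]),
             0.95)
  # noiseless zero background: planted tau exactly 1
  clean <- gen_expression(n_genes = 20, frac_specific = 1, fg_level = 10,
                          bg_level = 0, noise_cv = 0, seed = 3)
  cc <- specificity_calls(clean$expression)
  expect_true(all(cc$tau == 1))
  # fg = bg: flat profiles, tau 0
  flat <- gen_expression(n_genes = 10, frac_specific = 0.5, fg_level = 5,
                         bg_level = 5, noise_cv = 0, seed = 3)
  cf <- specificity_calls(flat$expression, transform = "identity")
  expect_true(all(cf$tau == 0))
})

test_that("tau comparisons across age classes detect planted differences", {
  # two identical groups: p near 1
  tr <- tibble::tibble(gene_id = paste0("g", 1:40),
                       tau = rep(c(0.2, 0.4, 0.6, 0.8), each = 10))
  # interleave classes so both groups hold the same tau multiset
  cat2 <- make_catalog(paste0("g", 1:40), rep(c("A", "B"), 20))
  gc0 <- compare_tau_by_age(tr, cat2)
  expect_gt(gc0$omnibus$p, 0.99)

  # a single outlier class: only its pairs flagged after BH
  set.seed(19)
  n <- 50
  classes <- rep(c("A", "B", "C", "D", "E"), each = n)
  taus <- pmin(1, pmax(0, c(rnorm(n, 0.3, 0.08), rnorm(n * 3, 0.72, 0.08),
                            rnorm(n, 0.72, 0.08))))
  tr5 <- tibble::tibble(gene_id = sprintf("g%03d", 1:(5 * n)), tau = taus)
  cat5 <- make_catalog(tr5$gene_id, classes)
  gc5 <- compare_tau_by_age(tr5, cat5)
  expect_lt(gc5$omnibus$p, 1e-6)
  # every pair involving the outlier class is flagged after BH, and those
  # pairs dominate the ranking; same-distribution pairs stay unremarkable
  pw <- gc5$pairwise
  involves_a <- pw$group1 == "A" | pw$group2 == "A"
  expect_true(all(pw$p_adj[involves_a] < 0.05))
  expect_true(all(sort(pw$p_adj)[1:4] == sort(pw$p_adj[involves_a])))
  expect_gt(median(pw$p_raw[!involves_a]), 0.1)

  # pre- vs during-radiation pooling gives a two-group Wilcoxon
  gc2 <- compare_tau_by_age(tr5, cat5, grouping = "pre_vs_during")
  expect_match(gc2$omnibus$method, "Wilcoxon")
  expect_lt(gc2$omnibus$p, 1e-6)
})

test_that("shifted tau distributions are detected with adequate power", {
  set.seed(29)
  rejections <- 0
  for (r in 1:200) {
    a <- runif(50, 0, 0.7); b <- pmin(1, a + 0.3)
    df <- data.frame(tau = c(a, b), g = rep(c("x", "y"), each = 50))
    if (compare_groups(df, "tau", "g")$omnibus$p < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_gte(rejections / 200, 0.8)
})
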