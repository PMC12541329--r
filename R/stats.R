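#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control, capped at 1, order-preserving with the
#' input vector. Thin, validating wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Empirical p-value with a pseudo-count
#'
#' `p = (1 + #draws meeting the direction) / (n + 1)`. Never returns zero; the
#' smallest attainable value is `1/(n + 1)`.
#'
#' @param observed Observed statistic (scalar).
#' @param null_draws Numeric vector of statistics under the null.
#' @param direction `"ge"` (upper tail) or `"le"` (lower tail).
#' @return Empirical p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_draws, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (length(null_draws) < 1) abort("need at least one null draw")
  hits <- if (direction == "ge") sum(null_draws >= observed)
          else sum(null_draws <= observed)
  (1 + hits) / (length(null_draws) + 1)
}

new_sfp_test <- function(statistic, df = NA_real_, p, method, n_sim = NA_integer_,
                         extra = list()) {
  structure(c(list(statistic = unname(statistic), df = unname(df),
                   p = unname(p), method = method, n_sim = n_sim), extra),
            class = "sfp_test")
}

#' @export
print.sfp_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g", x$statistic))
  if (is.finite(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %.4g", x$p))
  if (!is.na(x$n_sim)) cat(sprintf(" (%d simulations)", x$n_sim))
  cat("\n")
  invisible(x)
}

#' Kruskal-Wallis rank-sum test over a list of groups
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom, via [stats::kruskal.test()].
#'
#' @param groups A named or unnamed list of numeric vectors, one per group.
#' @return An `sfp_test` object.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) abort("need at least two non-empty groups")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1) {
    return(new_sfp_test(0, df = length(groups) - 1, p = 1,
                        method = "Kruskal-Wallis rank-sum test"))
  }
  kt <- kruskal.test(values, g)
  new_sfp_test(kt$statistic, df = kt$parameter, p = kt$p.value,
               method = "Kruskal-Wallis rank-sum test")
}

#' Wilcoxon rank-sum (Mann-Whitney) test with a signed Z
#'
#' Reports the Mann-Whitney U for the first sample and the signed Z from the
#' tie-corrected normal approximation (negative when the first sample ranks
#' lower). The p-value is exact for small tie-free samples in `"exact"` mode,
#' otherwise from the normal approximation without continuity correction.
#'
#' @param x,y Numeric vectors.
#' @param mode `"normal_approx"` or `"exact"`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return An `sfp_test` with fields `statistic` (U), `z`, `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("normal_approx", "exact"),
                              alternative = c("two.sided", "less", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y); nn <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  has_ties <- any(ties > 1)
  if (mode == "exact" && !has_ties && min(nx, ny) < 50) {
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = TRUE)$p.value)
    method <- "Wilcoxon rank-sum test (exact)"
  } else {
    p <- switch(alternative,
      two.sided = 2 * pnorm(-abs(z)),
      less      = pnorm(z),
      greater   = pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  new_sfp_test(u, df = NA_real_, p = p, method = method,
               extra = list(z = unname(z)))
}

#' Pearson chi-square test of independence
#'
#' Analytic p by default; with `monte_carlo_n` set, an empirical p over
#' margin-preserving simulated tables using the `(r + 1)/(n + 1)` estimator.
#' Adjusted standardized residuals are attached for post hoc use.
#'
#' @param tab A two-dimensional matrix or table of non-negative counts.
#' @param monte_carlo_n Optional number of simulated tables.
#' @param seed Seed for the Monte Carlo path (required when simulating).
#' @return An `sfp_test` with a `stdres` matrix field.
#' @export
chi_square_independence <- function(tab, monte_carlo_n = NULL, seed = NULL) {
  tab <- as.matrix(tab)
  if (length(dim(tab)) != 2) abort("table must be two-dimensional")
  if (any(tab < 0)) abort("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("table has a zero margin; drop empty rows/columns first")
  }
  if (is.null(monte_carlo_n)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    new_sfp_test(ct$statistic, df = ct$parameter, p = ct$p.value,
                 method = "Chi-square test of independence",
                 extra = list(stdres = ct$stdres, observed = ct$observed,
                              expected = ct$expected))
  } else {
    if (is.null(seed)) abort("seed is required for the Monte Carlo p-value")
    ct <- with_seed(seed, suppressWarnings(
      chisq.test(tab, simulate.p.value = TRUE, B = as.integer(monte_carlo_n))))
    new_sfp_test(ct$statistic, df = NA_real_, p = ct$p.value,
                 method = "Chi-square test of independence (Monte Carlo)",
                 n_sim = as.integer(monte_carlo_n),
                 extra = list(stdres = ct$stdres, observed = ct$observed,
                              expected = ct$expected))
  }
}

#' Nonparametric group comparison with post hoc pairwise tests
#'
#' Omnibus Kruskal-Wallis (Wilcoxon rank-sum when exactly two groups), per-group
#' sizes and medians, and all pairwise Wilcoxon rank-sum tests with
#' Benjamini-Hochberg adjustment.
#'
#' @param data A data frame.
#' @param value Name of the numeric column to compare.
#' @param group Name of the grouping column.
#' @param posthoc Run pairwise tests? Default `TRUE`.
#' @return An `sfp_group_comparison` object.
#' @export
compare_groups <- function(data, value, group, posthoc = TRUE) {
  df <- tibble(value = data[[value]], group = as.character(data[[group]]))
  df <- df[is.finite(df$value) & !is.na(df$group), ]
  sizes <- table(df$group)
  empty <- names(sizes)[sizes == 0]
  if (length(empty) > 0) warn(paste("dropping empty groups:",
                                    paste(empty, collapse = ", ")))
  labs <- sort(names(sizes)[sizes > 0])
  if (length(labs) < 2) abort("need at least two non-empty groups")
  split_vals <- lapply(labs, function(l) df$value[df$group == l])
  names(split_vals) <- labs

  omnibus <- if (length(labs) == 2) {
    wilcoxon_rank_sum(split_vals[[1]], split_vals[[2]])
  } else {
    kruskal_wallis(split_vals)
  }
  groups_tbl <- tibble(
    group = labs,
    n = vapply(split_vals, length, integer(1)),
    median = vapply(split_vals, median, numeric(1))
  )
  pairwise <- NULL
  if (posthoc && length(labs) >= 2) {
    combos <- utils::combn(labs, 2)
    pairwise <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
      a <- combos[1, i]; b <- combos[2, i]
      wt <- wilcoxon_rank_sum(split_vals[[a]], split_vals[[b]])
      tibble(group1 = a, group2 = b, statistic = wt$statistic, z = wt$z,
             p_raw = wt$p)
    })
    pairwise$p_adj <- bh_adjust(pairwise$p_raw)
  }
  structure(list(omnibus = omnibus, groups = groups_tbl, pairwise = pairwise),
            class = "sfp_group_comparison")
}

#' @export
print.sfp_group_comparison <- function(x, ...) {
  print(x$omnibus)
  cat("Groups:\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise (BH-adjusted):\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}
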