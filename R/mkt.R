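#' Threshold a nonsynonymous site frequency spectrum
#'
#' Retains segregating sites whose frequency is strictly above the cutoff
#' (derived-allele frequency `i / sample_size` by default; minor-allele
#' frequency in folded mode). Sites exactly at the boundary are excluded.
#'
#' @param sfs_n Numeric vector of site counts per derived-allele count bin,
#'   indexed `1 .. sample_size - 1`.
#' @param sample_size Number of sampled chromosomes.
#' @param cutoff Frequency cutoff. Default 0.05.
#' @param folded Apply the cutoff to minor-allele frequency instead of
#'   derived-allele frequency. Default `FALSE` (unfolded).
#' @return The thresholded segregating-site count.
#' @export
threshold_sfs <- function(sfs_n, sample_size, cutoff = 0.05, folded = FALSE) {
  if (length(sfs_n) != sample_size - 1) {
    abort("sfs_n must have sample_size - 1 bins (derived counts 1..n-1)")
  }
  if (any(sfs_n < 0)) abort("SFS counts must be non-negative")
  i <- seq_len(sample_size - 1)
  freq <- if (folded) pmin(i, sample_size - i) / sample_size else i / sample_size
  sum(sfs_n[freq > cutoff])
}

# Expected fraction of neutral SFS mass (standard 1/i shape) retained by the
# cutoff; used to rescale the thresholded count into a neutral-Pn estimate.
neutral_retention <- function(sample_size, cutoff = 0.05, folded = FALSE) {
  i <- seq_len(sample_size - 1)
  w <- 1 / i
  freq <- if (folded) pmin(i, sample_size - i) / sample_size else i / sample_size
  sum(w[freq > cutoff]) / sum(w)
}

#' Nonsynonymous/synonymous divergence ratio
#'
#' `omega = (Dn/Ln) / (Ds/Ls)` (per-site by default); with
#' `per_site = FALSE`, the raw-count ratio `Dn/Ds`.
#'
#' @param Dn,Ds Nonsynonymous and synonymous substitution counts.
#' @param Ln,Ls Nonsynonymous and synonymous site counts.
#' @param per_site Normalise by site counts. Default `TRUE`.
#' @return omega, or `NA` when `Ds == 0` (unusable).
#' @export
mkt_omega <- function(Dn, Ds, Ln = NULL, Ls = NULL, per_site = TRUE) {
  if (per_site && (is.null(Ln) || is.null(Ls))) {
    abort("per-site omega needs Ln and Ls")
  }
  out <- if (per_site) (Dn / Ln) / (Ds / Ls) else Dn / Ds
  out[Ds == 0] <- NA_real_
  if (per_site) out[Ln == 0 | Ls == 0] <- NA_real_
  out
}

#' Proportion of substitutions fixed by positive selection
#'
#' `alpha = 1 - (Ds * Pn_corr) / (Dn * Ps)`. May be negative under segregating
#' deleterious variation; it is reported unclipped.
#'
#' @param Pn_corr (Corrected) nonsynonymous segregating-site count.
#' @param Ps Synonymous segregating-site count.
#' @param Dn,Ds Substitution counts.
#' @return alpha, or `NA` when `Ps == 0` or `Dn == 0` (unusable).
#' @export
mkt_alpha <- function(Pn_corr, Ps, Dn, Ds) {
  out <- 1 - (Ds * Pn_corr) / (Dn * Ps)
  out[Ps == 0 | Dn == 0] <- NA_real_
  out
}

#' Decompose omega into adaptive and nonadaptive rates
#'
#' `omega_a = alpha * omega`, `omega_na = (1 - alpha) * omega`; the identity
#' `omega_a + omega_na = omega` holds exactly. Negative alpha yields a negative
#' adaptive rate, which is reported as such.
#'
#' @param omega,alpha Vectors of equal length.
#' @return Tibble with `omega_a`, `omega_na`.
#' @export
decompose_omega <- function(omega, alpha) {
  tibble(omega_a = alpha * omega, omega_na = (1 - alpha) * omega)
}

#' Per-gene McDonald-Kreitman statistics
#'
#' Computes omega, alpha with the SFS frequency-threshold correction on the
#' nonsynonymous class, and the adaptive/nonadaptive decomposition, per gene.
#'
#' The threshold removes the low-frequency bins where segregating deleterious
#' variants concentrate, but it also removes genuinely neutral low-frequency
#' variants; with `neutral_rescale = TRUE` (default) the retained count is
#' rescaled by the expected neutral mass above the cutoff under the standard
#' neutral `1/i` spectrum, giving an estimate of the number of neutral
#' segregating nonsynonymous sites rather than a truncated count.
#'
#' @param counts Data frame with columns `gene_id`, `Pn`, `Ps`, `Dn`, `Ds`,
#'   `Ln`, `Ls`, `sample_size` (and optionally `population`).
#' @param sfs Optional data frame with columns `gene_id`, `derived_count`,
#'   `n_sites` giving the nonsynonymous SFS; required when `cutoff > 0`. Per
#'   gene, the SFS must sum to that gene's `Pn`.
#' @param cutoff Frequency cutoff. Default 0.05. Zero disables the correction.
#' @param neutral_rescale Rescale the thresholded count to a neutral-Pn
#'   estimate. Default `TRUE`.
#' @param folded Passed to [threshold_sfs()].
#' @param per_site Per-site omega (default) or raw-count omega.
#' @return Tibble: `gene_id`, `Pn_corr`, `omega`, `alpha`, `omega_a`,
#'   `omega_na`, `usable`, `reason`.
#' @export
mkt <- function(counts, sfs = NULL, cutoff = 0.05, neutral_rescale = TRUE,
                folded = FALSE, per_site = TRUE) {
  need <- c("gene_id", "Pn", "Ps", "Dn", "Ds", "Ln", "Ls", "sample_size")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) abort(paste("counts is missing:", paste(miss, collapse = ", ")))
  if (cutoff > 0 && is.null(sfs)) {
    abort("an SFS table is required when cutoff > 0")
  }
  counts <- as_tibble(counts)
  pn_corr <- counts$Pn
  if (cutoff > 0) {
    sfs_by_gene <- split(sfs, sfs$gene_id)
    pn_corr <- vapply(seq_len(nrow(counts)), function(i) {
      gid <- counts$gene_id[i]
      n <- counts$sample_size[i]
      s <- sfs_by_gene[[gid]]
      if (is.null(s)) {
        if (counts$Pn[i] > 0) abort(paste0("gene ", gid, " has Pn > 0 but no SFS"))
        return(0)
      }
      vec <- numeric(n - 1)
      if (any(s$derived_count < 1 | s$derived_count > n - 1)) {
        abort(paste0("gene ", gid, ": derived counts outside 1..n-1"))
      }
      vec[s$derived_count] <- s$n_sites
      if (sum(vec) != counts$Pn[i]) {
        abort(paste0("gene ", gid, ": SFS sums to ", sum(vec),
                     " but Pn = ", counts$Pn[i]))
      }
      raw <- threshold_sfs(vec, n, cutoff = cutoff, folded = folded)
      if (neutral_rescale) raw / neutral_retention(n, cutoff, folded) else raw
    }, numeric(1))
  }
  om <- mkt_omega(counts$Dn, counts$Ds, counts$Ln, counts$Ls,
                  per_site = per_site)
  al <- mkt_alpha(pn_corr, counts$Ps, counts$Dn, counts$Ds)
  dec <- decompose_omega(om, al)
  reason <- case_when(
    counts$Ds == 0 ~ "zero synonymous divergence",
    counts$Ps == 0 ~ "zero synonymous polymorphism",
    counts$Dn == 0 ~ "zero nonsynonymous divergence",
    TRUE ~ NA_character_
  )
  tibble(gene_id = counts$gene_id,
         population = counts[["population"]] %||% NA_character_,
         Pn_corr = pn_corr,
         omega = om, alpha = al,
         omega_a = dec$omega_a, omega_na = dec$omega_na,
         usable = is.na(reason), reason = reason)
}

#' Pooled McDonald-Kreitman estimate over a gene set
#'
#' Sums counts across genes (the corrected nonsynonymous polymorphism summed
#' per gene, honouring per-gene sample sizes) and computes pooled omega, alpha
#' and the adaptive/nonadaptive decomposition. More stable than per-gene
#' estimates when individual counts are small.
#'
#' @inheritParams mkt
#' @return One-row tibble: `n_genes`, `Pn_corr`, `Ps`, `Dn`, `Ds`, `omega`,
#'   `alpha`, `omega_a`, `omega_na`.
#' @export
mkt_pooled <- function(counts, sfs = NULL, cutoff = 0.05,
                       neutral_rescale = TRUE, folded = FALSE,
                       per_site = TRUE) {
  per_gene <- mkt(counts, sfs = sfs, cutoff = cutoff,
                  neutral_rescale = neutral_rescale, folded = folded,
                  per_site = per_site)
  pn <- sum(per_gene$Pn_corr)
  ps <- sum(counts$Ps); dn <- sum(counts$Dn); ds <- sum(counts$Ds)
  om <- mkt_omega(dn, ds, sum(counts$Ln), sum(counts$Ls), per_site = per_site)
  al <- mkt_alpha(pn, ps, dn, ds)
  dec <- decompose_omega(om, al)
  tibble(n_genes = nrow(counts), Pn_corr = pn, Ps = ps, Dn = dn, Ds = ds,
         omega = om, alpha = al, omega_a = dec$omega_a,
         omega_na = dec$omega_na)
}

#' Compare evolutionary rates across gene groups
#'
#' Nonparametric comparison of a rate metric across groups (age classes,
#' core vs non-core subnetwork membership, ...). Unusable genes are excluded
#' and their number reported as a message.
#'
#' @param results Per-gene tibble from [mkt()].
#' @param groups Data frame with `gene_id` and `group` columns, or a named
#'   vector.
#' @param metric `"omega"`, `"omega_a"` or `"omega_na"`.
#' @return An `sfp_group_comparison`.
#' @export
compare_rates <- function(results, groups,
                          metric = c("omega", "omega_a", "omega_na")) {
  metric <- match.arg(metric)
  if (!is.data.frame(groups)) {
    groups <- tibble(gene_id = names(groups), group = unname(groups))
  }
  df <- dplyr::inner_join(results, groups, by = "gene_id")
  n_excl <- sum(!df$usable | !is.finite(df[[metric]]))
  if (n_excl > 0) message(n_excl, " gene(s) excluded as unusable")
  df <- df[df$usable & is.finite(df[[metric]]), ]
  compare_groups(df, metric, "group")
}
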