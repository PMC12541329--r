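#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.sfp_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p, method = x$method,
         n_sim = x$n_sim)
}

#' @export
glance.sfp_test <- function(x, ...) tidy.sfp_test(x)

#' @export
tidy.sfp_gof <- function(x, ...) {
  if (is.null(x$residuals)) {
    abort("no post hoc residuals in this object")
  }
  x$residuals
}

#' @export
glance.sfp_gof <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p, n = x$total,
         method = x$method)
}

#' @export
tidy.sfp_validation <- function(x, ...) {
  tibble(gene_id = x$discrepant_ids)
}

#' @export
glance.sfp_validation <- function(x, ...) {
  tibble(n_checked = x$n_checked, n_discrepant = x$n_discrepant,
         rate_percent = x$rate_percent)
}

#' @export
tidy.sfp_group_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) return(x$groups)
  x$pairwise
}

#' @export
glance.sfp_group_comparison <- function(x, ...) {
  tibble(statistic = x$omnibus$statistic, df = x$omnibus$df,
         p.value = x$omnibus$p, method = x$omnibus$method,
         n_groups = nrow(x$groups))
}

#' @export
tidy.sfp_assoc <- function(x, ...) x$posthoc

#' @export
glance.sfp_assoc <- function(x, ...) {
  tibble(statistic = x$test$statistic, p.value = x$test$p,
         method = x$test$method, n_sim = x$test$n_sim)
}
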