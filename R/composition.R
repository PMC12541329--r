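#' Count genes per age class
#'
#' `UNASSIGNED` genes are excluded, mirroring the exclusion of unclassifiable
#' genes from age-stratified statistics.
#'
#' @param catalog Catalog tibble with an `age_class` column.
#' @return Named integer vector over the ordered classes A..E.
#' @export
class_counts <- function(catalog) {
  cls <- catalog$age_class[catalog$age_class != "UNASSIGNED"]
  .check_classes(cls)
  counts <- table(factor(cls, levels = AGE_CLASSES))
  setNames(as.integer(counts), AGE_CLASSES)
}

#' Expected per-class counts under background proportions
#'
#' @param background_props Named proportions over classes A..E summing to 1.
#' @param total Total number of genes.
#' @return Tibble with `age_class`, `prop`, `expected`; expectations sum to
#'   `total` exactly.
#' @export
expected_counts <- function(background_props, total) {
  p <- background_props[AGE_CLASSES]
  if (any(is.na(p))) abort("background_props must name all classes A..E")
  .check_props(p)
  tibble(age_class = AGE_CLASSES, prop = unname(p),
         expected = unname(p) * total)
}

#' Chi-square goodness-of-fit test with post hoc residuals
#'
#' `chi2 = sum((O - E)^2 / E)` against expectations `E = p * total`, with a
#' chi-square reference on k - 1 degrees of freedom, plus per-class adjusted
#' standardized residuals `z = (O - E) / sqrt(E (1 - p_c))`, two-sided normal
#' p-values and Benjamini-Hochberg adjustment across the k classes.
#'
#' @param observed Named non-negative counts over k >= 2 classes.
#' @param props Proportions (same order/names as `observed`) summing to 1.
#' @param posthoc Compute per-class residual tests? Default `TRUE`.
#' @return An `sfp_gof` object: `chi2`, `df`, `p` and a `residuals` tibble.
#' @export
gof_test <- function(observed, props, posthoc = TRUE) {
  o <- as.numeric(observed)
  if (length(o) < 2) abort("need at least two classes")
  if (any(o < 0)) abort("counts must be non-negative")
  p <- unname(as.numeric(props))
  .check_props(p)
  classes <- names(observed) %||% as.character(seq_along(o))
  total <- sum(o)
  e <- p * total
  if (any(e == 0)) abort("an expected count is zero; pool classes first")
  chi2 <- sum((o - e)^2 / e)
  df <- length(o) - 1
  pval <- pchisq(chi2, df, lower.tail = FALSE)
  res <- NULL
  if (posthoc) {
    z <- (o - e) / sqrt(e * (1 - p))
    p_raw <- 2 * pnorm(-abs(z))
    res <- tibble(
      age_class = classes,
      observed = o,
      expected = e,
      z = z,
      p_raw = p_raw,
      p_adj = bh_adjust(p_raw),
      direction = if_else(z >= 0, "over", "under")
    )
  }
  structure(list(chi2 = chi2, df = df, p = pval,
                 total = total, residuals = res,
                 method = "Chi-square goodness-of-fit"),
            class = "sfp_gof")
}

#' Age-class composition test against background proportions
#'
#' [gof_test()] of the observed age-class counts of a gene set against
#' expectations from genome-wide background proportions.
#'
#' @param observed Named counts over A..E, or a catalog tibble (counted via
#'   [class_counts()]).
#' @param background_props Named background proportions over A..E.
#' @param posthoc Compute per-class residual tests? Default `TRUE`.
#' @return An `sfp_gof` object.
#' @export
age_composition_test <- function(observed, background_props, posthoc = TRUE) {
  if (is.data.frame(observed)) observed <- class_counts(observed)
  o <- observed[AGE_CLASSES]
  if (any(is.na(o))) abort("observed counts must name all classes A..E")
  names(o) <- AGE_CLASSES
  p <- background_props[AGE_CLASSES]
  gof_test(o, p, posthoc = posthoc)
}

#' @export
print.sfp_gof <- function(x, ...) {
  cat(sprintf("%s: chi2 = %.2f, df = %d, p = %.3g (n = %d)\n",
              x$method, x$chi2, x$df, x$p, x$total))
  if (!is.null(x$residuals)) {
    print(as.data.frame(x$residuals), row.names = FALSE, digits = 4)
  }
  invisible(x)
}
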