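#' Read a tab-separated table in the pipeline dialect
#'
#' Tab-separated, UTF-8, mandatory header row, `#` comment lines skipped.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  as_tibble(out)
}

#' Write a table in the pipeline TSV dialect
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_tsv_strict <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

# Deterministic 31-bit polynomial string hash for child seed streams.
# h*31 + b stays below 2^53, so double arithmetic is exact.
.hash31 <- function(...) {
  s <- paste(c(...), collapse = "\r")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a child seed for a named random stream
#'
#' Every stochastic operation in the package draws from a child stream keyed by
#' the operation name (and, where relevant, a unit identifier), so results do
#' not depend on the order in which operations are executed.
#'
#' @param seed Integer master seed.
#' @param ... Character/numeric keys naming the stream.
#' @return An integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  .hash31(format(as.integer(seed)), ...)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.check_classes <- function(x, arg = "age_class") {
  bad <- setdiff(unique(x[!is.na(x) & x != "UNASSIGNED"]), AGE_CLASSES)
  if (length(bad) > 0) {
    abort(paste0(arg, " contains values outside A..E: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

.check_props <- function(p, tol = 1e-9) {
  if (any(p < 0)) abort("proportions must be non-negative")
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("proportions must sum to 1 (got %.12f)", sum(p)))
  }
  invisible(TRUE)
}
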