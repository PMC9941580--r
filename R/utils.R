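# Shared helpers: rounding conventions, RNG scoping, small validators.

#' Percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` and rounds *half-up* at a fixed
#' number of decimal places, the convention used throughout the summary
#' report (base R `round()` rounds half-to-even, which does not reproduce
#' printed ratios such as 1,636/2,842 = 57.57).
#'
#' @param numerator,denominator Non-negative scalars, `numerator <= denominator`.
#' @param digits Decimal places to keep (default 1).
#' @return Numeric percentage in `[0, 100]`, or `NA_real_` (with a warning)
#'   when the denominator is zero.
#' @examples
#' percent_half_up(1636, 2842, digits = 2)  # 57.57
#' percent_half_up(339, 2842)               # 11.9
#' @export
percent_half_up <- function(numerator, denominator, digits = 1) {
  stopifnot(is.numeric(numerator), is.numeric(denominator), numerator >= 0)
  if (denominator == 0) {
    warning("denominator is zero; percentage undefined")
    return(NA_real_)
  }
  x <- 100 * numerator / denominator
  f <- 10^digits
  # half-up: nudge by a hair below half an ulp to defeat binary representation
  floor(x * f + 0.5 + 1e-9) / f
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps generator calls reproducible and
# side-effect free.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stable sub-seed derivation: distinct streams per stage, below 2^31
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

stop_if_not_scalar_fraction <- function(x, name, open_left = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x <= 1 && (if (open_left) x > 0 else x >= 0)
  if (!ok) stop(sprintf("'%s' must be a scalar in %s", name,
                        if (open_left) "(0, 1]" else "[0, 1]"), call. = FALSE)
  invisible(x)
}

# write a data.frame as deterministic TSV (no quotes, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "")
}

# numeric matrix (features x samples) <-> TSV with a leading id column
write_matrix_tsv <- function(mat, path, id_col = "feature") {
  df <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
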