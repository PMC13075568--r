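#' @keywords internal
"_PACKAGE"

# All randomness in the package flows from one master seed via named
# sub-seeds so that pipeline stages can be re-run independently yet
# bit-reproducibly.

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps a master seed and a stage tag to a 31-bit integer
#' seed. Used so that every stage of the pipeline draws from an independent
#' but reproducible stream.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the consumer (e.g. `"templates"`).
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (cc in utf8ToInt(tag)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

capnet_log <- function(fmt, ...) {
  if (isTRUE(getOption("capnet.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(fmt, ...))
}

stop_capnet <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_capnet("`%s` must be a numeric matrix", name)
  if (!all(is.finite(x)))
    stop_capnet("`%s` contains non-finite values", name)
  invisible(x)
}

# Pearson correlation of the rows of `x` (n x p) against rows of `y` (m x p),
# returned as an n x m matrix. Rows must have nonzero variance.
row_cor <- function(x, y) {
  xs <- standardize_rows(x)
  ys <- standardize_rows(y)
  tcrossprod(xs, ys) / (ncol(x) - 1L)
}

# Center each row and scale to unit sample sd; rows with zero variance error.
standardize_rows <- function(x, eps = 0) {
  x <- x - rowMeans(x)
  s <- sqrt(rowSums(x^2) / (ncol(x) - 1L))
  if (any(s <= eps))
    stop_capnet("rows with zero variance: %s",
                paste(utils::head(which(s <= eps), 5L), collapse = ", "))
  x / s
}
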