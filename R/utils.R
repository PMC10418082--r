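#' @useDynLib trnacharge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim quantile median rnorm runif rbinom rgeom setNames sd
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    b <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(COMPLEMENT[b], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
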