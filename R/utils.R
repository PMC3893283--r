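#' @useDynLib ednacensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that one
# integer seed per scenario/fit reproduces every draw.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Draw from a Dirichlet distribution
#'
#' Rows are independent draws from Dirichlet(`alpha`), generated by
#' normalizing independent Gamma variates. With `alpha = rep(1, k)` the draw
#' is uniform on the k-part simplex.
#'
#' @param n number of draws.
#' @param alpha concentration vector; length gives the number of parts.
#' @return an `n` x `length(alpha)` matrix whose rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Reverse-complement of plain character sequences (A/C/G/T/N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 helpers. Qualities live in [0, 45].
phred_decode <- function(qual) lapply(qual, function(q) utf8ToInt(q) - 33L)
phred_encode <- function(qint) vapply(qint, function(q) intToUtf8(q + 33L), "")

# Reverse a quality string in register with a reverse-complemented sequence.
rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ednacensus <- function(...) stop(..., call. = FALSE)
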