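# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper; `N` stays `N`.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards; all simulator substreams go through this
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, abs(seed) < 2^31)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Rand index between two partitions
#'
#' Fraction of element pairs on which two partitions agree (same cluster in
#' both, or different cluster in both). Used to compare a recovered gene
#' partition with a planted one.
#'
#' @param a,b vectors of cluster labels over the same elements (matched by
#'   position, or by names when both are named).
#' @return a number in \eqn{[0, 1]}; 1 means identical partitions.
#' @examples
#' rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop_input("partitions cover different elements")
  n <- length(a)
  if (n < 2) return(1)
  # pair agreement via contingency counts: R = 1 - (disagreements)/choose(n,2)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}
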