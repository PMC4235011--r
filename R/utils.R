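# Shared internal helpers: scoped RNG, sequence alphabet handling, small
# coordinate utilities.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so library calls never
# perturb user-level randomness.
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Uppercase and coerce to the RNA alphabet (T -> U). Errors on characters
# outside ACGTU.
as_rna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTU]", x)
  if (any(bad)) {
    stop("invalid-sequence: non-nucleotide characters in sequence(s) ",
         paste(which(bad), collapse = ", "))
  }
  chartr("T", "U", x)
}

# Random RNA sequence of length n from the current RNG stream.
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Length of a 1-based inclusive coordinate span
#'
#' Number of nucleotides covered by the inclusive interval
#' \code{[from, to]} in 1-based coordinates, the convention used for all
#' site and fragment coordinates in this package. For example, the span
#' 8589--9113 on a reference mRNA covers 525 nt.
#'
#' @param from,to 1-based inclusive start and end positions, `to >= from`.
#' @return Integer span length `to - from + 1`.
#' @examples
#' span_length(8589, 9113)
#' @export
span_length <- function(from, to) {
  if (!is.numeric(from) || !is.numeric(to) || from < 1 || to < from) {
    stop("invalid-argument: need 1 <= from <= to")
  }
  as.integer(to - from + 1)
}
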