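# Small internal helpers shared across modules.

#' @import methods
#' @importFrom stats median approx cor quantile runif rbinom rlnorm var lm coef
#' @importFrom utils adist head tail write.csv
NULL

.msg <- function(...) message("[dazzle] ", ...)

#' Reverse complement of a character DNA string
#' @param x character scalar (ACGTN + IUPAC codes allowed)
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## run a block with a private RNG stream; global .Random.seed restored on exit
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

## derive a child seed from a parent seed, stays below 2^31
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647L)
}

## uppercase and validate an ACGTN string
.norm_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (grepl("[^ACGTN]", x))
    stop(what, " contains non-ACGTN characters", call. = FALSE)
  x
}

## all k-mers of a string, 1-based start positions
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

## edit-distance identity between two strings
.identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  1 - as.numeric(adist(a, b)) / max(nchar(a), nchar(b))
}

## Wilson score interval for a binomial proportion
.wilson <- function(x, n, z = 1.96) {
  if (n == 0) return(c(NA_real_, NA_real_))
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw  <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

## stable content hash (md5 of serialized object, version-pinned)
.hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

## render an RU structure vector as in haplotyping reports, e.g. "15 + 2 + 5"
.structure_label <- function(ru) paste(ru, collapse = " + ")
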