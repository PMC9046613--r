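#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` strings, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_bases <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Truncated Poisson deviates
#'
#' Draws from a Poisson distribution conditioned on being at least `min`
#' (default 1, the zero-truncated Poisson), by inversion: a uniform is
#' drawn on `[P(X < min), 1)` and passed through the Poisson quantile
#' function, which is exact and O(1) even when the acceptance region is
#' tiny. Used for junction and host-deletion lengths and for fragment
#' piece counts, where a zero draw would be meaningless (a zero-length
#' gap is indistinguishable from a clean junction). Note the truncation
#' shifts the realised mean: at `lambda = 1` the zero-truncated mean is
#' `1/(1 - exp(-1))`, about 1.58.
#'
#' @param n number of deviates.
#' @param lambda Poisson mean (of the untruncated distribution); must be > 0.
#' @param min smallest permitted value.
#' @return integer vector of length `n`, all values `>= min`.
#' @export
rztpois <- function(n, lambda, min = 1L) {
  stopifnot(is.numeric(lambda), lambda > 0, min >= 1)
  lo <- stats::ppois(min - 1L, lambda)
  u <- stats::runif(n, lo, 1)
  as.integer(pmax(stats::qpois(u, lambda), min))
}

## Exact (a * b) mod 2^31 using 16-bit limbs so every intermediate stays
## below 2^53 and double arithmetic is exact on all platforms.
mulmod31 <- function(a, b) {
  m <- 2147483648
  a <- a %% m
  bh <- b %/% 65536
  bl <- b %% 65536
  (((a * bh) %% m) * 65536 + a * bl) %% m
}

#' Derive a reproducible per-job seed
#'
#' Deterministic, platform-independent integer mixer combining the global
#' seed with condition and replicate indices. Uses only exact 31-bit
#' double arithmetic and bitwise xor, so the same inputs give the same
#' seed on every machine (never the language's object hash).
#'
#' @param global_seed integer global seed.
#' @param condition 0-based condition index.
#' @param replicate 0-based replicate index.
#' @return a single integer in `[0, 2^31)`.
#' @export
mix_seed <- function(global_seed, condition, replicate) {
  m <- 2147483648
  x <- global_seed %% m
  for (v in c(condition, replicate)) {
    x <- bitwXor(as.integer(x), as.integer(v %% m))
    x <- x %% m
    x <- mulmod31(x, 2654435761)
    x <- (x + 104729) %% m
    x <- bitwXor(as.integer(x %/% 65536), as.integer(x))
    x <- x %% m
    x <- mulmod31(x, 1103515245)
  }
  as.integer(x %% m)
}

## sample one integer from 0:(n-1), uniform; safe for n == 1
runif_int0 <- function(n) {
  sample.int(n, 1L) - 1L
}

#' Read a FASTA file (or pass through in-memory sequences)
#'
#' Accepts a file path (plain or gzip FASTA), a [Biostrings::DNAStringSet],
#' or a named character vector; returns an upper-cased named character
#' vector of sequences. Record names are the first whitespace-delimited
#' word of each header.
#'
#' @param x path, `DNAStringSet`, or named character vector.
#' @return named character vector of uppercase sequences.
#' @export
load_fasta <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    seqs <- toupper(as.character(x))
    names(seqs) <- sub("\\s.*$", "", names(x))
    x <- seqs
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("expected a FASTA path, DNAStringSet, or named character vector")
  }
  if (anyDuplicated(names(x))) stop("duplicate sequence names in FASTA input")
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence '", names(x)[bad][1], "' contains characters outside {A,C,G,T,N}")
  }
  if (any(nchar(x) < 1L)) stop("empty sequence in FASTA input")
  x
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, filepath = path, width = as.integer(width))
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}
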