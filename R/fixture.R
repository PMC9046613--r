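#' Generate synthetic host and virus references
#'
#' Desk-scale stand-in for a real host chromosome and viral genome:
#' i.i.d. bases at a requested GC fraction, with optional runs of `N`
#' injected into the host to mimic assembly gaps. Deterministic under
#' `seed`.
#'
#' @param n_chromosomes number of host chromosomes (`chr1`, `chr2`, ...).
#' @param chromosome_length host chromosome length in bp.
#' @param virus_length virus genome length in bp.
#' @param gc_fraction probability that a base is G or C.
#' @param n_run_count number of `N` runs injected per host chromosome.
#' @param n_run_length length of each injected `N` run in bp.
#' @param seed integer seed (`NULL` = current RNG state).
#' @return list with `host` and `virus`, each a named character vector
#'   of sequences.
#' @examples
#' fix <- sim_fixture(chromosome_length = 1000, virus_length = 200, seed = 1)
#' nchar(fix$host)
#' @export
sim_fixture <- function(n_chromosomes = 1L, chromosome_length = 1e6,
                        virus_length = 5000L, gc_fraction = 0.5,
                        n_run_count = 0L, n_run_length = 0L, seed = NULL) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 1, virus_length >= 1,
            gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
            G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  rand_seq <- function(n) {
    paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
  }
  host <- vapply(seq_len(n_chromosomes), function(i) {
    s <- rand_seq(chromosome_length)
    if (n_run_count > 0L && n_run_length > 0L) {
      for (k in seq_len(n_run_count)) {
        at <- runif_int0(chromosome_length - n_run_length + 1L)
        substr(s, at + 1L, at + n_run_length) <-
          strrep("N", n_run_length)
      }
    }
    s
  }, "")
  names(host) <- paste0("chr", seq_len(n_chromosomes))
  virus <- stats::setNames(rand_seq(virus_length), "virus1")
  list(host = host, virus = virus)
}

#' Write a fixture to FASTA files
#'
#' @param fixture result of [sim_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector with the `host` and `virus` paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(host = file.path(dir, "host.fa"),
             virus = file.path(dir, "virus.fa"))
  write_fasta(fixture$host, paths[["host"]])
  write_fasta(fixture$virus, paths[["virus"]])
  paths
}
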