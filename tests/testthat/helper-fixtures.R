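## Small in-code fixtures shared across test files.

tiny_refs <- function(host_len = 20000, virus_len = 1000, seed = 101, ...) {
  sim_fixture(chromosome_length = host_len, virus_length = virus_len,
              seed = seed, ...)
}

## parameters scaled to the tiny fixtures; overrides as needed
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_ints = 5L, min_sep = 1000L, coverage = 4, epi_num = 0L),
    list(...))
  do.call(default_params, args)
}

## independent recomputation of the length-accounting identity from the
## ground-truth table: modified host length should equal
## host + fragments + gaps - overlaps - host deletions
expected_modified_length <- function(host, int_info) {
  frag_len <- vapply(int_info$fragmentStructure, function(s) {
    p <- vintsim:::parse_fragment_structure(s)
    sum(p$stop - p$start)
  }, numeric(1), USE.NAMES = FALSE)
  gaps <- sum(int_info$juncLenLeft[int_info$juncTypesLeft == "gap"]) +
    sum(int_info$juncLenRight[int_info$juncTypesRight == "gap"])
  overlaps <- sum(int_info$juncLenLeft[int_info$juncTypesLeft == "overlap"]) +
    sum(int_info$juncLenRight[int_info$juncTypesRight == "overlap"])
  sum(nchar(host)) + sum(frag_len) + gaps - overlaps - sum(int_info$hostDeleted)
}

## binomial 4-sigma band check
expect_within_4sd <- function(observed_frac, p, n) {
  sd4 <- 4 * sqrt(p * (1 - p) / n)
  expect_lt(abs(observed_frac - p), max(sd4, .Machine$double.eps))
}
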