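## Ambiguity (N) runs longer than `min_len_run`, per sequence:
## data frame of 0-based half-open (start, stop).
n_runs <- function(seq, min_len_run) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), stop = integer(0)))
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  keep <- len > min_len_run
  data.frame(start = start[keep], stop = start[keep] + len[keep])
}

#' Choose integration sites on the host genome
#'
#' Draws `n_ints` sites by rejection sampling: the chromosome is chosen
#' with probability proportional to its length (so positions are uniform
#' over the genome) and the position uniformly on the chromosome. A
#' candidate is rejected if it lies within `min_sep` of an already
#' accepted site on the same chromosome (distances in original host
#' coordinates) or inside a run of `N` longer than `min_sep / 2` —
#' junctions inside ambiguity runs are unresolvable by any detector.
#' Each site is given up to 1000 attempts before the placement is
#' declared infeasible.
#'
#' @param host named character vector of host chromosome sequences.
#' @param n_ints number of sites.
#' @param min_sep minimum pairwise distance (bp) between sites on a
#'   chromosome.
#' @return data frame with columns `chr`, `pos` (0-based), sorted by
#'   `(chr, pos)`.
#' @export
choose_sites <- function(host, n_ints, min_sep) {
  n_ints <- as.integer(n_ints)
  if (n_ints == 0L) {
    return(data.frame(chr = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  }
  lens <- nchar(host)
  if (sum(lens) < n_ints * min_sep) {
    stop("infeasible: ", n_ints, " sites at min_sep ", min_sep,
         " exceed the genome size (", sum(lens), " bp)")
  }
  runs <- lapply(host, n_runs, min_len_run = min_sep / 2)
  ## greedy placement can dead-end (earlier sites may leave no room), so the
  ## whole placement is restarted for up to 1000 rounds before giving up
  accepted <- NULL
  for (round in 1:1000) {
    cand <- lapply(host, function(x) integer(0))
    ok <- TRUE
    for (i in seq_len(n_ints)) {
      placed <- FALSE
      for (attempt in 1:200) {
        ci <- sample.int(length(host), 1L, prob = lens)
        pos <- runif_int0(lens[ci])
        r <- runs[[ci]]
        if (nrow(r) && any(r$start <= pos & pos < r$stop)) next
        if (length(cand[[ci]]) && min(abs(cand[[ci]] - pos)) < min_sep) next
        cand[[ci]] <- c(cand[[ci]], pos)
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) { accepted <- cand; break }
  }
  if (is.null(accepted)) {
    stop("could not place ", n_ints, " integration sites after 1000 ",
         "rejection attempts/rounds; reduce n_ints or min_sep")
  }
  out <- data.frame(
    chr = rep(names(host), lengths(accepted)),
    pos = unlist(lapply(accepted, sort), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
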