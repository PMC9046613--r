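#' Draw a viral fragment for integration
#'
#' With probability `p_whole` the whole viral genome is taken; otherwise a
#' sub-genomic fragment whose length is uniform on
#' `[min_len, min(max_len, virus length)]` and whose start is uniform among
#' valid starts. The fragment's orientation is drawn uniformly from
#' `{+,-}` (integrations occur in both orientations).
#'
#' Uses the current RNG stream; seed at the call site for reproducibility.
#'
#' @param virus_name name of the virus record.
#' @param virus_len length of the virus sequence in bp.
#' @param params simulation parameters (see [default_params()]).
#' @return a `viral_fragment`: list with `virus`, `pieces` (data frame of
#'   0-based half-open `start`, `stop`, `strand`, in realised order),
#'   `is_whole`, `is_rearranged`, `has_deletion`, `source_start`,
#'   `source_stop`.
#' @export
draw_fragment <- function(virus_name, virus_len, params) {
  if (params$min_len > virus_len) {
    stop("min_len (", params$min_len, ") exceeds virus length (", virus_len, ")")
  }
  whole <- stats::runif(1) < params$p_whole
  if (whole) {
    start <- 0L
    stop_ <- as.integer(virus_len)
  } else {
    maxl <- min(params$max_len, virus_len)
    len <- params$min_len + runif_int0(maxl - params$min_len + 1L)
    start <- runif_int0(virus_len - len + 1L)
    stop_ <- start + len
  }
  strand <- if (stats::runif(1) < 0.5) "+" else "-"
  structure(list(
    virus = virus_name,
    pieces = data.frame(start = as.integer(start), stop = as.integer(stop_),
                        strand = strand, stringsAsFactors = FALSE),
    is_whole = whole,
    is_rearranged = FALSE,
    has_deletion = FALSE,
    source_start = as.integer(start),
    source_stop = as.integer(stop_)
  ), class = "viral_fragment")
}

#' Apply structural variation to a viral fragment
#'
#' Rearrangement (probability `p_rearrange`) and deletion (probability
#' `p_delete`) are decided independently; both may occur. If either does,
#' the fragment is split at uniformly chosen internal breakpoints into `k`
#' pieces, with `k` drawn from Poisson(`lambda_split`) redrawn until it
#' reaches the required minimum — 2 if only rearranged, 3 if a deletion is
#' involved, so that both outer ends of the fragment survive and junction
#' semantics stay well defined. Rearrangement swaps two distinct uniformly
#' chosen pieces; deletion then removes one uniformly chosen interior
#' piece. Fragments too short to split (fewer bp than pieces required)
#' skip structural variation with cleared flags.
#'
#' @param frag a `viral_fragment` with a single piece.
#' @param params simulation parameters.
#' @return the (possibly) restructured `viral_fragment`.
#' @export
apply_structural_variation <- function(frag, params) {
  stopifnot(inherits(frag, "viral_fragment"), nrow(frag$pieces) == 1L)
  do_r <- stats::runif(1) < params$p_rearrange
  do_d <- stats::runif(1) < params$p_delete
  if (!do_r && !do_d) return(frag)

  src_start <- frag$source_start
  src_stop <- frag$source_stop
  flen <- src_stop - src_start
  kmin <- if (do_d) 3L else 2L
  if (flen < kmin) {
    return(frag)  # cannot split into kmin non-empty pieces; SV skipped
  }
  k <- NA_integer_
  for (tries in 1:1000) {
    kk <- rztpois(1L, params$lambda_split, min = kmin)
    if (kk <= flen) { k <- kk; break }
  }
  if (is.na(k)) k <- as.integer(flen)

  ## k-1 distinct internal breakpoints, ascending, in source coordinates
  breaks <- src_start + sort(sample.int(flen - 1L, k - 1L))
  bounds <- c(src_start, breaks, src_stop)
  strand <- frag$pieces$strand[1L]
  pieces <- data.frame(start = bounds[-(k + 1L)], stop = bounds[-1L],
                       strand = strand, stringsAsFactors = FALSE)
  ## realised order: a minus-strand fragment reads the source right-to-left
  if (strand == "-") pieces <- pieces[rev(seq_len(k)), , drop = FALSE]

  if (do_r) {
    ij <- sample.int(k, 2L)
    pieces[ij, ] <- pieces[rev(ij), ]
  }
  if (do_d) {
    drop <- 1L + sample.int(k - 2L, 1L)  # interior position only
    pieces <- pieces[-drop, , drop = FALSE]
  }
  rownames(pieces) <- NULL
  frag$pieces <- pieces
  frag$is_rearranged <- do_r
  frag$has_deletion <- do_d
  frag
}

#' Total length of a fragment's pieces
#' @param frag a `viral_fragment`.
#' @return integer bp.
#' @export
fragment_length <- function(frag) {
  sum(frag$pieces$stop - frag$pieces$start)
}

#' Realise a fragment's nucleotide sequence
#'
#' Concatenates the pieces in realised order, reverse-complementing
#' minus-strand pieces, and returns the exact bases that will appear in
#' the modified reference.
#'
#' @param frag a `viral_fragment`.
#' @param virus_seq the virus sequence (character scalar).
#' @return nucleotide string.
#' @export
realize_fragment <- function(frag, virus_seq) {
  parts <- substring(virus_seq, frag$pieces$start + 1L, frag$pieces$stop)
  minus <- frag$pieces$strand == "-"
  if (any(minus)) parts[minus] <- revcomp(parts[minus])
  paste(parts, collapse = "")
}

## "start-stop+" per piece, semicolon-joined, realised order
fragment_structure <- function(frag) {
  paste(sprintf("%d-%d%s", frag$pieces$start, frag$pieces$stop,
                frag$pieces$strand), collapse = ";")
}

parse_fragment_structure <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)-(\\d+)([+-])$", parts))
  data.frame(
    start = as.integer(vapply(m, `[`, "", 2L)),
    stop = as.integer(vapply(m, `[`, "", 3L)),
    strand = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

#' Generate episomal (non-integrated) viral sequences
#'
#' Draws `epi_num` episomes, each by [draw_fragment()] followed by
#' [apply_structural_variation()] with the same `p_whole`, `p_rearrange`
#' and `p_delete` as integrations, so episomes may be sub-genomic,
#' rearranged or deleted. Ids are `"epi0"`, `"epi1"`, ...
#'
#' @param viruses named character vector of virus sequences.
#' @param params simulation parameters.
#' @return list of lists with `epi_id` and `fragment`.
#' @export
make_episomes <- function(viruses, params) {
  n <- as.integer(params$epi_num)
  if (n < 0L) stop("epi_num must be >= 0")
  lapply(seq_len(n), function(i) {
    vi <- sample.int(length(viruses), 1L)
    frag <- draw_fragment(names(viruses)[vi], nchar(viruses[[vi]]), params)
    frag <- apply_structural_variation(frag, params)
    list(epi_id = sprintf("epi%d", i - 1L), fragment = frag)
  })
}
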