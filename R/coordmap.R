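#' Map modified-reference positions back to the original host
#'
#' The coordinate map built by [simulate_integrations()] is, per host
#' chromosome, an ordered set of blocks `(mod_start, mod_stop,
#' orig_start, orig_stop, kind)` tiling the modified sequence. `host`
#' blocks translate 1:1; `virus` and `gap` blocks are inserted sequence
#' with no original coordinate (zero-width on the original axis);
#' `host_deleted` blocks are zero-width on the modified axis and record
#' host bases lost to deletions or consumed by overlap junctions.
#'
#' @param coord_map the `coord_map` element of an `integration_sim`.
#' @param chr host chromosome name.
#' @param pos integer vector of 0-based positions in the modified
#'   sequence.
#' @return data frame with one row per input position: `chr`, `pos`
#'   (input), `original` (0-based original coordinate, `NA` for
#'   virus/gap-derived positions), `kind`, and `nearest` (for `NA`
#'   positions, the original coordinate flanking the insertion; equals
#'   `original` for host positions).
#' @export
map_to_original <- function(coord_map, chr, pos) {
  b <- coord_map[[chr]]
  if (is.null(b)) stop("unknown chromosome: ", chr)
  w <- b[b$mod_stop > b$mod_start, , drop = FALSE]  # positive-width blocks
  if (any(pos < 0L | pos >= max(w$mod_stop))) {
    stop("position out of range of the modified sequence")
  }
  i <- findInterval(pos, w$mod_start)
  kind <- w$kind[i]
  host <- kind == "host"
  original <- ifelse(host, w$orig_start[i] + (pos - w$mod_start[i]), NA_integer_)
  data.frame(
    chr = chr, pos = pos,
    original = as.integer(original),
    kind = kind,
    nearest = as.integer(ifelse(host, original, w$orig_start[i])),
    stringsAsFactors = FALSE
  )
}

#' Map original host positions into the modified reference
#'
#' Inverse of [map_to_original()] for host-derived positions: every
#' original host base that was neither deleted nor consumed by an
#' overlap junction has a unique modified coordinate; deleted bases map
#' to `NA`.
#'
#' @inheritParams map_to_original
#' @param pos integer vector of 0-based positions in the original host
#'   chromosome.
#' @return integer vector of modified coordinates (`NA` where deleted).
#' @export
map_to_modified <- function(coord_map, chr, pos) {
  b <- coord_map[[chr]]
  if (is.null(b)) stop("unknown chromosome: ", chr)
  h <- b[b$kind == "host", , drop = FALSE]
  if (any(pos < 0L | pos >= max(b$orig_stop))) {
    stop("position out of range of the original sequence")
  }
  i <- findInterval(pos, h$orig_start)
  ok <- i >= 1L & pos < h$orig_stop[pmax(i, 1L)]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- h$mod_start[i[ok]] + (pos[ok] - h$orig_start[i[ok]])
  out
}
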