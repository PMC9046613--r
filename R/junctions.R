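#' Draw a host-virus junction
#'
#' Each junction is a gap (probability `p_gap`: inserted bases
#' attributable to neither host nor virus), an overlap (probability
#' `p_overlap`: microhomology between host and virus at the breakpoint),
#' or otherwise clean (host runs straight into virus). Gap and overlap
#' lengths are zero-truncated Poisson(`lambda_junction`) — a zero-length
#' gap or overlap would be indistinguishable from a clean junction and
#' would silently distort the type frequencies. Gap bases are i.i.d.
#' uniform over `{A,C,G,T}`; overlap bases are filled in at realisation
#' time from the fragment's junction-adjacent end.
#'
#' @param params simulation parameters.
#' @return list with `type` (`"gap"`, `"overlap"` or `"clean"`), `len`
#'   (bp; 0 iff clean) and `bases`.
#' @export
draw_junction <- function(params) {
  stopifnot(params$p_gap + params$p_overlap <= 1)
  u <- stats::runif(1)
  if (u < params$p_gap) {
    len <- rztpois(1L, params$lambda_junction)
    list(type = "gap", len = len, bases = random_bases(len))
  } else if (u < params$p_gap + params$p_overlap) {
    len <- rztpois(1L, params$lambda_junction)
    list(type = "overlap", len = len, bases = "")
  } else {
    list(type = "clean", len = 0L, bases = "")
  }
}

#' Draw a host-deletion length for one integration site
#'
#' With probability `1 - p_host_deletion` no host bases are lost (returns
#' 0); otherwise the deletion length is zero-truncated
#' Poisson(`lambda_host_deletion`). Deleted bases are removed immediately
#' 3' of the insertion point.
#'
#' @param params simulation parameters.
#' @return integer bp (0 = no deletion).
#' @export
draw_host_deletion <- function(params) {
  if (stats::runif(1) >= params$p_host_deletion) return(0L)
  rztpois(1L, params$lambda_host_deletion)
}
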