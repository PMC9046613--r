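#' Junction points of simulated integrations
#'
#' Each integration has a left and a right junction. In the modified
#' reference the left junction occupies `[intStart, intStart + lenL)`
#' and the right `[intStop - lenR, intStop)`, where the length is 0 for a
#' clean junction (a pure breakpoint) and the gap/overlap length
#' otherwise (the ambiguous interval whose bases cannot be assigned
#' unambiguously to host or virus). In original host coordinates the
#' left junction sits at `hPos` and the right at `hPos + hostDeleted`.
#'
#' @param int_info integration table (from an `integration_sim` or read
#'   back from an int-info TSV).
#' @return data frame: `int_id`, `side`, `ref`, `mod_start`, `mod_stop`,
#'   `host_chr`, `host_pos`.
#' @export
junction_points <- function(int_info) {
  if (inherits(int_info, "integration_sim")) int_info <- int_info$integrations
  if (nrow(int_info) == 0L) {
    return(data.frame(int_id = integer(0), side = character(0),
                      ref = character(0), mod_start = integer(0),
                      mod_stop = integer(0), host_chr = character(0),
                      host_pos = integer(0), stringsAsFactors = FALSE))
  }
  lenL <- ifelse(int_info$juncTypesLeft == "clean", 0L, int_info$juncLenLeft)
  lenR <- ifelse(int_info$juncTypesRight == "clean", 0L, int_info$juncLenRight)
  out <- rbind(
    data.frame(int_id = int_info$id, side = "left", ref = int_info$chr,
               mod_start = int_info$intStart,
               mod_stop = int_info$intStart + lenL,
               host_chr = int_info$chr, host_pos = int_info$hPos,
               stringsAsFactors = FALSE),
    data.frame(int_id = int_info$id, side = "right", ref = int_info$chr,
               mod_start = int_info$intStop - lenR,
               mod_stop = int_info$intStop,
               host_chr = int_info$chr,
               host_pos = int_info$hPos + int_info$hostDeleted,
               stringsAsFactors = FALSE)
  )
  out[order(out$int_id, out$side == "right"), , drop = FALSE]
}

## one row per mate: read_id, mate, ref, start, stop
mate_spans <- function(placements) {
  if (nrow(placements) == 0L) {
    return(data.frame(read_id = character(0), mate = integer(0),
                      ref = character(0), start = integer(0),
                      stop = integer(0), stringsAsFactors = FALSE))
  }
  rbind(
    data.frame(read_id = placements$read_id, mate = 1L, ref = placements$ref,
               start = placements$r1Start, stop = placements$r1Stop,
               stringsAsFactors = FALSE),
    data.frame(read_id = placements$read_id, mate = 2L, ref = placements$ref,
               start = placements$r2Start, stop = placements$r2Stop,
               stringsAsFactors = FALSE)
  )
}

#' Find reads crossing each integration junction (chimeric reads)
#'
#' A mate supports a junction iff its span covers the junction's
#' ambiguous interval entirely plus at least `min_flank` aligned bases on
#' each side, so the read demonstrably contains both host- and
#' virus-derived sequence. Each mate of a pair is evaluated
#' independently; supporting ids carry the mate suffix (`"/1"`, `"/2"`).
#'
#' @param placements placement table ([plan_fragments()],
#'   [read_placements()] or [read_placements_sam()]).
#' @param junctions junction table from [junction_points()].
#' @param min_flank minimum bases required on each side of the junction
#'   interval (default 1; real detectors often need 20 or more).
#' @return named list, one element per junction (name
#'   `"<int_id>:<side>"`), each a character vector of read ids.
#' @export
find_chimeric <- function(placements, junctions, min_flank = 1L) {
  stopifnot(min_flank >= 1L)
  ms <- mate_spans(placements)
  out <- vector("list", nrow(junctions))
  if (nrow(junctions) == 0L) return(out)
  names(out) <- paste0(junctions$int_id, ":", junctions$side)
  for (i in seq_len(nrow(junctions))) {
    a <- junctions$mod_start[i]
    b <- junctions$mod_stop[i]
    hit <- ms$ref == junctions$ref[i] &
      ms$start <= a - min_flank & ms$stop >= b + min_flank
    out[[i]] <- if (any(hit)) {
      paste0(ms$read_id[hit], "/", ms$mate[hit])
    } else character(0)
  }
  out
}

#' Find discordant read pairs for each integration
#'
#' A pair is discordant evidence for an integration iff neither mate is
#' chimeric for either of its junctions, one mate lies entirely in
#' host-derived sequence (intersecting no inserted span on its record)
#' and the other lies entirely within that integration's inserted
#' (virus + junction) span.
#'
#' @inheritParams find_chimeric
#' @param int_info integration table.
#' @return named list per integration id: character vector of pair ids.
#' @export
find_discordant <- function(placements, int_info, min_flank = 1L) {
  if (inherits(int_info, "integration_sim")) int_info <- int_info$integrations
  junctions <- junction_points(int_info)
  chim <- find_chimeric(placements, junctions, min_flank)
  chim_ids <- function(int_id) {
    unique(sub("/[12]$", "", c(chim[[paste0(int_id, ":left")]],
                               chim[[paste0(int_id, ":right")]])))
  }
  out <- vector("list", nrow(int_info))
  names(out) <- as.character(int_info$id)
  p <- placements
  ## a mate is host-derived only if it avoids every inserted span on its record
  m1_ins <- in_any_insert_by_ref(p$ref, p$r1Start, p$r1Stop, int_info)
  m2_ins <- in_any_insert_by_ref(p$ref, p$r2Start, p$r2Stop, int_info)
  for (i in seq_len(nrow(int_info))) {
    same_ref <- p$ref == int_info$chr[i]
    s <- int_info$intStart[i]; e <- int_info$intStop[i]
    m1_virus <- same_ref & p$r1Start >= s & p$r1Stop <= e
    m2_virus <- same_ref & p$r2Start >= s & p$r2Stop <= e
    m1_host <- same_ref & !m1_ins
    m2_host <- same_ref & !m2_ins
    cand <- (m1_host & m2_virus) | (m1_virus & m2_host)
    if (any(cand)) {
      excl <- p$read_id %in% chim_ids(int_info$id[i])
      cand <- cand & !excl
    }
    out[[i]] <- p$read_id[cand]
  }
  out
}

in_any_insert_by_ref <- function(ref, start, stop, int_info) {
  hit <- rep(FALSE, length(ref))
  for (k in seq_len(nrow(int_info))) {
    hit <- hit | (ref == int_info$chr[k] &
                    start < int_info$intStop[k] & stop > int_info$intStart[k])
  }
  hit
}

#' Annotate the integration table with supporting reads
#'
#' Appends to each int-info row the ids of reads crossing its left and
#' right junctions and of discordant pairs, plus their counts. Original
#' columns and row order are preserved.
#'
#' @param int_info integration table.
#' @param chimeric result of [find_chimeric()].
#' @param discordant result of [find_discordant()] (optional; empty if
#'   omitted).
#' @return the annotated data frame with extra columns `leftReads`,
#'   `rightReads`, `discordantPairs` (semicolon-joined ids, `""` if
#'   none) and `nLeft`, `nRight`, `nDiscordant`.
#' @export
annotate_int_info <- function(int_info, chimeric, discordant = NULL) {
  if (inherits(int_info, "integration_sim")) int_info <- int_info$integrations
  known <- c(paste0(int_info$id, ":left"), paste0(int_info$id, ":right"))
  bad <- setdiff(names(chimeric), known)
  if (length(bad)) stop("support refers to unknown integration id(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(discordant)) {
    bad <- setdiff(names(discordant), as.character(int_info$id))
    if (length(bad)) stop("discordant support refers to unknown id(s): ",
                          paste(bad, collapse = ", "))
  }
  get_ids <- function(lst, key) {
    v <- lst[[key]]
    if (is.null(v)) character(0) else unique(v)
  }
  left <- lapply(int_info$id, function(i) get_ids(chimeric, paste0(i, ":left")))
  right <- lapply(int_info$id, function(i) get_ids(chimeric, paste0(i, ":right")))
  disc <- lapply(int_info$id, function(i)
    if (is.null(discordant)) character(0) else get_ids(discordant, as.character(i)))
  int_info$leftReads <- vapply(left, paste, "", collapse = ";")
  int_info$rightReads <- vapply(right, paste, "", collapse = ";")
  int_info$discordantPairs <- vapply(disc, paste, "", collapse = ";")
  int_info$nLeft <- lengths(left)
  int_info$nRight <- lengths(right)
  int_info$nDiscordant <- lengths(disc)
  int_info
}

#' Write supported junction locations as BED3
#'
#' One line per junction with at least one chimeric read, as a 1 bp
#' point feature at the junction's original-host coordinate (BED3 cannot
#' carry the gap/overlap ambiguity interval, which remains in the
#' annotated TSV): `chrom`, `host_pos`, `host_pos + 1`. Lines are sorted
#' by `(chrom, start)`; no header; LF endings.
#'
#' @param junctions junction table from [junction_points()].
#' @param chimeric result of [find_chimeric()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_supported_bed <- function(junctions, chimeric, path) {
  key <- if (nrow(junctions)) paste0(junctions$int_id, ":", junctions$side)
         else character(0)
  n_support <- vapply(key, function(k) length(chimeric[[k]] %||% character(0)),
                      integer(1))
  sup <- junctions[n_support > 0L, , drop = FALSE]
  sup <- sup[order(sup$host_chr, sup$host_pos), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(sup)) {
    writeLines(sprintf("%s\t%d\t%d", sup$host_chr, sup$host_pos,
                       sup$host_pos + 1L), con)
  }
  invisible(path)
}
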