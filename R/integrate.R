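#' Simulate viral integrations into a host reference
#'
#' Constructs a modified reference in which viral sequence has been
#' integrated at randomly chosen host sites, together with a full ground
#' truth. Per integration: a host chromosome is chosen with probability
#' proportional to its length and the position uniformly; a viral
#' fragment is drawn ([draw_fragment()]) and possibly restructured
#' ([apply_structural_variation()]); a junction type is drawn for each
#' side ([draw_junction()]); and a host deletion may remove bases
#' immediately 3' of the insertion point ([draw_host_deletion()]).
#' Episomal viral sequences ([make_episomes()]) are appended as extra
#' FASTA records named `epi0`, `epi1`, ...
#'
#' The realised modified chromosome is, per site and left to right:
#' host prefix, left-junction gap bases (if a gap), the oriented fragment
#' pieces, right-junction gap bases, then the host suffix, skipping any
#' deleted host bases. An overlap junction of length n consumes the n
#' host bases adjacent to the insertion point and represents them with
#' the fragment's terminal n bases, so the junction bases match the viral
#' fragment by construction (microhomology); those bases are counted
#' inside the fragment span.
#'
#' All coordinates are 0-based, half-open. `hPos` is the position in the
#' ORIGINAL host reference immediately before which the insertion
#' occurred; `intStart`/`intStop` delimit the inserted (virus + gap)
#' bases in the modified reference.
#'
#' @param host host reference: FASTA path, `DNAStringSet`, or named
#'   character vector (one or more chromosomes).
#' @param viruses viral reference(s), same accepted forms.
#' @param params simulation parameters, see [default_params()].
#' @param seed integer seed; if `NULL`, the current RNG state is used.
#' @return an object of class `integration_sim`: a list with
#'   `reference` (named character, modified chromosomes then episomes),
#'   `integrations` (the int-info data frame; see Details), `episomes`
#'   (epi-info data frame), `coord_map` (see [map_to_original()]),
#'   `host_names`, `params`, `seed`.
#' @details The `integrations` table has one row per integration with
#'   columns `id`, `chr`, `hPos`, `hostDeleted`, `virus`, `virusStart`,
#'   `virusStop`, `fragmentStructure`, `whole`, `rearrangement`,
#'   `deletion`, `numFragments`, `juncTypesLeft`, `juncTypesRight`,
#'   `juncLenLeft`, `juncLenRight`, `juncBasesLeft`, `juncBasesRight`,
#'   `intStart`, `intStop`.
#' @examples
#' fix <- sim_fixture(chromosome_length = 20000, virus_length = 1000, seed = 1)
#' sim <- simulate_integrations(fix$host, fix$virus,
#'                              default_params(n_ints = 5, min_sep = 500),
#'                              seed = 1)
#' sim
#' @export
simulate_integrations <- function(host, viruses, params = default_params(),
                                  seed = NULL) {
  host <- load_fasta(host)
  viruses <- load_fasta(viruses)
  params <- validate_params(params, viruses)
  if (any(grepl("^epi\\d+$", names(host)))) {
    stop("host chromosome names must not collide with episome ids (epiK)")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  sites <- choose_sites(host, params$n_ints, params$min_sep)
  n <- nrow(sites)

  ## per-site random draws, in (chr, hPos) order; int_ids follow this order
  events <- vector("list", n)
  for (i in seq_len(n)) {
    vi <- sample.int(length(viruses), 1L)
    frag <- draw_fragment(names(viruses)[vi], nchar(viruses[[vi]]), params)
    frag <- apply_structural_variation(frag, params)
    events[[i]] <- list(
      frag = frag,
      jl = draw_junction(params),
      jr = draw_junction(params),
      host_del = draw_host_deletion(params)
    )
  }
  episomes <- make_episomes(viruses, params)

  ## realise chromosome by chromosome
  modified <- character(0)
  coord_map <- list()
  rows <- vector("list", n)
  for (chr in names(host)) {
    hseq <- host[[chr]]
    L <- nchar(hseq)
    idx <- which(sites$chr == chr)
    parts <- character(0)
    blocks <- list()
    mod_len <- 0L
    cursor <- 0L  # original-coordinate position of next unconsumed host base

    add_block <- function(ms, me, os, oe, kind) {
      blocks[[length(blocks) + 1L]] <<-
        data.frame(mod_start = ms, mod_stop = me, orig_start = os,
                   orig_stop = oe, kind = kind, stringsAsFactors = FALSE)
    }

    for (i in idx) {
      ev <- events[[i]]
      hpos <- sites$pos[i]
      frag <- ev$frag
      fseq <- realize_fragment(frag, viruses[[frag$virus]])
      flen <- nchar(fseq)
      jl <- ev$jl
      jr <- ev$jr

      ## cap junction/deletion extents so neighbouring sites and the
      ## chromosome ends are never overrun (negligible under sane
      ## min_sep; a capped-to-zero gap/overlap degrades to clean)
      j <- which(idx == i)
      next_bound <- if (j < length(idx)) sites$pos[idx[j + 1L]] else L
      nL <- if (jl$type == "overlap") min(jl$len, hpos - cursor, flen) else 0L
      del <- min(ev$host_del, next_bound - hpos)
      nR <- if (jr$type == "overlap") {
        min(jr$len, next_bound - hpos - del, flen - nL)
      } else 0L
      if (jl$type == "overlap" && nL != jl$len) {
        if (nL == 0L) { jl$type <- "clean"; jl$bases <- "" }
        jl$len <- nL
      }
      if (jr$type == "overlap" && nR != jr$len) {
        if (nR == 0L) { jr$type <- "clean"; jr$bases <- "" }
        jr$len <- nR
      }
      gapL <- if (jl$type == "gap") jl$len else 0L
      gapR <- if (jr$type == "gap") jr$len else 0L

      ## host prefix up to the insertion point (minus overlap-consumed bases)
      pre_stop <- hpos - nL
      if (pre_stop > cursor) {
        parts <- c(parts, substring(hseq, cursor + 1L, pre_stop))
        add_block(mod_len, mod_len + (pre_stop - cursor), cursor, pre_stop, "host")
        mod_len <- mod_len + (pre_stop - cursor)
      }
      if (nL > 0L) {
        jl$bases <- substring(fseq, 1L, nL)
        add_block(mod_len, mod_len, pre_stop, hpos, "host_deleted")
      }
      int_start <- mod_len
      if (gapL > 0L) {
        parts <- c(parts, jl$bases)
        add_block(mod_len, mod_len + gapL, hpos, hpos, "gap")
        mod_len <- mod_len + gapL
      }
      parts <- c(parts, fseq)
      add_block(mod_len, mod_len + flen, hpos, hpos, "virus")
      mod_len <- mod_len + flen
      if (del > 0L) add_block(mod_len, mod_len, hpos, hpos + del, "host_deleted")
      if (nR > 0L) {
        jr$bases <- substring(fseq, flen - nR + 1L, flen)
        add_block(mod_len, mod_len, hpos + del, hpos + del + nR, "host_deleted")
      }
      if (gapR > 0L) {
        parts <- c(parts, jr$bases)
        add_block(mod_len, mod_len + gapR, hpos + del + nR, hpos + del + nR, "gap")
        mod_len <- mod_len + gapR
      }
      int_stop <- mod_len
      cursor <- hpos + del + nR

      rows[[i]] <- data.frame(
        id = i - 1L, chr = chr, hPos = hpos, hostDeleted = del,
        virus = frag$virus, virusStart = frag$source_start,
        virusStop = frag$source_stop,
        fragmentStructure = fragment_structure(frag),
        whole = frag$is_whole, rearrangement = frag$is_rearranged,
        deletion = frag$has_deletion, numFragments = nrow(frag$pieces),
        juncTypesLeft = jl$type, juncTypesRight = jr$type,
        juncLenLeft = jl$len, juncLenRight = jr$len,
        juncBasesLeft = jl$bases, juncBasesRight = jr$bases,
        intStart = int_start, intStop = int_stop,
        stringsAsFactors = FALSE
      )
    }
    if (cursor < L) {
      parts <- c(parts, substring(hseq, cursor + 1L, L))
      add_block(mod_len, mod_len + (L - cursor), cursor, L, "host")
      mod_len <- mod_len + (L - cursor)
    }
    modified[[chr]] <- paste(parts, collapse = "")
    coord_map[[chr]] <- do.call(rbind, blocks)
  }

  integrations <- if (n > 0L) do.call(rbind, rows) else empty_int_info()

  epi_rows <- lapply(episomes, function(e) {
    f <- e$fragment
    data.frame(id = e$epi_id, virus = f$virus, start = f$source_start,
               stop = f$source_stop, fragmentStructure = fragment_structure(f),
               whole = f$is_whole, rearrangement = f$is_rearranged,
               deletion = f$has_deletion, stringsAsFactors = FALSE)
  })
  epi_info <- if (length(epi_rows)) do.call(rbind, epi_rows) else
    data.frame(id = character(0), virus = character(0), start = integer(0),
               stop = integer(0), fragmentStructure = character(0),
               whole = logical(0), rearrangement = logical(0),
               deletion = logical(0), stringsAsFactors = FALSE)
  for (e in episomes) {
    modified[[e$epi_id]] <- realize_fragment(e$fragment, viruses[[e$fragment$virus]])
  }

  structure(list(
    reference = modified,
    integrations = integrations,
    episomes = epi_info,
    coord_map = coord_map,
    host_names = names(host),
    params = params,
    seed = seed
  ), class = "integration_sim")
}

empty_int_info <- function() {
  data.frame(
    id = integer(0), chr = character(0), hPos = integer(0),
    hostDeleted = integer(0), virus = character(0), virusStart = integer(0),
    virusStop = integer(0), fragmentStructure = character(0),
    whole = logical(0), rearrangement = logical(0), deletion = logical(0),
    numFragments = integer(0), juncTypesLeft = character(0),
    juncTypesRight = character(0), juncLenLeft = integer(0),
    juncLenRight = integer(0), juncBasesLeft = character(0),
    juncBasesRight = character(0), intStart = integer(0),
    intStop = integer(0), stringsAsFactors = FALSE
  )
}

#' @export
print.integration_sim <- function(x, ...) {
  ints <- x$integrations
  cat("Simulated viral integration reference\n")
  cat("  host chromosomes:", length(x$host_names),
      sprintf("(%s bp modified)",
              format(sum(nchar(x$reference[x$host_names])), big.mark = ",")), "\n")
  cat("  integrations:", nrow(ints), " episomes:", nrow(x$episomes), "\n")
  if (nrow(ints)) {
    cat(sprintf("  sub-genomic: %d  rearranged: %d  fragment-deleted: %d  host-deleted sites: %d\n",
                sum(!ints$whole), sum(ints$rearrangement), sum(ints$deletion),
                sum(ints$hostDeleted > 0)))
    jt <- table(factor(c(ints$juncTypesLeft, ints$juncTypesRight),
                       levels = c("clean", "gap", "overlap")))
    cat(sprintf("  junctions: %d clean, %d gap, %d overlap\n",
                jt[["clean"]], jt[["gap"]], jt[["overlap"]]))
  }
  invisible(x)
}

#' @export
summary.integration_sim <- function(object, ...) {
  ints <- object$integrations
  n <- nrow(ints)
  out <- list(
    n_integrations = n,
    n_episomes = nrow(object$episomes),
    frac_subgenomic = if (n) mean(!ints$whole) else NA_real_,
    frac_rearranged = if (n) mean(ints$rearrangement) else NA_real_,
    frac_deleted = if (n) mean(ints$deletion) else NA_real_,
    frac_host_deletion = if (n) mean(ints$hostDeleted > 0) else NA_real_,
    mean_host_deletion = if (any(ints$hostDeleted > 0))
      mean(ints$hostDeleted[ints$hostDeleted > 0]) else NA_real_,
    junction_types = if (n) prop.table(table(factor(
      c(ints$juncTypesLeft, ints$juncTypesRight),
      levels = c("clean", "gap", "overlap")))) else NULL
  )
  class(out) <- "summary.integration_sim"
  out
}

#' @export
print.summary.integration_sim <- function(x, ...) {
  cat("Integration simulation summary\n")
  cat(sprintf("  integrations: %d, episomes: %d\n", x$n_integrations, x$n_episomes))
  if (x$n_integrations > 0) {
    cat(sprintf("  fraction sub-genomic:      %.3f\n", x$frac_subgenomic))
    cat(sprintf("  fraction rearranged:       %.3f\n", x$frac_rearranged))
    cat(sprintf("  fraction fragment-deleted: %.3f\n", x$frac_deleted))
    cat(sprintf("  fraction host-deleted:     %.3f\n", x$frac_host_deletion))
    if (!is.na(x$mean_host_deletion))
      cat(sprintf("  mean host deletion (bp):   %.1f\n", x$mean_host_deletion))
    cat("  junction type frequencies:\n")
    for (k in names(x$junction_types))
      cat(sprintf("    %-8s %.3f\n", k, x$junction_types[[k]]))
  }
  invisible(x)
}

#' Write the per-replicate ground-truth outputs
#'
#' Writes `<prefix>.fa` (modified reference, 80-column FASTA),
#' `<prefix>.int-info.tsv` and `<prefix>.epi-info.tsv`.
#'
#' @param sim an `integration_sim`.
#' @param prefix output path prefix (directory + file stem).
#' @return named character vector of the paths written, invisibly.
#' @export
write_integration_outputs <- function(sim, prefix) {
  stopifnot(inherits(sim, "integration_sim"))
  paths <- c(
    fasta = paste0(prefix, ".fa"),
    int_info = paste0(prefix, ".int-info.tsv"),
    epi_info = paste0(prefix, ".epi-info.tsv")
  )
  write_fasta(sim$reference, paths[["fasta"]])
  write_tsv(sim$integrations, paths[["int_info"]])
  write_tsv(sim$episomes, paths[["epi_info"]])
  invisible(paths)
}
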