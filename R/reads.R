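#' Plan paired-end sequencing fragments
#'
#' For each reference record, the number of read pairs is
#' `ceiling(coverage * record_length / (2 * read_len))` (so even tiny
#' records get at least one pair). Fragment lengths are drawn from
#' Normal(`frag_mean`, `frag_sd`), rounded, and clamped to
#' `[read_len, record_length]`; fragment starts are uniform among valid
#' starts and the sequenced strand of the fragment is uniform. Reads are
#' inward-facing (FR): read 1 is the fragment's 5' end on the fragment
#' strand, read 2 the reverse complement of its 3' end.
#'
#' @param reference named character vector (modified reference records,
#'   including episomes), or an `integration_sim`.
#' @param params simulation parameters (uses `read_len`, `coverage`,
#'   `frag_mean`, `frag_sd`).
#' @return data frame of ground-truth placements: `read_id`, `ref`,
#'   `fragStart`, `fragStop`, `strand`, `r1Start`, `r1Stop`, `r2Start`,
#'   `r2Stop` (0-based half-open, on the modified reference).
#' @export
plan_fragments <- function(reference, params) {
  if (inherits(reference, "integration_sim")) reference <- reference$reference
  rl <- as.integer(params$read_len)
  out <- vector("list", length(reference))
  for (k in seq_along(reference)) {
    nm <- names(reference)[k]
    L <- nchar(reference[[k]])
    if (L < rl) {
      warning("record '", nm, "' (", L, " bp) shorter than read_len; skipped")
      next
    }
    n_pairs <- as.integer(ceiling(params$coverage * L / (2 * rl)))
    flen <- as.integer(round(stats::rnorm(n_pairs, params$frag_mean, params$frag_sd)))
    flen <- pmin(pmax(flen, rl), L)
    start <- as.integer(floor(stats::runif(n_pairs) * (L - flen + 1)))
    strand <- ifelse(stats::runif(n_pairs) < 0.5, "+", "-")
    stop_ <- start + flen
    plus <- strand == "+"
    r1s <- ifelse(plus, start, stop_ - rl)
    r2s <- ifelse(plus, stop_ - rl, start)
    out[[k]] <- data.frame(
      read_id = sprintf("%s-%d", nm, seq_len(n_pairs)),
      ref = nm, fragStart = start, fragStop = stop_, strand = strand,
      r1Start = as.integer(r1s), r1Stop = as.integer(r1s + rl),
      r2Start = as.integer(r2s), r2Stop = as.integer(r2s + rl),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no reference record is long enough for read_len")
  rownames(out) <- NULL
  out
}

## Phred quality string for the linear error ramp; same for every read.
ramp_quals <- function(read_len, p_start, p_end) {
  p <- seq(p_start, p_end, length.out = read_len)
  q <- ifelse(p <= 0, 41, round(-10 * log10(p)))
  q <- pmin(pmax(q, 2), 41)
  list(p = p, qual = intToUtf8(q + 33L), q = q)
}

apply_errors <- function(seqs, p) {
  ## substitute bases with position-dependent probability p; N never mutated
  rl <- length(p)
  n <- length(seqs)
  u <- matrix(stats::runif(n * rl), nrow = n, byrow = TRUE)
  hit <- which(u < matrix(p, nrow = n, ncol = rl, byrow = TRUE), arr.ind = TRUE)
  if (nrow(hit) == 0L) return(seqs)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (r in unique(hit[, 1L])) {
    cols <- hit[hit[, 1L] == r, 2L]
    s <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
    for (j in cols) {
      b <- s[j]
      if (b %in% c("A", "C", "G", "T")) {
        s[j] <- alt[[b]][sample.int(3L, 1L)]
      }
    }
    seqs[r] <- paste(s, collapse = "")
  }
  seqs
}

#' Realise read sequences and qualities from planned placements
#'
#' Extracts each mate's bases from the modified reference (reverse
#' complementing according to the fragment strand and FR orientation) and
#' applies a substitution-only error model: the per-base substitution
#' probability ramps linearly from `error_rate_start` at the 5' end of
#' the read to `error_rate_end` at the 3' end, and a substituted base is
#' uniform over the three alternatives. Quality characters encode the
#' model's error probability, `round(-10*log10(p))` clamped to `[2, 41]`
#' (Phred+33). `N` bases pass through unmutated with quality 2.
#'
#' @param placements placement table from [plan_fragments()].
#' @param reference named character vector of reference records.
#' @param params simulation parameters (uses `read_len`,
#'   `error_rate_start`, `error_rate_end`).
#' @return data frame: `read_id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`.
#' @export
realize_reads <- function(placements, reference, params) {
  if (inherits(reference, "integration_sim")) reference <- reference$reference
  rl <- as.integer(params$read_len)
  refseq <- reference[placements$ref]
  r1_raw <- substring(refseq, placements$r1Start + 1L, placements$r1Stop)
  r2_raw <- substring(refseq, placements$r2Start + 1L, placements$r2Stop)
  plus <- placements$strand == "+"
  r1 <- r1_raw; r2 <- r2_raw
  ## r1 reads the fragment strand 5'->3'; r2 is the inward mate
  if (any(!plus)) r1[!plus] <- revcomp(r1_raw[!plus])
  if (any(plus)) r2[plus] <- revcomp(r2_raw[plus])

  ramp <- ramp_quals(rl, params$error_rate_start, params$error_rate_end)
  if (any(ramp$p > 0)) {
    r1 <- apply_errors(r1, ramp$p)
    r2 <- apply_errors(r2, ramp$p)
  }
  qual_for <- function(s) {
    q <- rep(ramp$qual, length(s))
    has_n <- grepl("N", s, fixed = TRUE)
    for (i in which(has_n)) {
      qq <- ramp$q
      qq[gregexpr("N", s[i], fixed = TRUE)[[1]]] <- 2L
      q[i] <- intToUtf8(qq + 33L)
    }
    q
  }
  data.frame(
    read_id = placements$read_id,
    r1_seq = unname(r1), r1_qual = qual_for(r1),
    r2_seq = unname(r2), r2_qual = qual_for(r2),
    stringsAsFactors = FALSE
  )
}

#' Write a read-pair table as two FASTQ files
#'
#' Writes `<prefix>1.fq` and `<prefix>2.fq`, standard 4-line records,
#' ids suffixed `/1` and `/2`, mate order identical across the files.
#'
#' @param pairs data frame from [realize_reads()].
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_fastq <- function(pairs, prefix) {
  if (nrow(pairs) < 1L) stop("no read pairs to write")
  f1 <- paste0(prefix, "1.fq")
  f2 <- paste0(prefix, "2.fq")
  fq_lines <- function(ids, seqs, quals, mate) {
    as.vector(rbind(paste0("@", ids, "/", mate), seqs, "+", quals))
  }
  con <- file(f1, open = "wb")
  writeLines(fq_lines(pairs$read_id, pairs$r1_seq, pairs$r1_qual, 1L), con)
  close(con)
  con <- file(f2, open = "wb")
  writeLines(fq_lines(pairs$read_id, pairs$r2_seq, pairs$r2_qual, 2L), con)
  close(con)
  invisible(c(f1, f2))
}

#' Write / read the ground-truth placement table
#'
#' @param placements placement table from [plan_fragments()].
#' @param path TSV path.
#' @return `path` (write) or the placement data frame (read).
#' @export
write_placements <- function(placements, path) {
  write_tsv(placements, path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  read_tsv(path, colClasses = c(read_id = "character", ref = "character",
                                strand = "character"))
}

#' Read placements from a name-sorted SAM file
#'
#' Alternative placement source for externally simulated reads: primary
#' alignments of proper pairs are converted to the same table as
#' [plan_fragments()] (SAM 1-based positions converted to 0-based
#' half-open). Requires the `Rsamtools` package.
#'
#' @param path SAM file path.
#' @return placement data frame.
#' @export
read_placements_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_placements_sam() requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth"))
  a <- Rsamtools::scanBam(bam, param = prm)[[1]]
  primary <- bitwAnd(a$flag, 256L) == 0L & bitwAnd(a$flag, 2048L) == 0L &
    bitwAnd(a$flag, 4L) == 0L
  d <- data.frame(qname = a$qname, flag = a$flag,
                  ref = as.character(a$rname), start = a$pos - 1L,
                  stop = a$pos - 1L + a$qwidth,
                  stringsAsFactors = FALSE)[primary, , drop = FALSE]
  first <- bitwAnd(d$flag, 64L) == 64L
  m1 <- d[first, , drop = FALSE]
  m2 <- d[!first, , drop = FALSE]
  i <- match(m1$qname, m2$qname)
  ok <- !is.na(i)
  m1 <- m1[ok, , drop = FALSE]
  m2 <- m2[i[ok], , drop = FALSE]
  frag_start <- pmin(m1$start, m2$start)
  frag_stop <- pmax(m1$stop, m2$stop)
  data.frame(
    read_id = m1$qname, ref = m1$ref,
    fragStart = frag_start, fragStop = frag_stop,
    strand = ifelse(bitwAnd(m1$flag, 16L) == 16L, "-", "+"),
    r1Start = m1$start, r1Stop = m1$stop,
    r2Start = m2$start, r2Stop = m2$stop,
    stringsAsFactors = FALSE
  )
}
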