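#' Run one replicate end-to-end
#'
#' Simulates integrations, simulates reads, annotates junction support,
#' and writes the full per-replicate output set: `<prefix>.fa`,
#' `<prefix>.int-info.tsv`, `<prefix>.epi-info.tsv`, `<prefix>1.fq`,
#' `<prefix>2.fq`, `<prefix>.placements.tsv`,
#' `<prefix>.int-info.annotated.tsv`, `<prefix>.int-info.bed`.
#'
#' All randomness derives from `seed`: the RNG is seeded once and the
#' integration, read-planning and error draws consume one deterministic
#' stream, so a rerun is byte-identical.
#'
#' @param host,viruses references (path, `DNAStringSet` or named
#'   character).
#' @param params simulation parameters for this replicate.
#' @param seed integer seed for the replicate.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. `"cond0.rep0"`.
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a list with the `integration_sim`, the placement
#'   and annotated tables, and the output paths.
#' @export
run_replicate <- function(host, viruses, params, seed, out_dir, prefix,
                          quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(prefix, ": ", ...)
  stem <- file.path(out_dir, prefix)

  sim <- simulate_integrations(host, viruses, params, seed = seed)
  paths <- write_integration_outputs(sim, stem)
  ints <- sim$integrations
  say(nrow(ints), " integrations (", sum(!ints$whole), " sub-genomic, ",
      sum(ints$rearrangement), " rearranged, ", sum(ints$deletion),
      " with fragment deletion, ", sum(ints$hostDeleted > 0),
      " with host deletion), ", nrow(sim$episomes), " episomes")

  placements <- plan_fragments(sim$reference, params)
  pairs <- realize_reads(placements, sim$reference, params)
  write_fastq(pairs, stem)
  write_placements(placements, paste0(stem, ".placements.tsv"))
  say(nrow(placements), " read pairs at ", params$coverage, "x requested coverage")

  junctions <- junction_points(ints)
  chim <- find_chimeric(placements, junctions, params$min_flank)
  disc <- find_discordant(placements, ints, params$min_flank)
  annotated <- annotate_int_info(ints, chim, disc)
  write_tsv(annotated, paste0(stem, ".int-info.annotated.tsv"))
  write_supported_bed(junctions, chim, paste0(stem, ".int-info.bed"))
  supported <- sum(vapply(chim, length, integer(1)) > 0L)
  say(supported, "/", length(chim), " junctions with chimeric support, ",
      sum(lengths(disc)), " discordant pairs")

  invisible(list(
    sim = sim, placements = placements, annotated = annotated,
    paths = c(paths,
              fastq1 = paste0(stem, "1.fq"), fastq2 = paste0(stem, "2.fq"),
              placements = paste0(stem, ".placements.tsv"),
              annotated = paste0(stem, ".int-info.annotated.tsv"),
              bed = paste0(stem, ".int-info.bed"))
  ))
}

#' Run the full simulation pipeline from a config file
#'
#' Expands the config into its condition grid ([expand_conditions()]),
#' writes `simulation_summary.tsv`, and runs every replicate job
#' ([run_replicate()]) with its deterministic seed.
#'
#' @param config a config file path or a config list.
#' @param out_dir overrides the config's `out_dir` if given.
#' @param quiet suppress log messages.
#' @return invisibly, the job table with an extra `out_dir` attribute.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_sim_config(config) else
    validate_config(config)
  if (is.null(cfg$host_fasta) || is.null(cfg$virus_fasta)) {
    stop("config must set 'host_fasta' and 'virus_fasta'")
  }
  host <- load_fasta(cfg$host_fasta)
  viruses <- load_fasta(cfg$virus_fasta)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  jobs <- expand_conditions(cfg)
  write_summary(jobs, file.path(out_dir, "simulation_summary.tsv"))
  if (!quiet) message(nrow(jobs), " replicate job(s) across ",
                      length(unique(jobs$condition)), " condition(s)")
  for (i in seq_len(nrow(jobs))) {
    params <- as.list(jobs[i, names(.sim_param_defaults)])
    run_replicate(host, viruses, params, seed = jobs$seed[i],
                  out_dir = out_dir, prefix = jobs$output_prefix[i],
                  quiet = quiet)
  }
  attr(jobs, "out_dir") <- out_dir
  invisible(jobs)
}
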