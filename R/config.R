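## Simulation parameters.
##
## Every entry here may be list-valued in a config file; the Cartesian
## product of the lists defines the condition grid. Defaults are the
## package's reference condition, reflecting reported characteristics of
## AAV/vector integration (100 integrations, sub-genomic probability 0.5
## with >= 50 bp fragments, rearrangement/deletion probabilities 0.1
## with Poisson(1) piece counts, gap/overlap probabilities 0.2 with
## Poisson(1) junction lengths, host-deletion probability 0.2 with
## Poisson(20) lengths); read and spacing parameters are package defaults.

.sim_param_defaults <- list(
  n_ints               = 100L,
  min_sep              = 1000L,
  p_whole              = 0.5,
  min_len              = 50L,
  max_len              = 2000L,
  p_rearrange          = 0.1,
  p_delete             = 0.1,
  lambda_split         = 1,
  p_gap                = 0.2,
  p_overlap            = 0.2,
  lambda_junction      = 1,
  p_host_deletion      = 0.2,
  lambda_host_deletion = 20,
  epi_num              = 2L,
  read_len             = 150L,
  coverage             = 5,
  frag_mean            = 500,
  frag_sd              = 30,
  error_rate_start     = 0.001,
  error_rate_end       = 0.01,
  min_flank            = 1L
)

.prob_params  <- c("p_whole", "p_rearrange", "p_delete", "p_gap", "p_overlap",
                   "p_host_deletion", "error_rate_start", "error_rate_end")
.count_params <- c("n_ints", "min_sep", "min_len", "max_len", "epi_num",
                   "read_len", "min_flank")
.rate_params  <- c("lambda_split", "lambda_junction", "lambda_host_deletion")

.config_scalar_keys <- c("global_seed", "replicates",
                         "host_fasta", "virus_fasta", "out_dir")

#' Default simulation parameters
#'
#' Returns the package's reference condition: one complete set of
#' simulation parameters. Integration parameters reflect reported
#' characteristics of AAV/vector integration (see the package vignette);
#' read-simulation and spacing parameters are package defaults. Any
#' subset can be overridden.
#'
#' @param ... named overrides of individual parameters.
#' @return named list with one scalar value per simulation parameter.
#' @examples
#' p <- default_params(n_ints = 10, coverage = 2)
#' p$p_whole
#' @export
default_params <- function(...) {
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(.sim_param_defaults))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  utils::modifyList(.sim_param_defaults, over)
}

validate_param_values <- function(key, values) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values)) {
    stop("parameter '", key, "' must be one or more numeric values")
  }
  if (key %in% .prob_params && any(values < 0 | values > 1)) {
    stop("parameter '", key, "' must lie in [0, 1]")
  }
  if (key %in% .count_params && any(values < 0 | values != floor(values))) {
    stop("parameter '", key, "' must be a non-negative integer")
  }
  if (key %in% .rate_params && any(values <= 0)) {
    stop("parameter '", key, "' must be > 0")
  }
  if (key %in% c("coverage", "frag_mean") && any(values <= 0)) {
    stop("parameter '", key, "' must be > 0")
  }
  if (key == "frag_sd" && any(values < 0)) {
    stop("parameter '", key, "' must be >= 0")
  }
  invisible(values)
}

## Cross-parameter checks on one fully-resolved condition.
validate_params <- function(params, viruses = NULL) {
  for (key in names(.sim_param_defaults)) {
    if (is.null(params[[key]])) stop("missing parameter '", key, "'")
    if (length(params[[key]]) != 1L) stop("parameter '", key, "' must be scalar here")
    validate_param_values(key, params[[key]])
  }
  if (params$p_gap + params$p_overlap > 1) {
    stop("p_gap + p_overlap must be <= 1 (got ",
         params$p_gap + params$p_overlap, ")")
  }
  if (params$min_len < 1L) stop("min_len must be >= 1")
  if (params$min_len > params$max_len) stop("min_len must be <= max_len")
  if (params$read_len > params$frag_mean) stop("read_len must be <= frag_mean")
  if (params$min_flank < 1L) stop("min_flank must be >= 1")
  if (!is.null(viruses) && params$min_len > min(nchar(viruses))) {
    stop("min_len (", params$min_len, ") exceeds the shortest virus sequence (",
         min(nchar(viruses)), " bp)")
  }
  params
}

#' Read and validate a simulation config file
#'
#' The config is a YAML file in which every simulation parameter
#' (`n_ints`, `min_sep`, `p_whole`, `min_len`, `max_len`, `p_rearrange`,
#' `p_delete`, `lambda_split`, `p_gap`, `p_overlap`, `lambda_junction`,
#' `p_host_deletion`, `lambda_host_deletion`, `epi_num`, plus the read and
#' annotation parameters) may be a scalar or a list of values; the
#' Cartesian product of the lists defines the condition grid. Scalar keys:
#' `global_seed`, `replicates`, `host_fasta`, `virus_fasta`, `out_dir`.
#' Unknown keys are an error (a silent typo in a probability name would
#' corrupt a simulation); omitted parameters take the [default_params()]
#' values.
#'
#' @param path path to a YAML config file.
#' @return a validated config list with all defaults applied.
#' @seealso [expand_conditions()], [run_pipeline()]
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg))) stop("config must be a YAML mapping")
  validate_config(cfg)
}

#' @rdname read_sim_config
#' @param cfg a config given directly as a named list.
#' @export
validate_config <- function(cfg) {
  known <- c(names(.sim_param_defaults), .config_scalar_keys)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$replicates  <- cfg$replicates %||% 1L
  cfg$global_seed <- cfg$global_seed %||% 1L
  cfg$out_dir     <- cfg$out_dir %||% "sim_out"
  if (!is.numeric(cfg$replicates) || length(cfg$replicates) != 1L ||
      cfg$replicates < 1 || cfg$replicates != floor(cfg$replicates)) {
    stop("'replicates' must be a positive integer")
  }
  if (!is.numeric(cfg$global_seed) || length(cfg$global_seed) != 1L) {
    stop("'global_seed' must be a single integer")
  }
  for (key in names(.sim_param_defaults)) {
    vals <- cfg[[key]] %||% .sim_param_defaults[[key]]
    vals <- unlist(vals)
    validate_param_values(key, vals)
    cfg[[key]] <- vals
  }
  cfg
}

#' Expand a config into a grid of replicate jobs
#'
#' Forms the Cartesian product of all list-valued simulation parameters
#' (one combination = one condition) and repeats each condition
#' `replicates` times. Conditions are ordered lexicographically by
#' parameter name (alphabetical), with values in the order given in the
#' config, so `condX` indices are stable. Each job receives a
#' deterministic seed from [mix_seed()]`(global_seed, condition,
#' replicate)`; seeds are guaranteed pairwise distinct across the grid.
#'
#' @param cfg a config list from [read_sim_config()] or [validate_config()].
#' @return a data frame with one row per job: columns `condition`,
#'   `replicate` (both 0-based), `seed`, `output_prefix`
#'   (`"condX.repY"`), then one column per simulation parameter.
#' @examples
#' cfg <- validate_config(list(p_whole = c(0.3, 1), replicates = 2))
#' jobs <- expand_conditions(cfg)
#' nrow(jobs)  # 2 conditions x 2 replicates
#' @export
expand_conditions <- function(cfg) {
  cfg <- validate_config(cfg)
  nms <- sort(names(.sim_param_defaults))
  vals <- cfg[nms]
  lens <- vapply(vals, length, integer(1))
  if (prod(lens) < 1) stop("empty condition grid")

  ## expand.grid varies its first argument fastest; feed indices in
  ## reverse name order so the alphabetically-first parameter varies
  ## slowest, giving lexicographic condition order.
  idx <- expand.grid(rev(lapply(vals, seq_along)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(idx)), drop = FALSE]  # back to alphabetical cols
  n_cond <- nrow(idx)

  cond_tab <- as.data.frame(
    lapply(nms, function(k) vals[[k]][idx[[k]]]),
    col.names = nms
  )
  ## validate cross-parameter invariants per condition
  for (i in seq_len(n_cond)) {
    p <- as.list(cond_tab[i, , drop = FALSE])
    tryCatch(validate_params(p),
             error = function(e) stop("condition ", i - 1L, ": ",
                                      conditionMessage(e), call. = FALSE))
  }

  reps <- as.integer(cfg$replicates)
  condition <- rep(seq_len(n_cond) - 1L, each = reps)
  replicate <- rep(seq_len(reps) - 1L, times = n_cond)
  seeds <- mapply(mix_seed, cfg$global_seed, condition, replicate)
  ## deterministically resolve the (astronomically unlikely) collisions
  k <- 0L
  while (anyDuplicated(seeds)) {
    i <- which(duplicated(seeds))[1L]
    seeds[i] <- mix_seed(seeds[i], 1048576L + k, i)
    k <- k + 1L
  }
  jobs <- cbind(
    data.frame(condition = condition,
               replicate = replicate,
               seed = as.integer(seeds),
               output_prefix = sprintf("cond%d.rep%d", condition, replicate),
               stringsAsFactors = FALSE),
    cond_tab[condition + 1L, , drop = FALSE]
  )
  rownames(jobs) <- NULL
  jobs
}

#' Write the run summary table
#'
#' Writes one row per replicate job — every simulation parameter plus the
#' condition index, replicate index, seed and output prefix — to a
#' tab-separated file (conventionally `simulation_summary.tsv`).
#'
#' @param jobs job table from [expand_conditions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(jobs, path) {
  if (!is.data.frame(jobs) || nrow(jobs) < 1L) stop("'jobs' must be non-empty")
  write_tsv(jobs, path)
}
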