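# vintsim

Ground-truth simulation of viral and vector integration sequencing data.

Tools that detect where a virus or gene-therapy vector has integrated
into a host genome need benchmark data with known answers. Real
integration events are messy: often only a **sub-genomic fragment** of
the viral genome integrates, the integrated sequence may be
**rearranged** or carry an internal **deletion**, the host/virus
junctions may contain a **gap** (bases from neither genome) or an
**overlap** (microhomology shared by both), and the host genome
frequently loses bases at the integration site. `vintsim` simulates all
of these, tracks the exact ground truth, and emits the files an
integration-detection benchmark needs.

## The model

For each of `n_ints` integrations, a host chromosome is chosen with
probability proportional to its length and an insertion point `hPos`
uniformly along it, subject to a minimum pairwise spacing `min_sep`
(positions inside long ambiguity `N` runs are rejected). The inserted
sequence is drawn as:

- the whole viral genome with probability `p_whole`, otherwise a
  sub-genomic fragment with length uniform on `[min_len, max_len]` and
  uniform start; orientation is uniform on {+, −};
- with probability `p_rearrange` / `p_delete` (independent), the
  fragment is split into *k* pieces at uniform internal breakpoints,
  *k* ~ Poisson(`lambda_split`) conditioned on *k* ≥ 2 (rearrangement)
  or *k* ≥ 3 (deletion); rearrangement swaps two random pieces, deletion
  removes one interior piece;
- each junction is a gap with probability `p_gap`, an overlap with
  probability `p_overlap`, else clean; gap/overlap lengths are
  zero-truncated Poisson(`lambda_junction`). Gap bases are uniform
  random; overlap bases are the fragment's terminal bases, which replace
  the adjacent host bases so the junction matches both sequences;
- with probability `p_host_deletion`, a zero-truncated
  Poisson(`lambda_host_deletion`) number of host bases is deleted
  immediately 3′ of the insertion point.

`epi_num` episomal (non-integrated) viral sequences, drawn with the same
fragment and structural-variation model, are appended as extra records.
Paired-end reads are then simulated from the modified reference
(inward-facing pairs; counts set by `coverage`; fragment lengths
Normal(`frag_mean`, `frag_sd`); a linear substitution-error ramp from
`error_rate_start` to `error_rate_end` along the read), and every read
whose span covers a junction's ambiguous interval plus `min_flank` bases
on each side is recorded as chimeric support, with host/virus discordant
pairs tallied separately.

All coordinates are 0-based half-open; a coordinate map lets any
modified-reference position be lifted back to the original host.

## Worked example

```r
library(vintsim)

fix <- sim_fixture(chromosome_length = 100000, virus_length = 2000, seed = 1)
p   <- default_params(n_ints = 20, min_sep = 2000, coverage = 4)
sim <- simulate_integrations(fix$host, fix$virus, p, seed = 42)
sim
#> Simulated viral integration reference
#>   host chromosomes: 1 (132,409 bp modified)
#>   integrations: 20  episomes: 2
#>   sub-genomic: 8  rearranged: 1  fragment-deleted: 1  host-deleted sites: 3
#>   junctions: 25 clean, 7 gap, 8 overlap
```

The host grew from 100,000 to 132,409 bp: the inserted viral fragments
plus gap bases, minus overlap-consumed and deleted host bases. The
ground-truth table records every event; `hPos` is the insertion point in
the *original* host coordinates, `intStart`/`intStop` the inserted span
in the modified reference:

```r
sim$integrations[1:3, c("id", "chr", "hPos", "virusStart", "virusStop",
                        "whole", "juncTypesLeft", "juncTypesRight")]
#>   id  chr hPos virusStart virusStop whole juncTypesLeft juncTypesRight
#> 1  0 chr1   15        324      1645 FALSE         clean        overlap
#> 2  1 chr1 5402        295      1728 FALSE         clean          clean
#> 3  2 chr1 9090          0      2000  TRUE       overlap          clean

pl <- plan_fragments(sim$reference, p)
ch <- find_chimeric(pl, junction_points(sim$integrations), p$min_flank)
sum(lengths(ch) > 0)
#> [1] 38
```

At 4× coverage, 38 of the 40 junctions are already crossed by at least
one read; deeper coverage drives this to ~100%.

The full pipeline — condition grid from a YAML config, per-replicate
FASTA/TSV/FASTQ/BED outputs and a `simulation_summary.tsv` — runs via
`run_pipeline("simulation.yml")` or the bundled CLI
(`exec/vintsim run --config simulation.yml`); a template config ships in
`inst/extdata/simulation.yml`.

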