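---
title: "Simulating viral integration data with vintsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating viral integration data with vintsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vintsim)
```

## Why simulate integrations

Software that detects viral or vector integration from sequencing data
is hard to validate on real samples, because the true integration sites
are unknown. `vintsim` builds a *reference with known integrations*: it
modifies a host genome by inserting viral sequence with realistic
complications, simulates reads from the result, and records exactly
which reads carry evidence for each junction. Detector output can then
be scored against this ground truth.

The simulation deliberately reproduces the features that make real
integrations (wild-type AAV and AAV-derived vectors being the
motivating case) hard to detect: sub-genomic fragments, rearranged and
internally deleted inserts, junction gaps and microhomologies, and
host-side deletions.

## The generative model

One replicate proceeds in three stages.

**Integration.** `n_ints` insertion points are placed by rejection
sampling: a chromosome is drawn with probability proportional to its
length (so points are uniform over the genome), the position uniformly
on the chromosome; candidates closer than `min_sep` to an accepted
site, or inside a run of `N` longer than `min_sep/2`, are rejected.
Distances are measured in original host coordinates. If a greedy
placement dead-ends, the whole placement restarts; after 1,000 fruitless
rounds the configuration is declared infeasible. For each site the
inserted fragment is drawn (whole genome with probability `p_whole`,
else length uniform on `[min_len, min(max_len, virus length)]`,
start uniform, orientation uniform on {+,−}), then structural variation
is applied, then the two junctions and the host deletion are drawn.
Integration ids are assigned in (chromosome, position) order.

**Reads.** For every record of the modified reference (including
episomes), `ceiling(coverage * length / (2 * read_len))` inward-facing
pairs are planned — the ceiling guarantees even a tiny episome is
covered — with Normal(`frag_mean`, `frag_sd`) fragment lengths rounded
and clamped to `[read_len, record length]` (clamping rather than
redrawing introduces negligible bias when records are much longer than
the mean). Substitution errors follow a linear ramp from
`error_rate_start` at the 5′ end to `error_rate_end` at the 3′ end;
quality characters encode the model's per-position error probability
(`round(-10*log10 p)` clamped to `[2, 41]`, Phred+33). There are no
indel errors and no instrument-specific error profiles: the generator
is self-contained and its error process is exactly known, which is what
a ground-truth benchmark needs.

**Annotation.** Because the simulator knows every read's true placement,
junction support is computed from placements, not from realignment. A
mate is chimeric for a junction when its span covers the junction's
ambiguous interval entirely plus at least `min_flank` bases on each
side; a pair is discordant for an integration when neither mate is
chimeric for it, one mate lies wholly in host-derived sequence and the
other wholly inside the inserted span. An optional SAM input path
(`read_placements_sam()`) lets externally generated reads be annotated
the same way.

## Parameters

| key | meaning | default |
|---|---|---|
| `n_ints` | integrations per replicate | 100 |
| `min_sep` | minimum site spacing, bp (original coordinates) | 1000 |
| `p_whole` | probability the whole virus integrates | 0.5 |
| `min_len`, `max_len` | sub-genomic fragment length bounds, bp | 50, 2000 |
| `p_rearrange`, `p_delete` | structural-variation probabilities | 0.1, 0.1 |
| `lambda_split` | Poisson mean piece count when splitting | 1 |
| `p_gap`, `p_overlap` | junction-type probabilities (per junction) | 0.2, 0.2 |
| `lambda_junction` | Poisson mean junction length, bp | 1 |
| `p_host_deletion` | probability of host deletion per site | 0.2 |
| `lambda_host_deletion` | Poisson mean deletion length, bp | 20 |
| `epi_num` | episome count | 2 |
| `read_len` | read length, bp | 150 |
| `coverage` | fold coverage | 5 |
| `frag_mean`, `frag_sd` | sequencing fragment length, bp | 500, 30 |
| `error_rate_start`, `error_rate_end` | substitution rate at read ends | 0.001, 0.01 |
| `min_flank` | bases required beyond a junction to call a read chimeric | 1 |

The integration-model defaults are the package's reference condition,
matching published observations on AAV integration (half of events
sub-genomic with a 50 bp minimum, rearrangement/deletion each at 0.1
with Poisson(1) splitting, gap/overlap each at 0.2 with ~1 bp
junctions, host deletions at 0.2 with mean 20 bp). `max_len`,
`min_sep`, `epi_num` and the read parameters have no published
counterpart; their defaults are package choices: `max_len` 2000 keeps
sub-genomic fragments clearly partial on a ~5 kb genome, `min_sep` 1000
keeps neighbouring events from interacting at 150 bp reads and ~500 bp
fragments, and the read defaults mirror a common Illumina paired-end
configuration. In a config file any parameter may be a list; the
Cartesian product (conditions ordered by sorted parameter name, values
in config order) times `replicates` defines the grid, and each job's
seed is a deterministic 31-bit mix of `(global_seed, condition,
replicate)` so grids reproduce across machines.

## Design choices worth knowing

- **Coordinates** are 0-based half-open throughout; `hPos` is reported
  0-based and is directly BED-compatible.
- **Truncated draws by inversion.** Junction lengths, host-deletion
  lengths and piece counts are Poisson draws conditioned on a minimum,
  sampled by inverse CDF on the truncated range. A zero-length gap or
  overlap is indistinguishable from a clean junction, so lengths are
  conditioned ≥ 1; the realised mean at `lambda_junction = 1` is
  therefore `1/(1 − e^−1) ≈ 1.582`, not 1. Piece counts are conditioned
  ≥ 2 for rearrangement (a swap needs two pieces) and ≥ 3 for deletion,
  and deletions remove only interior pieces, so the fragment's outer
  ends — and with them the junction semantics — always survive.
- **Rearrangement and deletion are independent events**; both can affect
  one fragment.
- **Overlap realisation.** An overlap of length *n* consumes the *n*
  host bases adjacent to the insertion point and represents them with
  the fragment's terminal *n* bases. This guarantees the defining
  property of microhomology — the junction bases match the viral
  fragment — without searching the host for natural homology; the
  host-side identity of those bases is not preserved and the bases are
  accounted as virus-derived. Host deletions remove bases immediately
  3′ of the insertion point.
- **Degenerate geometry.** Junction and deletion extents are capped so
  they can never overrun a neighbouring site or a chromosome end; a cap
  that forces an overlap/gap to length 0 degrades it to a clean
  junction. With the default `min_sep` this never occurs in practice.
- **The coordinate map** tiles each modified chromosome into
  host/virus/gap blocks, with zero-width `host_deleted` blocks recording
  lost host intervals (including overlap-consumed bases). This makes
  the original↔modified mapping exact and testable: mapping every
  non-deleted host base out and back is the identity.
- **Episomes** use the same `p_whole`/`p_rearrange`/`p_delete` model as
  integrations, so they may be sub-genomic; they have no host junctions
  and never contribute junction support.

## What the synthetic fixtures do and do not show

`sim_fixture()` generates i.i.d. host/virus sequence at a chosen GC
fraction, optionally with injected `N` runs. That suffices to exercise
every code path and every distributional claim the tests make (event
frequencies, length accounting, coordinate round-trips, junction
support at depth). It does **not** contain repeats, segmental
duplications, or host/virus homology, so passing tests say nothing
about how *detectors* cope with ambiguous alignments — only that the
simulated truth is internally consistent. Benchmarks of real tools
should use real references (e.g. an AAV2 genome and a human
chromosome), which the simulator accepts as ordinary FASTA.

## Problem sizes used in the test suite

Unit tests run on 5–50 kb hosts with sub-kilobase viruses. The
distributional checks pool 50 replicates of the reference condition on
a synthetic 1 Mb host with a 5 kb virus (5,000 events, 10,000
junctions) and accept empirical frequencies within four binomial
standard deviations of their parameters — wide enough to be stable
across seeds, tight enough to catch any systematic bias. The same
pooled computation, seeded from the command line, is what
`scripts/acceptance.R` reports.

## Limitations

- No integration-site sequence preference (hotspots, motifs): positions
  are uniform.
- No concatemeric multi-copy inserts beyond what one fragment's
  rearrangement produces.
- Substitution-only read errors; no indels, PCR duplicates, GC bias or
  per-cycle quality structure.
- BED output collapses a gap/overlap junction to a 1 bp point at its
  host-side coordinate; the full ambiguity interval is only in the
  annotated TSV.
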