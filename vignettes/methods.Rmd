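---
title: "Genotyping multi-copy immune-receptor V genes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping multi-copy immune-receptor V genes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgenotyper)
```

## The problem

Immunoglobulin and T-cell-receptor variable (V) gene loci contain dozens of
short (~280–300 bp), highly similar gene copies, each segregating several
alleles that differ by only a few substitutions, with additional
high-identity paralogs ("orphons") scattered elsewhere in the genome. A
150 bp read from one of these genes typically aligns almost equally well to
several database alleles, so per-read mapping cannot decide the genotype.
The observation that rescues the problem is global: across the whole read
set, the *depth of coverage* on each real gene copy must match the
genome-wide sequencing depth. `vgenotyper` turns that observation into an
integer linear program (ILP).

## Read recruitment and the depth profile

Reads are extracted from an indexed BAM over the target locus plus orphon
regions (`recruit_reads()`), deduplicated by read name and mate flag and
treated as single-end from then on — the ILP assigns individual reads and
pair information adds nothing to the depth constraints. Orphon regions
themselves can be derived offline by mapping database-derived reads to a
reference genome and merging contiguous placements, dropping regions
shorter than one read length (`discover_orphons()`; the merge-and-filter
logic is exact interval union via `IRanges::reduce`, checked in the tests
against a brute-force union oracle).

The expected depth is estimated from a large background region away from
the locus (`estimate_depth()`): per-base depth sampled at 10,000 uniformly
random positions (seeded), zero-depth positions included so that sparse or
targeted data produce a conservatively low mean rather than a silently
wrong one. The estimate is on the raw, diploid scale; because the ILP's
copy-number variable multiplies a *per-copy* depth, the pipeline divides
the mean by the background ploidy and the SD by its square root
(Poisson-consistent) before model construction. This per-copy reading is
the only one under which an ordinary two-copy gene at genome-average
coverage is feasible with copy number 2.

## Candidate mapping

Every recruited read is aligned end-to-end against every allele of the
padded database (`map_reads_to_alleles()`). Alleles are padded with
flanking `N`s (default 150, one read length) and positions aligned against
`N` are free, so a read overhanging an allele end aligns at the cost of its
overlapping bases only. Substitutions and gap bases cost one edit;
candidates up to 25 edits are kept, the equivalent of an end-to-end
alignment score floor of −50 at a mismatch penalty of 2. The aligner is
seed-and-extend: exact 15-mers looked up in an index of the padded
database, then banded semi-global dynamic programming around the seeded
diagonals. Anchoring the alignment start to the seeded diagonals matters:
with read-length padding, an unanchored placement could slide entirely
into the `N` flank at zero cost, which is meaningless. The consequence is
that a placement must share at least one exact 15-mer with the allele;
alignments whose true gap offset exceeds the DP band (default 5) can be
missed, which at these read lengths and divergences is negligible. An
adapter (`read_sam_candidates()`) ingests SAM from an external all-mapper
for parity experiments.

## The assignment ILP

With candidates $(r, a)$ and edit distances $e_{ra}$, the model
(`build_model()`) has binaries $x_{ra}$ (read $r$ assigned to allele $a$),
$d_r$ (read discarded), $z_a$ (allele called), and integers
$c_a \in [0, C_{\max}]$:

$$\min \sum e_{ra} x_{ra} + P \sum_r d_r$$

subject to

* $\sum_a x_{ra} + d_r = 1$ for every read;
* $x_{ra} \le z_a$, and $z_a \le c_a \le C_{\max} z_a$;
* for every allele $a$ and landmark group $g$:
  $c_a(\mu - s\sigma) \;\le\; \mathrm{cov}_{a,g} \;\le\; c_a(\mu + s\sigma)$,

where $\mathrm{cov}_{a,g}$ is the mean, over the group's landmarks, of the
number of assigned reads covering each landmark, and $(\mu, \sigma)$ is
the per-copy depth profile. Coverage is evaluated only at landmarks — a
few uniformly spaced positions per allele — to keep the model small.

Choices worth recording:

* **Landmark layout.** Default 6 groups × 6 landmarks, at interior
  positions $\mathrm{round}(k \cdot \ell / 37)$, $k = 1..36$ for core
  length $\ell$; the termini are avoided because clipped/overhang
  alignments make edge coverage unreliable. For cores shorter than twice
  the landmark count the rule degenerates to evenly spaced distinct
  offsets (saturating at one per base, with a warning below 36 bp).
  Positions depend only on core length, so equal-length alleles share
  landmarks.
* **Group-mean constraints.** The depth window is enforced on the group
  mean rather than per landmark; the mean smooths single-landmark
  fluctuations and edge effects while groups retained along the allele
  still localise coverage gaps. Per-landmark constraints at the same $s$
  would discard many legitimate reads at Poisson troughs.
* **Additive tolerance.** The window is $\mu \pm s\sigma$ *per copy* with
  $s = 1.5$ by default; accuracy is insensitive to $s$ in the 1–2 range
  and to the landmark layout (4–8 groups/landmarks), so the defaults are
  safe for general use.
* **Discard penalty.** $P = 2 \cdot \text{max distance} + 1 = 51$:
  discarding is strictly worse than accepting any single candidate, so it
  only absorbs reads that no depth-feasible assignment can host — e.g.
  reads from uncatalogued paralogs, or flank-overhang reads with too
  little allele sequence to place.
* **$C_{\max} = 4$.** Higher amplifications are rare and inflate the
  model; the cap is configurable.

The solver backend is HiGHS through `scipy.optimize.milp` (single-threaded
and deterministic for a fixed model), bridged by a bundled Python script;
models are serialised as JSON sparse triplets and several models can be
solved in one interpreter invocation. `brute_force_solve()` enumerates
tiny instances exhaustively (ties broken toward lexicographically smaller
allele sets) and serves as the independent oracle in the tests — on
guarded random instances the two routes must agree exactly on the
objective. Co-optimal solutions are solver-dependent; nothing downstream
depends on which one is returned, and stability is measured explicitly by
the confidence metric.

## Confidence: prefix consistency

`near_optimal_solutions()` re-solves the model under an added constraint
forcing the objective to be at least 2 %, 4 %, 6 % and 8 % worse than the
optimum, each band independently minimised. An allele's *prefix
consistency* is the count of consecutive bands (starting after the
optimum) in which it remains present, stopping at the first absence: 0
means the allele is interchangeable with an alternative at essentially no
cost, 4 means it survives an 8 % objective degradation. When the optimal
objective is 0 a multiplicative bound collapses, so the band bound becomes
$\delta \cdot P \cdot |\text{reads}|$ — one discarded read sets the scale
of "one unit of worse". An infeasible band (the model cannot be made that
much worse) yields an empty present set, terminating the count.

`calibrate_thresholds()` scans thresholds per gene on truth-labelled
calls, reporting PPV, recall, passing proportion and
$F_\beta$ ($\beta = 0.5$, precision-weighted), with ties resolved to the
lower threshold. The recall denominator defaults to the gene's total
true-positive calls; a per-gene truth total can be supplied instead
(`recall_denominator = "truth_total"`), since either reading is defensible
and they differ only when true alleles are missed entirely.

## Mendelian concordance and benchmarking

`gene_concordance()` scores one gene: with two child copies, one copy's
allele must be in the mother's calls and the other's in the father's (in
either order); with more than two, some pair of distinct copies must be
explainable one from each parent; with one, the allele must be in at least
one parent; required-but-missing parental calls give `parent_missing`.
Note the two-copy rule makes a homozygous child discordant when only one
parent carries the allele — the literal one-from-each-parent reading —
which penalises genuine uniparental-looking CNV events; this is a
deliberate, conservative choice. The default trio denominator is
functional genes with at least one child call (genes deleted in the child
are untestable under these rules); a fixed gene set can be supplied for
small loci conventionally scored over all genes.

`presence_precision_recall()` defaults to copy-insensitive set semantics
because assembly-derived truth sets over-count copies on overlapping,
unphased contigs; multiset (CNV-sensitive) counting is available.
`annotate_contigs()` builds truth sets by exact (or bounded-mismatch,
indel-free) search of allele cores against contigs on both strands —
deterministic, which matters for reproducible truth sets; genuinely
diverged novel alleles will not match and are out of scope.

## The synthetic-data generator

`generate_locus()` emulates the statistical structure the method relies
on: one ancestor, genes diverged by point substitutions at rate 0.10,
alleles within a gene at 0.01, lengths 280–300 bp. Those defaults are the
study conditions: within-family identity of roughly 80–90 % reproduces the
cross-gene mapping ambiguity of real V-gene families, and ~98–99 %
within-gene identity mirrors real allele spacing of a few substitutions.
The mutation model is substitution-only by default (an indel option exists
at a reduced rate) — the ILP consumes edit distances, and substitutions
suffice to exercise the ambiguity the method must resolve.
`simulate_genotype()` draws per-gene copy numbers (default: always two,
one per haplotype), `simulate_trio()` inherits one copy per parent
uniformly and can inject a chosen number of non-Mendelian events,
`simulate_reads()` emits uniform-coverage reads and
`downsample_reads()` thins them binomially.

Read simulation places starts uniformly over the window
`core_start − read_length + 1 … core_end − 1` with a Poisson count of
`depth × (core + read_length − 1) / read_length` per copy, which makes the
expected depth at *every* core base equal to the nominal per-copy depth —
the assumption the depth-consistency constraints encode; template `N`
bases are emitted as random bases because the flank represents unknown
context, not literal `N`. A per-gene dropout option emulates the read
loss V(D)J rearrangement causes in B-cell-derived samples. What the
generator does **not** emulate: GC-dependent coverage bias, quality-score
error profiles, paired-end inserts, indel sequencing errors, and novel
alleles absent from the database. Passing tests therefore demonstrate the
machinery is correct under the model's own assumptions; accuracy on real
data is additionally limited by exactly those unmodelled features.

## Numerical and degenerate-input choices

* Edit-distance ties between strands go to the forward strand; only the
  best placement per (read, allele) is kept.
* Reads with no candidate within 25 edits are pre-discarded at cost $P$
  (constant objective offset) rather than entering the model.
* An empty candidate table short-circuits to an empty call set; an empty
  trio denominator yields `NA` concordance, never 1.0.
* Zero-depth sampled positions count toward the depth mean and SD;
  a zero mean is a hard error (nothing can be genotyped).
* All generators and the pipeline are pure functions of their seeds; the
  solver is deterministic for a fixed model, and batch solving preserves
  per-model independence.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise loci of 3–20 genes with
2–5 alleles each at 10–30× per-copy coverage (thousands of reads, ILPs up
to roughly 50,000 variables), solver-vs-oracle agreement on 100+ random
guarded instances (≤ 6 reads, 3 alleles, copy cap 2), and depth estimation
over a 20 kb synthetic pileup — sizes chosen so the full validation runs
comfortably on a single CPU while still producing ILPs whose relaxations
are non-trivial.

## Known limitations

* Copy phasing is not attempted; trio concordance consequently tests
  explainability, not full haplotype inheritance.
* Novel alleles are not discovered; reads from them are either absorbed
  by near neighbours or discarded.
* CRAM input should be converted to BAM first; orphon discovery against a
  real reference requires an external aligner's SAM.
* The exact constraint granularity of depth consistency (per landmark vs
  per group, bound vs objective term) admits variants; the group-mean
  bound used here keeps the model linear and small, and the parameter
  sweep machinery exists precisely to compare such variants.
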