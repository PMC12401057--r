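# vgenotyper

Germline genotyping of immune-receptor **variable (V) gene families** —
IGKV, IGLV, IGHV, TRAV, TRBV, TRGV, TRDV and similar multi-copy loci — from
short-read whole-genome sequencing.

These loci are among the most repetitive regions of the human genome: tens
of near-identical ~280–300 bp genes, each with several alleles differing by
a handful of substitutions, plus distant look-alike copies ("orphons")
elsewhere in the genome. Standard reference-based variant calling fails
here because most reads map ambiguously. `vgenotyper` resolves the
ambiguity globally with an integer linear program and reports per-gene
allele calls with copy numbers and a solution-stability confidence score.

## Method

Given reads recruited from the target locus and its orphon regions, every
read *r* is aligned end-to-end against every allele *a* of an IMGT-style
database (alleles padded with flanking `N`s so overhanging reads align at
no cost), giving candidate assignments with edit distances
*e*<sub>*ra*</sub>. The ILP chooses binary assignments
*x*<sub>*ra*</sub>, per-read discard indicators *d*<sub>*r*</sub>, and
per-allele copy numbers *c*<sub>*a*</sub> ∈ {0, …, C<sub>max</sub>} to

minimise  Σ *e*<sub>*ra*</sub> *x*<sub>*ra*</sub> + *P* Σ *d*<sub>*r*</sub>

subject to every read being assigned exactly once or discarded, reads only
going to called alleles, and a **depth-consistency constraint**: for every
called allele and every *landmark group* (6 groups of 6 uniformly spaced
positions per allele by default), the group-mean read coverage must lie
within *c*<sub>*a*</sub>(μ ± *s*σ), where μ and σ are the per-copy depth
mean and SD estimated from a background region and *s* (default 1.5) is
the tolerance in SD units. Discarding costs *P* (default 51, strictly
worse than any accepted assignment) and absorbs reads from uncatalogued
paralogs.

Call confidence is quantified by **prefix consistency**: the ILP is
re-solved under constraints forcing the objective ≥ 2 %, 4 %, 6 %, 8 %
worse than optimal, and each called allele is scored by the number of
consecutive bands in which it persists (0 = present only in the optimum,
4 = stable through all bands). Per-gene thresholds can be calibrated on
labelled data by maximising F<sub>β</sub> (β = 0.5, precision-weighted).

Validation machinery included: Mendelian trio concordance (per-gene
inheritance rules for 1, 2 and >2 child copies), allele-presence
precision/recall against truth sets, assembly-contig annotation by
exact/near-exact allele search, and a fully seeded synthetic-data
generator (locus, diploid-with-CNV genotypes, trios, error-bearing
uniform-coverage reads) so the entire pipeline is testable offline.

## Worked example

Simulate a six-gene locus, genotype it, and compare against the planted
truth:

```r
library(vgenotyper)

db     <- generate_locus(n_genes = 6, alleles_per_gene = 3, seed = 42)
padded <- pad_alleles(db, 150)                      # N-pad for clipped mapping
geno   <- simulate_genotype(db, seed = 43)          # diploid truth genotype
reads  <- simulate_reads(geno, padded, depth = 30, seed = 44)

res <- genotype_reads(reads, padded, depth_profile(30, sqrt(30)))
tidy(res)
#> # A tibble: 12 × 6
#>    gene_id allele_id copy_number n_assigned_reads mean_edit_distance
#>  1 SYNV1   SYNV1*01            1               79              0.481
#>  2 SYNV1   SYNV1*02            1               75              0.733
#>  3 SYNV2   SYNV2*01            1               81              0.506
#>  ...
#> # ℹ 1 more variable: prefix_consistency <int>

glance(res)
#> # A tibble: 1 × 8
#>   status  objective n_reads n_discarded n_calls n_genes mean_depth sd_depth
#> 1 optimal      4039    1089          69      12       6         30     5.48

presence_precision_recall(res$calls$allele_id, unique(geno$allele_id))
#> # A tibble: 1 × 2
#>   precision recall
#> 1         1      1
```

Every gene's two planted alleles are recovered (12 calls over 6 genes,
presence precision and recall both 1.0). The 69 discarded reads are
flank-overhang reads with too little allele sequence to place; the
objective is total edit distance plus discard penalties.
`autoplot(res)` draws the per-gene copy numbers shaded by prefix
consistency.

For real data, `genotype_bam()` runs the full pipeline from an indexed
BAM plus target/orphon BEDs, and `inst/cli/vgenotyper` exposes
`genotype`, `trio`, `simulate`, `discover-orphons` and `benchmark`
subcommands for shell use. `trio_concordance()`, `calibrate_thresholds()`
and `genotype_matrix()` cover downstream validation and association
export.

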