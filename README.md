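# karyoevo

Tools for reconstructing tumor clonal evolution from single-cell karyotypes
and matched binned copy-number profiles.

Spectral karyotyping (SKY) reports, for every metaphase cell, the copy
number of each chromosome and its structural rearrangements — nonreciprocal
translocations `t(a;b)`, reciprocal pairs `t(a;b)&t(b;a)`, fusions `f(a;b)`
and rings `ring(a;b)`. Because an NRT breakpoint is unique at the nucleotide
level, a shared NRT is a clonal marker. `karyoevo` is for researchers who
have such per-metaphase tables (plus, optionally, 10-kb binned log2
copy-ratio profiles from whole-genome sequencing) and want to reconstruct
how the tumor evolved: which cells form clones, where whole-genome
duplication (WGD) happened, in what order founder clones arose, and how they
seeded multiple anatomical sites.

## The methods at the core

* **WGD calling** — tumors with and without WGD separate bimodally at
  ploidy 2.5, i.e. 50 chromosomes in mouse; a cell with total count
  *n* ≥ 50 is post-WGD ("sub-4N").
* **Clonality and acquisition** — an event seen in > 50% of a sample's
  metaphases is clonal; a clonal NRT with two copies and two copies of each
  translocated chromosome in sub-4N cells was acquired before WGD
  (cNRT^2N), one copy with three participant copies after WGD (cNRT^4N).
  Any cNRT^2N marks the multifocal Type 2 evolution pattern, otherwise a
  cNRT^4N marks the single-mass Type 1 pattern.
* **Event-weighted distance** — between two cells
  `d = w_wgd·|wgd_a − wgd_b| + w_copy·Σ_chr|dev_a − dev_b| + Σ_events w(e)`,
  with weight 1 per chromosome gain/loss, 1 per fusion/ring/RT difference,
  1 for WGD (one genetic event) and 5 for de novo NRT acquisition; copies of
  pre-WGD events are ploidy-adjusted, so NRT-then-WGD scores 5 + 1 = 6, not
  10.
* **Neighbor joining** — classic Saitou–Nei agglomeration (deterministic
  tie-breaking, negative branch estimates clamped with the deficit moved to
  the sibling), rooted on a synthetic normal euploid `CONTROL` cell so that
  root-to-leaf path length equals accumulated event weight.
* **Founder clones** — maximal clades of identical canonical genotypes,
  ordered by genotype containment under two rules: WGD is irreversible, and
  genomes go from simple to complex.
* **Sharing null** — the probability that two metaphases from different
  animals share an NRT, `p = (n_d / n_r) / (n_a − 1)`, estimated by Monte
  Carlo over sampled metaphase pairs and validated against exhaustive
  enumeration.
* **CNV trees** — L1 distance `Σ_i |r_a^i − r_b^i|` over 10-kb bins for NJ
  trees of sequenced clones, and shared/private segment-event partitions
  (identical boundaries in ≥ 2 samples; whole-chromosome events excluded)
  for "manual" trees with trunk ∝ shared and branches ∝ private events.

A forward simulator (`simulateCase`) generates cohorts with known ground
truth — scripted founding NRT and WGD, drift rates for gains/losses and
structural events, multi-site seeding — and is what the test suite measures
the estimators against.

## Worked example

```r
library(karyoevo)

case <- simulateCase(simulationConfig(seed = 1))   # a Type 2 cohort
calls <- callClonalEvents(case$samples$SVZR)
calls[calls$clonal, c("notation", "n_carrying", "n_total", "acquisition")]
#>        notation n_carrying n_total acquisition
#> 1 t(4;7)@bp0001         10      12     CNRT_2N

classifyCaseType(case$samples)
#> [1] "TYPE_2"

cellsAll <- unlist(lapply(case$samples, cells), recursive = FALSE)
d  <- buildDistanceMatrix(cellsAll, scope = "M1")
tr <- rootWithOutgroup(neighborJoining(d))
lin <- orderFounderClones(identifyFounderClones(tr, cellsAll, scope = "M1"))
lin
#> CloneLineage: 23 FC(s), 5 ordered edge(s), 0 unresolved
```

The planted founding translocation `t(4;7)` is recovered as clonal in 10 of
12 SVZ metaphases and classified as acquired at the 2N stage (one copy in
near-2N cells, two copies in the sub-4N tumor cells), which makes the animal
a Type 2 case; the rooted NJ tree over all 24 cells then yields founder
clones ordered into a lineage. A thin command-line wrapper over the same
functions ships at `inst/cli/karyoevo.R` (subcommands `simulate`, `tree`,
`clones`, `sharing`, `cnv-tree`, `cnv-compare`, `cnv-events`, `fisher`,
`run`).

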