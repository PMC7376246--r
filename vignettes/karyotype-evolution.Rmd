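---
title: "Reconstructing tumor clonal evolution from single-cell karyotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tumor clonal evolution from single-cell karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoevo)
```

# The analysis problem

Spectral karyotyping (SKY) resolves, for every metaphase cell, the copy
number of each chromosome and the structural rearrangements it carries —
nonreciprocal translocations (NRTs, `t(a;b)`), reciprocal pairs
(`t(a;b)&t(b;a)`), fusions (`f(a;b)`) and ring chromosomes (`ring(a;b)`).
Because an NRT's breakpoint is unique at the nucleotide level, an NRT shared
by two cells is a clonal marker: both cells descend from the single cell in
which it arose. `karyoevo` turns a table of per-metaphase karyotypes into a
reconstruction of tumor clonal evolution: ploidy and whole-genome-duplication
(WGD) calls, clonality and acquisition classification of NRTs, event-weighted
neighbor-joining (NJ) trees rooted on a euploid ancestor, founder-clone
lineages with multi-site seeding patterns, a Monte-Carlo null for NRT sharing
across animals, and matched trees from binned whole-genome copy-number
profiles.

# The data model

A `MetaphaseKaryotype` holds one cell: a named count for each of the 21 mouse
chromosomes (chr1–19, X, Y) plus a list of `StructuralEvent`s. The total
chromosome count includes every counted body on the spread — intact
chromosomes and derivative chromosomes alike — because that is what is
counted under the microscope. Participant order in an event is preserved as
written (`t(2;4)` is not `t(4;2)`); two events are "the same" when kind and
ordered participants match, with an optional breakpoint tag overriding
notation-level identity. Untagged events are identified only within one
animal: independent recurrence of the same breakpoint in two animals is so
unlikely (that is what the sharing null quantifies) that cross-animal
identity requires sequence-level evidence, which the tag models.

Sex chromosomes default to the male baseline X = 1, Y = 1 and are
configurable.

# Ploidy and WGD

Tumor populations with and without WGD separate bimodally in chromosome
count around ploidy 2.5 — 50 chromosomes in mouse. `classifyPloidy()` calls
a cell `SUB_4N` when its total count is at least 50, `NEAR_2N` otherwise.
The boundary count itself is assigned to the WGD side: ploidy exactly 2.5
belongs to the upper mode of the bimodal split.

# Clonality and cNRT acquisition

An event is clonal in a sample when observed in strictly more than half of
its metaphases. For clonal NRTs (cNRTs) the package infers whether the NRT
was acquired before or after WGD from the copy pattern in post-WGD cells:

* acquired at the 2N stage and doubled along with the genome — two copies of
  the NRT with two copies of each translocated chromosome (`CNRT_2N`);
* acquired after WGD — one copy of the NRT with three copies of each
  translocated chromosome (`CNRT_4N`).

The classifier takes the modal NRT copy number and the modal
participant-chromosome count among sub-4N carriers; the `CNRT_4N` rule
accepts three *or more* participant copies, since a post-WGD acquisition in
an unlosses 4N background leaves four. When only near-2N carriers exist with
a single copy, the event is the one-copy pre-WGD state and also `CNRT_2N`.
Modal ties break toward `UNDETERMINED` rather than a guess — post-WGD losses
can erase the pattern, and the classifier must tolerate that honestly.

At the animal level, any `CNRT_2N` marks the multifocal two-phase evolution
pattern (`TYPE_2`); otherwise a `CNRT_4N` marks the single-mass pattern
(`TYPE_1`). This is the karyotype-based correlate only; radiographic growth
patterns are out of scope.

# The event-weighted distance

Every chromosomal event contributes its weight to the distance between two
cells: 1 per chromosome gain or loss, 1 per fusion/ring/reciprocal presence
difference, 1 for WGD (one genetic event, not 40 chromosome-level changes)
and 5 for the de novo acquisition of an NRT, whose unique breakpoint makes
it the strongest lineage marker. The distance is defined on canonical
profiles: the WGD flag; deviations of each chromosome count from the euploid
baseline, with the baseline doubled in WGD cells; and the event set with
ploidy-adjusted copies (an event present in two copies in a WGD cell is
inferred to predate the duplication and counts as one). Consequently a cell
that acquired an NRT and then doubled its genome sits at distance
5 + 1 = 6 from normal — not 10 — and a trisomy sits at 1.

```{r distance}
ctrl <- controlCell()
nrtThenWgd <- metaphaseKaryotype("w", "S", baselineCounts() * 2L,
                                 list(structuralEvent("NRT", c("2", "4"),
                                                      copies = 2L)))
pairDistance(ctrl, nrtThenWgd)
```

Two consequences of this definition are worth knowing. First, per-chromosome
differences between two aneuploid cells count as the absolute copy
difference, |Δ| (each unit gain or loss is one event); the alternative
reading — unit cost per differing chromosome regardless of magnitude — is
not used. Second, the triangle inequality is not guaranteed; NJ accepts
non-metric dissimilarities, and the implementation does not pretend
otherwise.

# Trees

`neighborJoining()` is a from-scratch implementation of the classic
Saitou–Nei agglomeration under the minimum-evolution principle, with two
numerical policies chosen for reproducibility: ties in the Q criterion break
toward the lexicographically lowest label pair (internal nodes inherit the
smallest leaf label of their subtree), and negative branch-length estimates
are clamped to zero with the deficit moved to the sibling edge so the pair's
joint length is preserved. Identical input therefore yields byte-identical
Newick output. The independent cross-checks in the test suite are an
exhaustive enumeration of all unrooted topologies on up to six leaves with
integer branch lengths (NJ must recover each exactly from its additive
matrix) and topological agreement with `ape::nj` on random matrices.

Rooting adds a synthetic euploid `CONTROL` cell (40 chromosomes, no events)
to the matrix and places the root on its pendant edge; the path length from
the root to any leaf is then the accumulated event weight of that cell, and
leaf-to-leaf path lengths are unchanged by rooting.

# Founder clones

A founder clone (FC) is the extrapolated ancestor of a maximal clade whose
members share an identical canonical genotype — the same structural-event
identity set, WGD state and per-chromosome deviations. A clone that merely
lost one more chromosome is a distinct clone: that is precisely the kind of
intermediate (an unobserved chromosome-loss-only founder) the lineage
reconstruction needs to expose. Because identical cells sit on zero-length
branches, NJ may arrange them as a paraphyletic grade; clades carrying the
same genotype signature are therefore merged into one FC. Singleton FCs are
reported but are low-confidence by nature; cohort-level summaries should
filter on member count.

Ordering uses the two rules of karyotype evolution: WGD is irreversible
(edges only run from near-2N to sub-4N genotypes, with the pre-WGD genotype
doubled before containment testing, and subsequent losses allowed), and
genomes move from simple to complex. Each FC's parent is the FC whose
genotype is the maximal proper subset of its own; when two incomparable
candidates tie, the parentage is recorded as unresolved rather than guessed,
because the original analyses resolved such cases by manual reasoning the
package should not imitate silently.

`inferSeedingPattern()` summarizes dispersal: a site whose cells trace to
more than one FC shows polyclonal seeding; an FC whose descendants occupy
more than one site shows parallel seeding.

# The inter-lineage sharing null

To quantify how unlikely it is that two cells from *different* animals share
an NRT, `estimateInterlineageP()` samples unordered pairs of distinct
metaphases uniformly with replacement from the pooled cohort (self-pairs
excluded; the sampling scheme is the simplest one consistent with a fixed
pair budget) and computes

$$p = \frac{n_d}{n_r}\cdot\frac{1}{n_a - 1}$$

where $n_r$ pairs share at least one NRT, $n_d$ of those cross animals and
$n_a$ animals are pooled; the factor $1/(n_a-1)$ normalizes for
inter-lineage pairs being $(n_a-1)$ times as likely as intra-lineage pairs.
`exactInterlineageP()` enumerates all pairs instead and is the reference the
estimate converges to. The cohort-scale headline value of this statistic
requires the original several-hundred-metaphase dataset, which is not
distributable; the package validates the estimator against exhaustive
enumeration on synthetic cohorts instead.

# Binned copy-number profiles

`CNVProfile` wraps a `GRanges` of fixed-width bins (10 kb by default,
0-based half-open in files) with a `log2Ratio` column, read from either the
package's native bin table or a Control-FREEC-style ratio file (linear
ratios converted to log2). Three analyses consume it:

* **SKY/WGS cross-validation** — the SKY side estimates each chromosome as
  `log2(ci / median(c))` with the median over chromosomes 1–19 and X
  (chromosome Y excluded; median normalization cancels ploidy); the WGS side
  is the per-chromosome median of bin values; `compareSkyWgs()` reports the
  Pearson correlation over shared chromosomes.
* **L1 clone trees** — the distance between two profiles is the summed
  absolute per-bin log2 difference (a true metric, property-tested), fed to
  the same NJ machinery with an all-zero normal outgroup.
* **Shared/private segment trees** — contiguous runs of bins beyond
  ±0.3 log2 become segment events (the threshold is a package default, as
  upstream callers do not expose theirs; it is configurable); events with
  identical boundaries and direction in at least two samples are shared,
  whole-chromosome events (≥95% of the chromosome's binned length, the 5%
  slack absorbing terminal-bin artifacts) are excluded as nonspecific; the
  "manual" tree has trunk length proportional to shared and branch lengths
  to private event counts.

# The synthetic-data generator

`simulateCase()` is a forward simulator, not a fixture: cells divide
synchronously once per generation from a single normal founder; each
daughter may gain or lose single chromosomes (default 0.02 per chromosome
per generation), acquire an NRT (0.01 per generation, each with a globally
unique breakpoint tag), a fusion (0.005) or a ring (0.003); WGD happens at
most once per lineage and doubles every chromosome and derivative, followed
by a random loss burst of intact chromosomes down to a target of 60–80
total bodies — the count range characteristic of sub-4N tumor populations.
Derivative copies are lost only through the ongoing per-generation loss
rate, which is what creates the `UNDETERMINED` acquisition cases the
classifier must tolerate. No field-measured per-generation rates exist;
the defaults are deliberately modest drift rates chosen once to reproduce
the qualitative cohort structure (dominant clonal NRTs, a minority of
private events per cell) and are not calibrated to any quantitative target.

The two scenarios script the founding events. `TYPE2` plants one NRT in
generation 1 and a WGD in one NRT-bearing lineage a third of the way
through, then samples an SVZ site as an 80/20 mixture of near-2N
NRT-bearing and normal cells and parenchymal sites from the post-WGD pool —
so the founding NRT appears with one copy in near-2N and two copies in
sub-4N cells, exactly the pattern the acquisition classifier keys on.
`TYPE1` plants the WGD first and the NRT after it. Seeding modes control
whether tumor sites draw from one post-WGD sister lineage (`PARALLEL`),
both (`POLYCLONAL`), or a mixture (`MIXED`). NRT formation consumes one
copy of each participant chromosome, which is what produces the printed
two-copies-with-two-partners and one-copy-with-three-partners patterns.

Every sampled cell carries a replayable event ledger; replaying it from the
normal founder reproduces the cell's counts exactly, and the true genealogy
over the sampled cells is returned as a `phylo` with branch lengths in
weighted events. `karyotypeToBins()` converts a karyotype to a binned
profile using the same median normalization as the SKY-side estimate (so
noiseless matched data correlate perfectly by construction), with optional
Gaussian bin noise and focal overlays for emulating early driver deletions.
Two caveats about realism: derivative chromosomes are not redistributed
onto their participants in the binned profile, and the generator models no
selection, no spatial structure and no breakpoint sequence — so passing
tests demonstrate that the estimators recover what the generative model
plants, not that real tumors satisfy the model.

A note on ground truth for tree depth: the ledger weights events in
"paper" units (an NRT is 5 regardless of the copy changes it causes),
while the karyotype a tree is built from also shows the participant copies
the translocation consumed. Tree-depth fidelity is therefore tested against
an independent brute-force distance to the euploid ancestor — the
accumulated event weight as expressed in the observable karyotype — rather
than against raw ledger sums, which conflate the two unit systems.

# Statistics

`fisherExact2x2()` computes the two-sided Fisher exact test by direct
hypergeometric enumeration, summing the probabilities of all tables (fixed
margins) no more probable than the observed one — the "probability mass ≤
observed" convention, matching common implementations; the test suite
verifies equality with `stats::fisher.test` on every 2×2 table with total at
most 30. No multiple-testing correction is applied by default (raw p-values
are the reporting convention for these small cohorts); Holm adjustment is
available behind a flag in `proportionReport()`.

# Problem sizes and determinism

The test and validation runs use cohorts of 2–3 sites with 12–14 metaphases
each from 9 synchronous generations (512 final cells), 25–50 simulator
seeds per property, 10⁵ sampled pairs for the sharing null, and reduced
chromosome sizes (about 1/100 of the mouse genome, a few thousand 10-kb
bins) for binned profiles — sizes chosen so the full suite exercises every
code path at cohort-like scale while remaining quick to run. All randomness
flows from explicit seeds; identical inputs and seeds give byte-identical
trees, exports and reports.

# Known limitations

* Event identity without breakpoint tags is notation-level and
  animal-scoped; genuinely distinct NRTs between the same chromosome pair
  within one animal are conflated unless tags are supplied.
* The distance treats structural events as presence/absence plus copy
  differences; it does not model breakpoint positions, and the triangle
  inequality can fail.
* Founder-clone identification requires exact genotype identity; heavily
  drifted clones fragment into singletons rather than clustering fuzzily.
* The human karyotype is not supported; the chromosome universe is the
  21-label mouse set.
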