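---
title: "Methods: Y-chromosome lineage analysis with ylineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-chromosome lineage analysis with ylineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

# Scope

`ylineage` implements the computational stages of a Y-chromosome lineage
study of the kind used to characterise Native American haplogroup Q-M3
sublineages: candidate SNP discovery filtering, hierarchical haplogroup
classification, weighted median-joining Y-STR networks, rho-statistic
TMRCA dating, hierarchical AMOVA and multiple correspondence analysis.
Because studies of this kind rarely deposit machine-readable per-sample
genotypes, the package also contains a first-class synthetic-data module
that generates cohorts with the statistical structure the analyses
assume, so every stage can be exercised and validated end to end. The
`analysis/` scripts in the repository run the whole sequence over one
synthetic cohort.

# The synthetic cohort generator

## Mutation model

Y-STR loci evolve under the symmetric single-step stepwise mutation model
(SMM): along a lineage of length $T$ generations each locus accumulates a
$\mathrm{Poisson}(\mu T)$ number of mutation events, each changing the
repeat count by $\pm 1$ with probability $1/2$. The SMM is the standard
assumption behind step-counting haplotype networks and rho dating; the
default rate is the evolutionary calibration $\mu = 6.9\times10^{-4}$ per
locus per 25-year generation. Repeat counts are floored at 1 (a reflecting
bound that is unreachable in practice from the default ancestral allele of
14 repeats at realistic $\mu T$).

Two checks pin the generator to this law: the mean absolute per-locus
displacement matches its exact compound-Poisson expectation over
replicates, and a chi-square goodness-of-fit test accepts the
negative/zero/positive displacement frequencies.

## Genealogies

* **Star genealogy** — all $n$ lineages descend independently from one
  founder $T$ generations ago. This is the default for dating tests
  because the rho standard deviation used here,
  $\sigma = \sqrt{\rho/n}$, assumes a star-like expansion.
* **Two-level hierarchy** — populations nested in groups.
  `divergence_generations = c(a, b)` are the *shared drift times* along
  the group-ancestor and population-ancestor branches; each sample then
  evolves independently for the residual $T - a - b$ generations. This
  parametrisation makes the limits transparent: `c(0, 0)` gives fully
  exchangeable haplotypes; `a ≈ T, b = 0` puts all variance among groups;
  $a > b$ makes the among-group variance component dominate the
  among-population one, which the tests verify by majority vote over
  replicates.

## SNP placement

SNP markers of a haplogroup tree are placed once on genealogy branches
(infinite sites). The branch for a child node is always a descendant of
its parent node's branch, and branches assigned to sibling nodes are
mutually disjoint (no ancestor–descendant relation), because sibling
haplogroups are disjoint clades. Branches are drawn with probability
proportional to their clade size, so markers get realistic carrier
frequencies (uniform sampling almost always lands on single-sample leaf
branches in a cohort-sized genealogy); a parent's own branch is a
candidate for one child, which reproduces spine markers carried by the
whole sample and sibling branches with null frequency. When a node's clade cannot be placed
disjointly (e.g. the genealogy is too shallow below the parent's branch),
the node's markers are emitted with zero derived carriers rather than
breaking the hierarchy. These two rules make derived-carrier sets
perfectly nested, so the classifier must recover the deepest planted node
with zero conflicts — the placement-inversion test.

What the generator does **not** emulate: genotyping failure patterns
(missingness is available in file formats but not simulated), homoplasy
on SNPs (infinite sites), STR mutation-rate heterogeneity across loci,
multi-step STR mutations, and population growth/migration within groups.
Passing tests therefore demonstrate correctness of the estimators under
the stated models, not robustness to those real-data complications.

# Discovery filtering

A candidate survives when it (i) is an SNV, (ii) is absent from the
known-variant catalog, (iii) lies outside repeat-masked regions, (iv) has
no other variant within half the field-of-view window on either side, and
(v) is a transversion. Decisions taken where the procedure was
underspecified:

* The "3000-nucleotide field of view" is read as a **total** window of
  3000 nt centred on the variant (±1500 nt per side), configurable via
  `filter_config(window_nt=)`.
* Proximity is judged against the **full input list**, including variants
  rejected by other rules — what a curator sees in a browser field of
  view. With that convention, re-filtering the kept set is idempotent.
* Catalog membership is by (chromosome, position) only; allele-aware
  matching is a flag (`allele_aware_known`).
* Coordinates: VCF positions are 1-based; the BED mask is 0-based
  half-open; all internal arithmetic is 1-based inclusive.

# Haplogroup classification

The packaged Q-M3 tree is data (`inst/extdata/qm3_tree.yaml`), not code;
alternative trees are drop-in files. The spine
Q-M242 → Q-L56 → Q-M346 → Q-L54 → Q-M3 → Q-M848 and the placement of
Q-Z780/Q-CTS11780 as the sibling branch follow the published marker
hierarchy; the branch order among the shallow CO sublineages is read from
a figure and is encoded as two age-ordered clades — the tree file
documents this and is easy to amend.

Classification descends from the root through derived nodes and reports
the deepest one. The default missing-data policy is **strict** (descent
stops at the first untyped node) because allele-specific PCR failures
should not promote a sample down-tree; `permissive` continues through a
missing node when a deeper derived node exists. Multi-marker
(phyloequivalent) nodes require any typed marker derived and none
ancestral; disagreement is reported as a conflict, as is any sample
derived below an explicitly ancestral node. Percentages in frequency
tables round half-up to one decimal, the convention of published
frequency tables (153 of 231 prints as 66.2).

# Median-joining networks

Distances are weighted L1 on repeat counts — the weighted number of
single-repeat steps. The construction collapses identical haplotypes,
forms the minimum spanning network (union of all minimum spanning trees,
relaxed by `epsilon`), adds quasi-median (coordinate-wise median) vectors
of triplets formed by a network link plus a third node whenever the
median shortens the local three-point connection (the cheapest medians
within `epsilon` are added each round), and finally removes obsolete
median vectors (inferred nodes of degree ≤ 2 whose removal does not
lengthen the minimum spanning tree).

Numerical choices: locus weights are integers proportional to inverse
allele variance, scaled so the most variable locus has weight 1 and
clamped to [1, 99] (the convention of network-software weight fields) —
the exact published weighting constants behind this scheme are not
reproduced anywhere accessible, so the clamped inverse-variance rule is a
documented stand-in, and `scheme = "uniform"` disables it. Ties in node
processing are broken by lexicographic order of haplotype vectors, so
construction is deterministic. DYS385a/b are accepted in input but
excluded from all distance computations, matching standard practice for
duplicated loci.

# Rho dating

The ancestral haplotype is the per-locus modal allele (ties to the
smallest allele, for determinism). $\rho$ is the mean unweighted step
count from each carrier to the ancestor; steps are unweighted even when
the network uses variance weights, because rho counts mutations rather
than weighted lengths. $\sigma = \sqrt{\rho/n}$ is the star-genealogy
approximation; the tree-based variance is out of scope because per-SNP
genealogies are not available. Conversion:
$\mathrm{TMRCA} = \rho / (L\mu) \times g$ years with $L = 15$ loci by
default (the 17-plex minus DYS385a/b) and $g = 25$ years. Only the EMR
calibration ships with a numeric value; OMRS/OMRB/OMRG are named presets
that require an explicit rate, since no packaged number exists for them.
Sublineages are dated over **all** derived carriers of each SNP; a
single-carrier sublineage dates to $\rho = 0$ and is flagged
low-confidence rather than erroring.

On star simulations with $\mu T \le 0.02$ per locus the estimator's
relative bias stays within a few percent (modal-ancestral inference and
step cancellation are the two bias sources; both are second order in
$\mu T$), which the recovery tests check at 10% and the acceptance
simulation at 5%.

# AMOVA

The two-level decomposition partitions variance among groups (Va), among
populations within groups (Vb) and within populations (Vc) from the
pairwise squared-distance matrix, using the standard expected-mean-square
coefficients for unbalanced designs. The default metric is the pairwise
number of differing loci; an R_ST-style squared repeat-size difference is
a flag — published tables rarely state which metric produced them, so
both are available. Negative components are reported unmodified (they are
legitimate method-of-moments estimates), percentages always total 100
within rounding, and degrees of freedom total $n-1$. Significance uses
seeded permutations (default 9999): populations among groups for Va,
samples among populations within groups for Vb, and samples among
populations over the whole dataset for the Phi_ST context. With one
population per group the decomposition collapses to one level (Vb ≡ 0);
with a single group, Va is undefined and a one-level AMOVA is reported.

# MCA

Multiple correspondence analysis uses the **indicator** matrix (not the
Burt matrix): 0/1 columns over (marker × state) categories, with missing
`"."` as its own category, correspondence-analysis scaling, and a singular
value decomposition. Inertia percentages are raw (Benzécri-uncorrected)
by default, with `benzecri = TRUE` available, since published cumulative
percentages often do not state the convention. Supplementary labels
(e.g. sample origin) are projected onto the axes by the CA transition
formula without influencing them. Constant markers are excluded with a
warning; a fully constant table returns zero inertia rather than an
error.

# Problem sizes and seeds

All randomness flows through explicit integer seeds; there is no hidden
global state, and identical seeds give byte-identical outputs (provenance
headers deliberately carry no timestamp). The shipped analysis scripts
use a 231-sample cohort (the size of a realistic regional study), an
80-haplotype subsample for the network stage (the quasi-median search
grows quickly with distinct haplotypes), 999 AMOVA permutations, and
200 replicates of n = 500 star genealogies for the dating-recovery
simulation — sizes chosen so each stage completes in seconds to a couple
of minutes on a single core while keeping Monte-Carlo error well inside
the tolerances the tests assert.

# Known limitations

* The packaged tree's CO-sublineage branch order is approximate (figure
  provenance); classification results at those depths depend on it.
* Rho dating assumes a star genealogy for its SD and is biased for
  strongly structured clades; the nested-sublineage test checks ordering,
  not calibration, in that regime.
* The discovery stage does not call variants or assess coverage
  uniformity; it filters an existing candidate list.
* The AMOVA permutation engine recomputes components from the fixed
  distance matrix; it does not handle covariates or more than two levels.
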