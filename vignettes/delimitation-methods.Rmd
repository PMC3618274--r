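---
title: "Species delimitation with motudelim: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species delimitation with motudelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motudelim)
```

Single-locus species delimitation asks whether a set of candidate groups
(MOTUs) behaves like separate species in the data at hand.  No single
statistic settles that question, so this package implements an ensemble —
distance-based barcode-gap methods, tree-topology statistics and the
mixed Yule-coalescent model — plus a consensus counter that turns their
individual verdicts into a defensible range of species counts.  This
vignette records the models as implemented, the conventions chosen where
the literature is silent, and what the shipped validation does and does
not demonstrate.

## Distances

`dist_matrix()` computes uncorrected p-distances and Kimura 2-parameter
distances from per-pair transition (P) and transversion (Q) proportions,

$$d_{K2P} = -\tfrac12\,\log(1 - 2P - Q) - \tfrac14\,\log(1 - 2Q),$$

over *comparable* sites: both residues in `A,C,G,T`.  Gaps, `?` and
IUPAC ambiguity codes are never counted as differences.  Two deletion
policies are offered; the package default for gap analyses is pairwise
deletion, so that indel-rich loci do not erase signal in clean ones —
complete deletion remains available and is what one would quote for
distance-matrix tree building.  When `1 - 2P - Q \le 0` or
`1 - 2Q \le 0` the pair is *saturated*: the entry is `NA` and summaries
exclude it with a warning.  Clamping would silently bias means, so it is
not done.

Standard errors of group-level mean distances
(`group_distance_summary()`) come from a bootstrap over alignment
columns, 500 replicates by default, with distances recomputed on each
resample; this is the convention of the classical distance software that
reports such tables.  Groups with one member have no within-group
distance and report `n/c`.

## Barcode-gap analysis and threshold rules

The overall analysis (OGA) compares a focal group's within-distances to
its distances against the amalgam of all other sequences; the pairwise
analysis (PGA) restricts the comparison to one named partner, which
additionally identifies the group *responsible* for a missing gap.  The
gap criterion is strict separation of ranges,
`min(inter) > max(intra)`, and the gap range is their difference.

The four decision rules are scored from three statistics:

| rule | supported when | default |
|------|----------------|---------|
| fixed 3% | `mean(intra) < 0.03` and `min(inter) ≥ 0.03` | — |
| fixed 4% | the same at 0.04 | — |
| 10× | `mean(inter) ≥ 10 · mean(intra)` | — |
| 3.2–4.1× | `mean(inter) ≥ 3.2 · mean(intra)`, flagged *strong* at ≥ 4.1× | decision bound 3.2 |

Two conventions deserve comment.  First, the fixed rules test the
*mean* within-group divergence against the threshold (not the maximum):
this is the only reading under which a group whose maximum intra
exceeds 4% but whose mean (3.3%) does not can still score `+` at the 4%
threshold while failing the 3% one — the calibration pattern the
acceptance tests pin down.  Second, the 3.2–4.1× rule is a band, and the
literature proposing it never states which bound decides; the liberal
bound (3.2) decides here and the conservative one (4.1) sets the
*strong* flag.  Singleton groups have no within-group distances: every
rule returns `na` and the gap verdict rests on the inter distances alone.

## ABGD-style partitioning

`detect_barcode_gap()` scans the sorted pairwise distances $d_{(1)} \le
\dots \le d_{(m)}$ for the first index $i$ with

$$d_{(i+1)} - d_{(i)} > X \cdot \theta_i, \qquad
  \theta_i = \max\{P,\ \text{mean}(d_{(1..i)})\},$$

considering only candidates with $d_{(i+1)} \ge P$ (distances wholly
below the prior are intraspecific by assumption).  The partition is the
set of single-linkage components below the detected gap, re-applied
recursively within components.  Priors run over a log-spaced series from
`p_min` = 0.001 to `p_max` = 0.1 in 10 steps.

The relative gap width defaults to `X = 1.5`, the reference
implementation's default.  Values around 15 are sometimes quoted, but at
COI-typical scales they make the criterion unsatisfiable — a gap of
width ~0.12 can never exceed `15 · θ` when `θ` is floored at priors up to
0.1 — and the tests demonstrate exactly that (no gap is ever detected at
`X = 15` on realistic data).  Both values are exercised in the test
suite.

Because the largest priors sit near the gap scale itself, they
legitimately detect nothing even on cleanly separated data; ABGD output
is therefore summarised, as is customary, by the partition that stays
*stable* across the prior series (`abgd_stable_count()`, the modal
primary group count).

## Tree-topology statistics

**GSI.**  For a group of $n$ tips, the raw statistic is
$GS = n / \sum_{u \in U}(c_u - 1)$ over the internal nodes $U$ of the
spanning subtree connecting the group's tips up to and including their
MRCA, where $c_u$ is the child count (so polytomies contribute their
true degree).  $GS$ is normalised between its monophyly value
$n/(n-1)$ — which any monophyletic configuration attains regardless of
tree shape — and its minimum $n/\sum_{\text{all } u}(c_u-1)$ on the
actual tree, making the index tree-shape aware.  The p-value permutes
group labels over all tips with the add-one estimator
$(1 + \#\{gsi^\ast \ge gsi\})/(1 + n_{perm})$, 10,000 permutations by
default.  Because the statistic is discrete, the permutation p-value is
*super-uniform* (valid but slightly conservative) rather than exactly
uniform; the test suite checks validity at several cutoffs rather than a
continuity-based goodness-of-fit.  Multiple tests are corrected with
Holm's step-down procedure (`sequential_bonferroni()`).

**Rosenberg's P_AB.**  Under the null that all $a + b$ tips coalesce
with every join sequence equally likely, the probability of reciprocal
monophyly counts the labelled histories in which all within-group joins
precede the final one:

$$P_{AB} = \frac{2\, a!\, b!\, (a+b-2)!}{(a+b)!\, (a+b-1)!}.$$

The package derives this closed form and verifies it against an
independent memoised recursion over join sequences for every
$a + b \le 8$ (e.g. $P_{2,2} = 1/9$).

**Rodrigo's P(RD).**  The distinctiveness ratio is crown depth (mean
path from the clade node to its tips) over stem length.  The exact null
of the original plugin is not recoverable from its description, so the
package declares its own: ratios of all same-size, non-root clades
pooled from `n_sim` neutral coalescent trees of the same tip count, with
a lower-tail add-one p-value (small ratio = distinct).  A zero-length
stem gives an infinite ratio and p = 1.

**SDP summary.**  Intra and Inter are mean patristic distances (within
the focal group, and to the closest partner group).  P ID(Strict) is
implemented as a leave-one-out nearest-neighbour criterion — a focal
member is correctly identified when its nearest tip by patristic
distance is a group-mate, ties counting as failure — with a Wilson 95%
interval.  This is an operational stand-in for the plugin's unpublished
formula and is documented as an approximation.

## GMYC

Trees must arrive ultrametric; `prepare_ultrametric()` only resolves
polytomies (deterministically, with zero-length branches) and verifies
ultrametricity — rate smoothing is deliberately out of scope.  Exact
age ties, which zero-length branches create, are broken by a
deterministic epsilon of $10^{-8}$ × tree height applied parent-first.

The likelihood is an inhomogeneous pure-birth process on the inter-node
intervals.  Order the $n-1$ branching times from root to present; the
root event is conditioned on, and each remaining event is paired with
the interval on its *younger* side, so a cluster's deepest coalescence
is evaluated while its two daughter lineages coexist and always has a
positive rate.  Interval $i$ of length $x_i$ contributes
$\log b_i - b_i x_i$ with the total rate

$$b_i = \lambda_{div}\, A_i^{\,p_{div}}
      + \lambda_{coal} \sum_j \bigl(c_{ij}(c_{ij}-1)\bigr)^{p_{coal}},$$

where $A_i$ counts lineages of the diversification class and $c_{ij}$
the lineages of within-species cluster $j$ crossing the interval.  The
total rate appears in the log term for *every* model — null, single- and
multiple-threshold — so their likelihoods are directly comparable; the
event times alone are the data, and which process produced an event is
not treated as an observed mark.  The null model is the special case of
a single class spanning the whole tree.

The threshold is profiled over observed node ages (standard practice;
no continuous optimisation), and the no-transition configuration is
included among the candidates, which makes the null exactly nested and
the likelihood-ratio statistic non-negative by construction.  For each
candidate, $(\lambda_{div}, p_{div}, \lambda_{coal}, p_{coal})$ are
optimised jointly (log-scale rate multipliers; exponents bounded in
$[10^{-6}, 2]$; L-BFGS-B from a data-driven start and from the unit
start).  The LR test against the null uses df = 3 for the
single-threshold model — the choice that reproduces the classical
published p-values from their LR statistics, anchored in the acceptance
tests via `gmyc_lr_pvalue(40.7, 3)` ≈ 7.5×10⁻⁹.

The multiple-threshold model is fitted by greedy forward refinement:
starting from the best single-threshold configuration, every move that
splits one existing cluster at a younger node age inside it is scored by
AIC (parameter count 4 + number of thresholds), and the search stops
when AIC no longer improves or `max_thresholds` is reached.  Different
clades may therefore transition at different ages.  Like other
multiple-threshold implementations it can over-split when within-species
rate variation mimics extra transitions; its df is configurable because
no canonical value exists.

Entities are the maximal subtrees whose root age lies at or below the
threshold (clusters) plus the tips hanging directly from diversification
branches (singletons).

## Consensus counting

`count_species_range()` enumerates every tiling of a scope (a nominal
species, or the genus) by pairwise-disjoint, collectively-exhaustive
hypotheses.  Nesting makes a parent and its children mutually exclusive
alternatives, which is what produces ranges such as "7 or 8".  Three
conventions:

* a hypothesis scored `+` counts one species; `-` is unusable;
* a hypothesis scored `na` (the method cannot assess it — typically a
  singleton MOTU under distance-based rules) may *cover* its ids inside
  a tiling but contributes zero to the count.  This matches how
  published consensus tables treat untestable singletons: present in the
  taxonomy, absent from the method's species total;
* a column whose usable hypotheses include no `+` at all is refused —
  a count of zero species over a non-empty scope is meaningless.

Composite hypotheses (a clade that absorbs haplotypes from a
neighbouring group, declared as an alias) are alternatives to their
components, never combinable with an overlapping parent.  One known
consequence: a method that simultaneously supports a parent group and an
overlapping composite admits no disjoint tiling, and the enumerator says
so rather than guessing — strict tiling cannot reproduce every count one
finds in published tables whose hypothesis families overlap.

## The synthetic-data generator

`sim_config()` defaults define the regime the validation runs in:

| parameter | default | meaning |
|-----------|---------|---------|
| `K`, `n_k` | 7; (26, 1, 12, 6, 12, 6, 19) | species and sample sizes, including a singleton |
| `species_depth_range` | (0.07, 0.105) subst./site | species-tree node heights, i.e. between-species divergence 14–21% |
| `pop_scale` | 0.00175 subst./site | within-species coalescent scale; expected within divergence ≈ 0.35%, expected between/within depth ratio 20 |
| `seq_length`, `kappa` | 600 bp; 4 | COI-like locus under a two-parameter substitution process |
| `indel_blocks`, `indel_length` | 1; 3 | per-species diagnostic indel blocks for the rDNA-like locus |

The species tree is a Yule draw whose internal node heights are mapped
linearly into `species_depth_range`, so *every* between-species split is
deep — emulating data in which the groups of interest are long-isolated
lineages.  Within-species coalescents are grafted at the species tips on
the population scale, capped (with a warning) at 90% of the available
stem in the rare draw that would not fit.  Sample sizes, the singleton
group, the divergence band and the shallow/deep contrast mirror a deeply
structured land-snail barcoding study; the depth-ratio-20 default is the
regime in which threshold-based delimitation is expected to work, and
the recovery tests quantify that it does (each of ABGD, single-threshold
GMYC and OGA recovers K = 7 in at least 90% of 50 seeded replicates).

What the generator does *not* emulate: gene-tree/species-tree discordance
(each dataset has one genealogy; no incomplete lineage sorting across
species boundaries, no migration), rate variation among sites or
lineages, alignment error, and realistic indel evolution (diagnostic
indels are injected post hoc at known columns).  Passing the recovery
tests therefore shows the methods work when their assumptions hold, not
that they are robust to violations of them.  Empirical trees also arrive
with inference error the truth trees here lack.

## Problem sizes in the shipped validation

The test suite runs the recovery experiment on 50 replicates of the
default 7-species configuration (82 tips, 600 bp) and the size check of
the GMYC LR test on 200 single-population coalescent trees of 50 tips —
sizes at which the full suite completes in a few minutes on one core
while keeping the Monte-Carlo error of the checked proportions small
(binomial SE ≈ 1.5–4%).  The permutation and simulation defaults exposed
to users (10,000 GSI permutations, 1,000 P(RD) null trees, 500 bootstrap
replicates) are the field's customary reporting standards; tests use
smaller, seeded values of the same machinery.

## Known limitations

* The GMYC ultrametricity requirement is checked, not repaired: trees
  dated elsewhere (or simulated) are the expected input.
* P ID(Strict) and the P(RD) null are declared operational definitions,
  not reverse-engineered reproductions of closed-source plugins.
* The ABGD gap rule is the deterministic rule stated above, chosen for
  reproducibility; it shares the reference method's inputs and defaults
  but is not a line-for-line port, and very small priors over-split by
  design.
* Consensus tiling is exact but strict: overlapping hypothesis families
  must be expressed as aliases, and scopes that no supported hypothesis
  set can tile raise errors instead of returning a guess.
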