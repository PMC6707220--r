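---
title: "Molecular timing and chronological reconstruction of myeloma genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular timing and chronological reconstruction of myeloma genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmchron)
```

## The problem

Multiple myeloma genomes accumulate chromosomal gains (most prominently the
trisomies of hyperdiploidy), structural variants and point mutations over
years of preclinical and post-diagnosis evolution. A single biopsy cannot
observe that history directly, but copy-number gains leave a datable
fingerprint: every point mutation already present on an allele when that
allele is duplicated is duplicated with it. Late gains therefore carry many
duplicated ("two-of-three-copy") clonal mutations; early gains carry few.
mmchron implements the full chain of inference built on this idea —
mutation-multiplicity timing of gains, subclone reconstruction, structural
variant timing, cohort-level ordering of lesions, and dependency analysis
of driver events — together with a forward simulator that generates data
with known ground truth in the pipeline's own input formats.

## The timing model

Mutations accrue on each allele copy as a Poisson process with a constant
clonal rate $r$ per copy per unit *molecular time* — a relative clock that
runs from 0 (fertilized egg) to 1 (emergence of the most recent common
ancestor of the tumor). A gain at molecular time $T$ duplicates every
mutation already on the gained copy. With `CN`$_m$ denoting the count of
clonal mutations on $m$ copies, the expected class counts are linear in the
gain times:

| state | expectations |
|---|---|
| trisomy 2:1 | $E[CN2] = rT$, $E[CN1] = r(3 - 2T)$ |
| CN-LOH 2:0 | $E[CN2] = rT$, $E[CN1] = 2r(1 - T)$ |
| 3:1 | $E[CN3] = rT_1$, $E[CN2] = r(T_2 - T_1)$, $E[CN1] = r(4 - T_1 - 2T_2)$ |
| 4:1 | $E[CN4] = rT_1$, $E[CN3] = r(T_2{-}T_1)$, $E[CN2] = r(T_3{-}T_2)$, $E[CN1] = r(5 - T_1 - T_2 - 2T_3)$ |

Inverting these gives the estimators in `time_trisomy()`, `time_cnloh()`
and `time_multigain()`. Each is exact when fed the expected counts (the
test suite checks this on a grid of planted times), and each weighted total
$\sum_m m\,E[CN_m]$ equals (number of final copies) $\times\ r$ — a
bookkeeping identity the simulator is also tested against.

Two formula choices deserve comment:

* **Trisomy.** The estimator is written as
  $T = 3\,CN2 / (2\,CN2 + CN1)$, the algebraic resolution of
  $CN2/(CN2 + (CN1 - CN2)/3)$ that is unbiased under the model above.
* **CN-LOH.** A commonly quoted form, $CN2/((CN2+CN1)/2)$, evaluates to 2
  rather than 1 when every lineage mutation is duplicated, because its
  denominator omits the doubled post-event accrual on the two retained
  copies. The default here is the model-consistent
  $T = 2\,CN2/(2\,CN2 + CN1)$; the alternative remains available via
  `time_cnloh(counts, mode = "as-printed")` for comparability.

For states with several extra copies the package assumes a *chain lineage*:
each subsequent duplication copies a descendant of the previously
duplicated copy. This is the only lineage under which the 3:1 and 4:1
estimators above are exact, and the simulator implements the same lineage,
so forward and inverse models agree by construction.

Multi-gain states acquired in a *single* event (e.g. a tetrasomy) show no
intermediate multiplicity cluster; `single_vs_sequential()` calls a state
"single" when intermediate classes are consistent with misassignment noise
(below `max(3, 0.02 n)` mutations by default).

## From reads to multiplicity classes

`compute_cvaf()` converts a raw variant allele fraction into the fraction
of tumor allele copies carrying the mutation,
$\mathrm{cVAF} = \mathrm{VAF}\,(\rho\,C + 2(1-\rho))/(\rho\,C)$ for purity
$\rho$ and local total copy number $C$; it is the exact inverse of the
simulator's read model. `assign_multiplicity()` fits a mixture whose
component locations are *fixed* at $m/C$ — only weights (and, in the
Gaussian mode, a shared dispersion) are free. The default likelihood is
binomial at the observed depth, which keeps the component variances honest
at shallow coverage; the Gaussian mode on c-VAFs mirrors common practice
with general-purpose mixture fitters.

SNVs whose maximum posterior falls below `min_assign_prob` (default 0.80)
are reported unassigned — the "gray dots" excluded from cluster counts.
One subtlety: feeding the *thresholded* tallies into the timing estimators
is selection-biased, because a small class squeezed between two larger
neighbors loses disproportionately many of its members to the exclusion
rule (for a 4:1 at rate 100 and depth 60 the bias on the third gain time
is about $-0.1$). Timing therefore uses the posterior-expected class
counts (`expected_counts`, the EM soft tallies, which are threshold-free
and consistent); the hard assignments keep their role for reporting and
for counting eligible clonal SNVs. `bootstrap_timing()` accepts either
form and resamples mutations, not counts.

Only segments longer than 1 Mb carrying more than 50 clonal SNVs are
eligible for timing (both inequalities strict), and samples whose
length-weighted mean copy number strictly exceeds 3 are flagged as
whole-genome duplicated.

## Time windows

Gains are grouped into shared time windows by clustering segments over
their bootstrap time distributions: within each bootstrap replicate,
complete-linkage clustering of the replicate's segment times, cut at
$2\sqrt{2}\,\hat\sigma$ where $\hat\sigma$ is the pooled bootstrap
standard deviation — two standard errors of a pairwise difference, the
scale below which two estimates of the *same* time are expected to fall
(cutting at $1\,\hat\sigma$ would split same-window segments, since two
unbiased estimates of one time differ by $\approx 1.1\,\hat\sigma$ on
average). Per-replicate labels are then combined by majority
co-clustering. When serial samples are available, a gain absent from an
earlier sample is forced into a later window than every gain already
present there; `validate_serial_timing()` quantifies the agreement between
the single-sample ordering and the serial presence/absence ordering.

## Subclones and trees

`gibbs_cluster()` fits a Dirichlet-process binomial mixture across
samples: $\mathrm{alt}_{is} \sim \mathrm{Binomial}(\mathrm{tot}_{is},
c_{is} f_{z_i s})$, where $f_{ks}$ is the cancer cell fraction of subclone
$k$ in sample $s$ and $c_{is}$ maps CCF to read fraction through purity,
multiplicity and copy number. The sampler uses truncated stick-breaking
(30 components), a Gamma(1,1) prior on the concentration resampled every
sweep, and a discrete CCF grid (step 0.01) for the non-conjugate frequency
updates; chains default to 1000 sweeps with 300 discarded. Point estimates
come from the pairwise co-assignment matrix (average linkage, cut at
co-clustering probability 0.5), which is invariant to label switching;
consensus fragments holding under 2% of mutations are absorbed into their
highest-affinity cluster, since a cluster of a few outlier reads is not a
subclone by any operational standard.

Trees over subclones follow the pigeonhole principle: in every sample the
summed CCF of a node's daughters may exceed the node's CCF by at most the
tolerated error (0.001), and subclones with fewer than 50 mutations are
excluded. `enumerate_trees()` performs the depth-first search over parent
assignments (candidate roots first — a root must accept every other
subclone as a daughter); `brute_force_trees()` enumerates all rooted
parent vectors as an independent oracle, and the two are tested for exact
agreement on random instances, including infeasible ones (the empty tree
list is a legitimate result).

## Structural variant timing

`compute_rvaf()` adjusts the fraction of SV-supporting reads for purity,
copy number and SV cancer cell fraction. Inside a clonal trisomy a
pre-gain SV on the duplicated allele sits at an adjusted fraction of 2/3
and a single-copy SV at 1/3; `classify_by_rvaf()` performs the two-
hypothesis binomial comparison, with a posterior threshold of 0.9
operationalizing the "approximately 66% / 33%" bands (values in between,
or shallow depth, abstain as indeterminate rather than guess). One-copy
calls are disambiguated where possible by the copy-number outcome of
nested deletions (2:0 observed inside → post-gain on the non-duplicated
allele; 1:1 → post-gain on a duplicated copy; 1:0 → pre-gain on the
duplicated allele) or by SNVs/SNPs phased onto all SV-supporting reads.

## Cohort ordering and driver dependencies

`derive_precedence_pairs()` turns per-patient evidence into win/loss pairs
conservatively: two timed gains are ordered only when their bootstrap
intervals are disjoint; a clonal lesion precedes a subclonal one; anything
ambiguous emits no pair; only each patient's earliest sample contributes by
default. `fit_bradley_terry()` estimates earliness abilities by monotone
minorization-maximization, regularized by a symmetric pseudo-win
augmentation of 1e-3 per pair (a weak prior toward equal abilities that
keeps separable data finite); the augmented log-likelihood is asserted to
be nondecreasing at every iteration, and the fit is checked against a
grid-search oracle.

`fit_logic_gate()` enumerates *all* boolean functions of up to three
parent events (so any AND/OR/NOT combination is covered), scores each
function's output against the child with a two-sided Fisher exact test
(direct hypergeometric tail summation), and breaks ties by the smallest
AND/OR/NOT gate decomposition, computed once by relaxation over truth
tables. `learn_structure_small()` finds the globally BDeu-optimal network
(equivalent sample size 1, at most three parents) by exact dynamic
programming over variable orders — practical to 14 events, which covers
the recurrent-lesion matrices this package targets; larger catalogs should
be subset to the events of interest.

## What the simulator does and does not emulate

`simulate_gain_history()`, `simulate_reads()`, `simulate_patient()`,
`simulate_svs()` and `simulate_cohort_matrix()` generate: per-allele
Poisson mutation accrual with gains at known times (chain lineage),
binomial read sampling at Poisson depth under the purity/copy-number read
model, planted subclone trees with per-sample CCFs, SVs placed pre/post
gain, and binary driver matrices from known gate networks with bit-flip
noise. Defaults reflect the study conditions the estimators are assessed
under: clonal rate 100 mutations per copy per unit time, depth 60 for
timing recovery (about 40-fold genomes carry a few hundred clonal SNVs on
a timeable chromosome), depth 100 and purity 0.8 for SV and subclone
recovery.

Not modeled: sequence-level reads (no FASTQ or alignment artifacts),
mutational-signature composition or burst-like rate changes (AID/APOBEC
activity makes real myeloma mutation rates nonlinear in chronological
time, which is precisely why all times here are *relative* molecular
times), subclonal copy number, and caller-specific biases. Passing the
recovery tests therefore demonstrates correctness of the inference given
the model's assumptions, not robustness to every artifact of real data.

## Numerical choices and degenerate inputs

* Estimates are clipped to $[0,1]$ rather than erroring on noisy counts;
  multi-gain times are additionally sorted so $T_{1st} \le T_{2nd} \le
  T_{3rd}$ always holds.
* The 3:1 denominator term $(CN1 - 2\,CN2 - CN3)/4$ is clipped at zero
  before division when sampling noise drives it negative.
* Mixture EM stops at a log-likelihood change of 1e-8; component
  probabilities are floored at 1e-300 before logs.
* Fisher tail summation uses the customary $1 + 10^{-7}$ relative slack
  when comparing table probabilities; zero margins give $p = 1$.
* MM iterations stop when the largest ability change drops below 1e-8.
* Empty SV files, segments with too few SNVs, and infeasible tree
  instances degrade softly: the pipeline records the abstention in its log
  and continues with what remains.

## Problem sizes

The shipped tests run the stages at the scales used throughout this
document: 1000 simulated segments (250 per copy state) for timing
recovery, 500 simulations for bootstrap coverage, 200 random instances for
the tree oracle, a 450-mutation two-sample chain at the default 1000/300
sweeps for clustering recovery, 500 SVs, 500 random 2x2 tables, 100 seeds
for gate recovery and 200 simulated patients for ranking recovery. These
sizes were chosen to estimate each property to comfortably better than the
margin being asserted while keeping a full run in the minutes range on one
core.
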