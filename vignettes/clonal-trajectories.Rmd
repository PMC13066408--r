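---
title: "Methods: CCF integration, clone trees, and trajectory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CCF integration, clone trees, and trajectory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetraj)
```

`clonetraj` reconstructs clonal evolution in T-cell lymphoblastic neoplasia
(T-ALL and T-LBL) from targeted panel sequencing and SNP-array data, and
derives cohort statistics from the reconstructed clone trees: ordered
evolutionary trajectories, nested-level summaries, and a relapse-hazard
model on clone composition. This vignette explains the models, the
parameters that matter, and the design decisions behind them.

## From observations to cancer cell fractions

All integration happens on the cancer cell fraction (CCF) scale: the
fraction of tumor cells carrying an event.

**Small variants.** For a variant with allele frequency $v$ at a locus of
tumor copy number $n_t$ (normal copy number $n_n = 2$), mutated on $m$
copies, in a sample of purity $\rho$,

$$\hat\varphi \;=\; v \,\frac{\rho\, n_t + (1-\rho)\, n_n}{m\,\rho},$$

clamped to $[0, 1]$; a raw value above 1.1 raises a model-violation flag
(the observation contradicts the assumed copy state). Multiplicity is
chosen by enumerating $m \in \{1, \dots, n_t\}$ and keeping the smallest
$m$ whose implied CCF does not overshoot 1 by more than 0.1 — the same
tolerance as the flag, so that a clonal variant read slightly above its
expected VAF is not silently reassigned to two copies. Confidence
intervals are Wilson intervals on $v$ (depths vary and VAFs sit near
boundaries, where Wald intervals misbehave) pushed through the linear map.

**Copy-number events.** Segments are classed from the integer copy number:
CN 0–1 deletion (`del`), CN 2 with allelic imbalance copy-neutral LOH
(`LOH`), CN 3–4 duplication (`dup`). For a fraction $f$ of tumor cells
carrying the event (aberrant cell fraction $\rho f$), the expected
B-allele frequency is $(1-\rho f)/(2-\rho f)$ for a one-copy deletion,
$(1-\rho f)/2$ for copy-neutral LOH, and $1/(2+\rho f)$ for a one-copy
gain; logR follows the total-copy ratio. `cnv_fraction()` inverts the BAF
relation in closed form and reports the logR-implied fraction as a
diagnostic only — BAF is the cleaner signal and wins. $f$ is already a
cell fraction and enters tree building directly as the event's CCF.

**Purity.** Deep panels cover too little genome for ASCAT/ABSOLUTE-style
purity–ploidy grids, so purity is estimated as
$\min(1,\, q_{95}(2\,\mathrm{VAF}))$ over variants in copy-neutral
regions, and floored by the largest aberrant cell fraction $\rho f$ any
CNV implies — a sample cannot be less pure than its most prevalent
aberration. The floor matters in patients whose clonal events are all
copy-number changes: without it there is no clonal VAF to anchor on and
every CCF downstream is inflated. An explicit purity (blast percentage
from metadata) overrides both.

## Clustering events in CCF space

Events are grouped into clones by a binomial mixture over CCF space. Each
sequencing variant contributes its raw counts: alt reads out of depth,
with success probability $c \cdot s$ where $c$ is the cluster CCF and
$s$ is the variant's clonal-VAF scale $m\rho/(\rho n_t + (1-\rho)n_n)$.
Working on the counts, not on clamped point estimates, is important at
the top of the CCF range: a clonal variant whose estimate clips at 1.0
would otherwise fake a separate mode next to estimates at 0.9. Array
fractions, which have no read counts, enter as pseudo-binomial
observations at a delta-method effective size
$f(1-f)/\widehat{\mathrm{var}}(f)$.

The mixture is fit by EM for $k = 1..6$ with 10 deterministic restarts
each; $k$ is selected by BIC; clusters closer than 0.05 mean CCF at every
timepoint are merged. Events absent at a timepoint (e.g. dropped below
the detection threshold) contribute CCF 0 there — clones may regress.
With one event, $k = 1$ is returned without ceremony.

## Tree enumeration and selection

Candidate clone trees over the clusters are enumerated exhaustively: a
depth-first search over parent assignments (the normal-cell root is
implicit) with incremental pruning by the **sum rule** — at every node and
timepoint the children's CCFs may not exceed the parent's CCF by more
than $\varepsilon$, and the root may not exceed 1. Panel data yields few
clusters, so exhaustive enumeration (capped at 8 clusters) is preferable
to any heuristic search: every consistent explanation is on the table,
and ambiguity can be counted honestly.

The working tolerance is
$\varepsilon = \max(0.05,\; 2 \times \text{mean Wilson half-width})$ of
the event CCFs — it must scale with sampling noise. If no tree passes,
$\varepsilon$ is relaxed stepwise ($2\times$, $4\times$) before the
reconstruction is declared failed; in the pipeline a failed patient is
logged and excluded, never fatal to the cohort run.

**Allele phasing.** Variants of one gene within read-pair distance can be
phased. A `different_allele` pair cannot share a haplotype, so at most
$n_\text{alleles}$ (2 without a copy gain) pairwise-incompatible events
may lie on one root-to-leaf lineage, co-resident events included; a
`same_allele` pair must stay collinear. These constraints filter the
candidate list and can, in favorable cases, reduce a single-timepoint
ambiguity to a unique topology — three same-gene frameshifts with CCFs
$\{a, a, b\}$ and no copy gain force two parallel branches with the
equal-CCF pair co-resident, which the test suite checks as a worked case.

**Selection.** Among surviving candidates: minimal total sum-rule excess,
then fewest leaves (parsimony toward linear evolution), then
lexicographic parent vector. The number of co-optimal trees is attached
to the result as an ambiguity report; ties are never broken randomly, so
identical inputs give identical trees.

## Trajectories and nested levels

Events are labeled by gene symbol, or for CNVs by class and location
(`del_in_9p`, `LOH_in_9p`, `dup20`): arm-level when at least 90% of the
segment sits in one arm, whole-chromosome otherwise (approximate
cytoband-derived centromeres for GRCh38, GRCh37 optional).

An ordered trajectory of length 2 or 3 is a tuple of labels on distinct
nodes in **strict ancestor order**; any strict ancestor counts, not only
parent–child, so `LOH_in_9p -> BCL11B -> NOTCH1` contains
`LOH_in_9p -> NOTCH1` and the two reports stay mutually consistent.
Same-node pairs are excluded: their order is unknowable. Per patient a
trajectory counts once. Cohort reporting retains length-2 trajectories in
at least 10% and length-3 in at least 5% of a subgroup's trees, both
thresholds inclusive.

**Enrichment test.** The null preserves everything about each patient
except the ordering information: labels are reshuffled uniformly over
each tree's nodes, keeping the topology and the per-node label counts.
The statistic is cohort support; with the standard +1 correction,
$p = (1 + \#\{\text{permutations} \ge \text{observed}\}) / (1 + B)$.
All trajectories share the same joint permutations, and
Benjamini–Hochberg adjustment is applied within one subgroup and length
class. Because the support statistic is a small count, these p-values are
**super-uniform** (conservative) by construction: the achievable
rejection rate at $\alpha = 0.05$ sits below 0.05 and approaches it only
as cohorts grow and the support distribution gains atoms. The calibration
suite therefore measures the rejection rate on cohorts of 60 trees with
common labels, where discreteness is mild; with 15-tree cohorts of rare
labels the same test rejects almost never, which is conservatism, not
miscalibration.

**Nested levels.** The founding malignant clone sits at level 1; an
event's level is the 1-based depth of the clone where it is first
acquired; the tree's level is its maximal depth. The cohort summary is
weighted: per event class, all occurrences count equally; per tree, each
patient is weighted by its number of events, so event-rich (better
resolved) patients carry proportionally more information.

## The relapse-hazard model

The covariate is the **NOTCH1-wild-type tumor fraction**: at diagnosis,
the CCF of the largest clone minus the CCF of the largest clone carrying
a NOTCH1 event (a clone carries the marker if it or any ancestor acquired
it; under the nested CCF convention that maximal carrying clone already
includes its mutant descendants), in percentage points of $[0, 100]$. If
no clone carries NOTCH1 the whole largest clone is wild-type. An
alternative reading — summing disjoint mutant branches — is exposed as a
mode flag but not the default.

The Cox proportional-hazards partial likelihood is maximized by
Newton–Raphson with step halving to a gradient norm below $10^{-8}$,
with **Efron's** tie correction: relapse times have day granularity, so
ties are the rule, and Breslow's approximation degrades there. The test
suite cross-checks the solver against an independent reference
implementation to $|\Delta\beta| \le 10^{-6}$. Monotone likelihood
(perfect separation) is flagged rather than reported as an estimate. A
hazard ratio of $h$ per percentage point is reported alongside the
derived phrasing $100(h-1)\%$ risk increase per point.

Among relapsed patients, time to relapse by mutation status is compared
with a two-sided Wilcoxon rank-sum test (the underlying comparison is of
relapse-time distributions; a log-rank alternative over all patients is
available).

## The synthetic cohort generator

The generator exists so every downstream stage is testable without
patient-level data. It emulates four subgroups (pediatric/adult ×
T-ALL/T-LBL) with:

* clone trees of 1–8 clones over 1–4 sampling timepoints (days 0 / ~300 /
  ~700 / ~1100, with most patients sampled once — relapse samples are the
  exception, as in real cohorts);
* an event vocabulary mirroring the recurrent lesions of the disease
  (NOTCH1, PHF6, FBXW7, PTEN, BCL11B, USP7, KMT2D, TP53; `del_in_9p`,
  `LOH_in_9p`, `dup_in_9p`, `dup20`, `del_in_6q`). Gene inclusion
  probabilities follow reported per-subgroup mutation frequencies
  (e.g. NOTCH1 0.78 pediatric vs 0.61 adult T-ALL); the chr9p del/LOH
  probabilities are anchored so that the implied co-presence with NOTCH1
  matches reported patient-level co-occurrence (38.7% / 35.5% in
  pediatric T-ALL, 15% / 19% in pediatric T-LBL);
* a planted ordering bias: biased (from → to) label pairs are placed
  jointly on the tree with a 10× weight on arrangements where the `from`
  node is a strict ancestor of the `to` node — by default
  `LOH_in_9p -> NOTCH1` in both pediatric subgroups, the enrichment the
  trajectory test is designed to detect;
* panel reads at Poisson(500) depth with binomial alt counts; array BAF
  and logR from the closed-form signal model plus Gaussian noise
  (SD 0.01 and 0.05); purity uniform on [0.7, 1];
* relapse times exponential with
  $\lambda = \lambda_0 \exp(\beta\,x)$, $\beta = \ln 1.032$ per
  percentage point of NOTCH1-wild-type fraction,
  $\lambda_0 = 2\times10^{-4}$/day, independent exponential censoring at
  $2.5\times10^{-4}$/day. Exponential (not Weibull) times keep the
  planted hazard ratio analytically exact.

**Identifiability by construction.** Truth CCFs are drawn so that the
architecture is the *unique* sum-rule-consistent tree given them,
verified by running the enumerator in counting mode and redrawing
otherwise. Multi-child nodes split most of the parent's CCF (siblings
separate each other); a single child nearly exhausts its parent except at
one designated timepoint, where a sweep/regression window of at least the
configured CCF gap (default 0.15) opens between them. Single-timepoint
patients receive linear architectures of at most five clones: branching —
and chains beyond that depth at 0.15 spacing — are
information-theoretically unidentifiable from one sample (the worked
phasing case above is exactly the situation where only allele phasing
rescues a single-timepoint branching). This matters for what the
recovery tests mean: with an identifiable truth, reconstruction error
measures the algorithm, not inherent ambiguity. Real cohorts contain
unidentifiable patients; on those, the package reports its tie-broken
choice together with the co-optimal count rather than feigning certainty.

**What the generator does not emulate:** germline background variants,
read-level artifacts (strand bias, mapping error), subclonal copy-number
mixtures beyond a single class per segment, mutation loss (the infinite
sites assumption holds except for regression of whole clones to CCF 0),
inter-gene correlation beyond the planted ordering biases, and cohort
case–control sampling structure. Tests passing on synthetic cohorts
demonstrate correctness of the machinery under the stated noise model,
not robustness to every artifact of real panels.

## Problem sizes and numerical choices

The property suites run on one CPU in minutes: closed-form inversion on a
~5,000-point grid; recovery on 100 noiseless and 100 depth-500 patients
with up to 5 clones; calibration on 500 null cohorts of 60 trees at 199
permutations; power on 100 cohorts of 40 trees at 999 permutations; Cox
recovery on 100 replicates of n = 800. Tie-breaks are fixed
(violation → leaf count → lexicographic), EM restarts are seeded
deterministically, and all randomness descends from one master seed via
named substreams, so adding patients never perturbs existing ones.

Degenerate inputs are handled explicitly: a single event yields a
one-clone tree; a constant covariate or fewer than two events is a
refused Cox fit; genes mutated in all or no patients are skipped in age
association; a variant inside a homozygous deletion has no defined
multiplicity and is excluded with a flag; empty permutation inputs and
empty BH inputs return empty results.

## Known limitations

* The enrichment test's null is within-patient label shuffling; the
  original analysis's exact test construction is not public, so adjusted
  p-values need not be numerically comparable to published ones.
* CCFs assume the local segment applies to all clones; variants whose
  copy state differs between clones of one patient are flagged, not
  modeled.
* No multivariable adjustment in the hazard model (no MRD, stage, or
  matched-design weighting); relapse-enriched cohorts do not reflect
  population incidence, and neither do synthetic ones.
* Arm assignment uses approximate centromere positions; segments near
  the centromere boundary may be labeled at chromosome level.
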