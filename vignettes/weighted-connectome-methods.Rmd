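---
title: "Weighted structural connectomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted structural connectomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamnet)
```

# The problem

Diffusion tractography produces streamlines: polyline trajectories that
putatively follow white-matter paths between gray-matter regions. Turning a
tractogram into a brain network requires an edge weight, and naive choices
(raw streamline counts, mean fractional anisotropy) are biased by streamline
length, seeding density, and image resolution. `streamnet` implements a
dimensionless weighting that removes these biases, a threshold-free weighted
topology framework on top of it, and the downstream group-inference and
cognition-correlation machinery needed for a case–control connectome study
(here: Parkinson's disease with and without mild amnestic impairment, versus
healthy controls).

# The edge weight

For nodes $i$ and $j$ with surface areas $A_i, A_j$ (mm²), the weight of the
connecting edge is

$$
w(e_{ij}) \;=\; \frac{2}{A_i + A_j}\,
\frac{V_{voxel}}{P_{voxel}} \sum_{f \in \text{retained}} \frac{1}{l(f)},
$$

where $V_{voxel}$ is the voxel volume (mm³), $P_{voxel}$ the number of
seed points placed per voxel, and $l(f)$ the arc length (mm) of a retained
streamline. The units cancel (mm³ / (mm² · mm)), so the weight is
dimensionless and invariant to a global rescaling of spatial units; dividing
by $P_{voxel}$ removes the seeding paradigm, and the $1/l$ factor removes
the length bias that makes long tracts accumulate more streamlines per unit
of anatomical connection.

**Retention (the characteristic filter).** A candidate streamline for pair
$(i,j)$ — one whose endpoints lie in the voxel masks of $i$ and $j$ — is
retained only if its *seed* voxel lies in $R$, the set of voxels traversed
by the pair's candidate streamlines minus both node masks. Streamlines
seeded inside a node, or in voxels off the white-matter path, are discarded.
This is a strict control against the high false-positive rate of
tractography: a spurious connection contributes at most a handful of long
(hence low-$1/l$) streamlines, so its weight is small. On the standard
10-node phantom (50-streamline, 20 mm bundles, $P_{voxel} = 25$), adding a
single spurious 40 mm streamline between 10% of the unconnected node pairs
changes global mean node strength by about 0.2% (`analysis/01`,
`scripts/acceptance.R`), under the 1% robustness bound claimed for the
weighting.

**Conventions the implementation fixes** (the source method leaves them
open; each is declared in file headers and documented here):

* streamline-to-edge assignment is by endpoint containment in node voxel
  masks, one pair per streamline; self-loops and unassigned streamlines are
  dropped with a logged count;
* $R$ is computed from point-in-voxel tests on the polyline resampled at
  one quarter of the smallest voxel edge; voxel indices are 0-based with
  half-open boxes (a point at an exact boundary belongs to the upper voxel);
* duplicate trajectories are counted once per retained seed — the seed, not
  the geometry, is the unit the $P_{voxel}$ normalisation assumes;
* node surface area is taken as supplied metadata (a segmentation product),
  not recomputed from the voxel mask;
* the FA comparison weighting averages fractional anisotropy over the same
  voxel set $R$, for comparability with the dimensionless weight.

# Topology indices

All indices are computed on the weighted matrix with no threshold: weak
edges stay.

* **Graph density** $D$: fraction of node pairs with a positive weight (the
  one binary index).
* **Node strength** $s_i = \sum_j w_{ij}$.
* **Clustering** (Zhang–Horvath): with weights normalised by the graph
  maximum, $\hat w = w / \max w$,
  $C_i = \sum_{j \ne k} \hat w_{ij}\hat w_{jk}\hat w_{ki} \,/\,
  [(\sum_j \hat w_{ij})^2 - \sum_j \hat w_{ij}^2] \in [0,1]$.
  The max-normalisation is required for the $[0,1]$ range; it makes $C$
  scale-free but sensitive to the single largest weight.
* **Path length** (strength of the shortest path): edges get distance
  $d = 1/w$; $L(i,j)$ is the reciprocal of the minimal summed distance, so
  larger values mean stronger routes and $L(i,j) = w_{ij}$ when the direct
  edge is optimal. This strength-like reading (rather than reporting the
  raw distance) is our documented choice; it makes path length correlate
  positively with node strength, matching how the index behaves in the
  study it supports. The raw distance remains available
  (`as_distance = TRUE`). Disconnected pairs are excluded from means and
  counted, never coerced to zero. Ties in the optimal-route search are
  broken deterministically (Dijkstra over a fixed node order).
* **Small-worldness** $S = (C_{obs}/C_{rand}) / (L_{obs}/L_{rand})$ against
  an Erdős–Rényi ensemble matched on node count, density, and weight pool
  (weights resampled with replacement from the observed positive weights);
  20 seeded realisations by default, averaged before the ratio.

A caveat worth knowing: because Zhang–Horvath clustering scales as
$1/\max w$, the ensemble's $C_{rand}$ is biased upward for heavy-tailed
weight pools (a resampled pool's maximum is stochastically smaller than the
observed maximum), which biases $S$ below 1 for weight distributions with a
dominant top edge. Self-consistency ($S \approx 1$ for an ER graph against
its own ensemble) holds cleanly for mild pools, and that is how the test
suite checks it.

# Group inference

Global indices are compared between groups with two-sided Mann–Whitney
tests on the raw per-subject values. Node-level indices are first
residualised on each subject's graph density (ordinary least squares across
all subjects pooled, residual plus grand mean), removing the global
connectivity component from local comparisons; then each node is tested,
and each family of $N$ node tests (one family per index × group pair) is
corrected with the Grenander-based false-nondiscovery procedure:

1. fit the Grenander density — the left derivative of the least concave
   majorant (LCM) of the p-value ECDF, a nonincreasing step density
   integrating to 1 (computed by upper convex hull; the test suite checks it
   against a pool-adjacent-violators oracle);
2. estimate the null proportion $\hat\eta_0$ as the density's flat-tail
   step — the last positive step of the LCM density (the zero step beyond
   the largest observed p-value carries no information), clipped to [0,1];
3. adjust by the tail-area ratio $q(t) = \min(1, \hat\eta_0 t / \hat F(t))$
   with $\hat F$ the LCM CDF, and enforce monotonicity of $q$ in the raw
   p-values;
4. report alongside the false-nondiscovery quantity
   $\mathrm{FNDR}(t) = (1-\hat\eta_0)(1-\hat F_1(t))/(1-\hat F(t))$,
   $\hat F_1 = (\hat F - \hat\eta_0 t)/(1-\hat\eta_0)$, defined as 0 when
   $\hat\eta_0 = 1$.

The exact variant used by the original packaged tool is not recoverable
from its description; this tail-area construction is documented step by
step, and classical Benjamini–Hochberg on the raw p-values is exposed as a
comparison mode (`correction = "BH"`). The Mann–Whitney p-value is exact
(full enumeration, as in `wilcox.test`) when the smaller group has at most
8 subjects and the pooled values are tie-free — chosen so the 9-subject
group is handled reproducibly — and otherwise uses the normal approximation
with tie and continuity corrections. Families are one per (index, group
pair); global tests are not multiplicity-corrected, matching the reported
analysis structure.

# Cognition correlations

Per group, each network index (global, or per node over the
significant-node set) is correlated with each cognitive measure — working
memory, processing speed, memory composites; plus the motor score (UPDRS
III) for the disease groups — by Spearman partial correlation: all three
vectors are rank-transformed (midranks) and the first-order partial
correlation formula is applied to the ranks. The default covariate is
education; age is supported through the same argument because the source
material is internally inconsistent about which was used, and neither is
asserted as ground truth. Correlations are Fisher z-transformed
($z = \operatorname{atanh}\rho$); strong-correlation flags use
$|z| > 0.55$ for global tables and $|\rho| > 0.50$ for node-level count
matrices, both exposed as `run_config()` thresholds. Two independent
correlations are compared with the Fisher z difference test
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. Records with undefined $\rho$ (zero rank
variance, as happens for a restricted-range measure) are excluded from
counts and tallied.

# The synthetic generators

Nothing in this package requires imaging data; two generators create fully
ground-truthed inputs.

**Phantoms** (`make_phantom()`): cuboid nodes on a planar lattice in a real
voxel grid (default 2 mm isotropic voxels, 20 mm spacing, 4 mm node cubes),
bundles of identical center-to-center streamlines between lattice
neighbours (arc-lengthened via a midpoint tent when a target length is
requested), seeds cycling deterministically over the corridor voxels with
$P_{voxel}$ slots per voxel (default 125, matching the emulated tracking
protocol; robustness analyses use 25), and optional single-streamline
spurious connections of at least 40 mm between unconnected pairs. Because
every streamline in a bundle shares one polyline, edge weights have exact
closed forms, which the tests exploit.

**Cohorts** (`make_cohort()`): three groups (default 40 controls, 31
PD-Well, 9 PD-MI) share one 82-node edge support drawn at 40% density with
log-normal weights (meanlog $\log 0.05$, sdlog 1 — nonnegative,
right-skewed, heavy top tail). Each subject's matrix is the support scaled
by: the group's global strength multiplier (defaults 1 / 0.9501 / 0.8677,
i.e. the 4.99% and 13.23% reductions used as calibration constants), a
focal multiplier (default 0.85, PD-MI only) on edges incident to the
designated 27-node set, and three log-normal noise layers — per edge
(sdlog 0.25), per node applied to incident edges (sdlog 0.10), and a small
global subject factor (sdlog 0.03). After the focal reduction each matrix
is rescaled so the realised global contrast equals the configured
multiplier exactly, keeping global and focal effects separable. Cognitive
composites, education, age and the motor score are drawn per group with the
study's demographic means and spreads, and each composite's rank
correlation with the subject's realised global mean strength and with
education is injected through a Gaussian copula
($a = 2\sin(\pi\rho_S/6)$, exact for the Spearman target in expectation);
default targets follow the study's global correlation table (e.g. working
memory versus strength: +0.22 controls, −0.52 PD-Well; UPDRS versus
strength +0.68 in PD-MI), with 0.30 for the education–composite
association, a conventional magnitude for education–cognition covariance.

The noise decomposition deserves a note. Between-subject variability in
mean node strength is dominated here by the node- and edge-level layers
(global factor only 3%), because the generator's fixed support keeps graph
density constant across subjects: the density control that absorbs shared
global variation in real cohorts has no handle in this synthetic world, so
a large shared factor would correlate all node tests in a family and
inflate the corrected error rate through no fault of the inference code.
With the layered noise, the full local pipeline on effect-free cohorts
keeps its within-family rejection rate below the nominal $\alpha$ (checked
in the acceptance suite). What the generator consequently does *not*
emulate: density variation across subjects, anatomical triangle structure
(its supports are Erdős–Rényi, so clustering and small-worldness magnitudes
are far from brain-like values), spatial autocorrelation of edges, and any
dependence of cognitive measures on anything but strength and education.
Passing tests therefore demonstrate correctness of the machinery and
recoverability of injected effects, not realism of brain topology.

**P-value mixtures** (`make_pvalue_mixture()`): $n\pi_0$ uniform nulls plus
$n(1-\pi_0)$ one-sided normal alternatives, for exercising the Grenander
estimator and the false-nondiscovery adjustment under known truth.

# Numerical and scale choices

* Streamline–voxel traversal resamples at ¼ voxel edge: a straight segment
  cannot skip a voxel at that step, and the cost is linear in length.
* The LCM hull uses a small negative tolerance ($10^{-15}$) when discarding
  non-concave corners so collinear knots collapse deterministically.
* `er_null()` and `small_worldness()` take explicit integer seeds; every
  generator is a pure function of its spec and seed, and the tractogram
  writer emits byte-stable files so determinism is testable at the file
  level.
* Degenerate inputs are contracts, not surprises: empty tractograms warn
  and return zero matrices; all-zero graphs warn and return zero
  clustering; fully tied Mann–Whitney samples return $p = 1$; zero-variance
  densities make the adjustment a no-op; undefined correlations are flagged
  `NA` and excluded from counts with a tally.
* Problem sizes in the tests and analysis scripts — 10-node phantoms,
  cohorts of 16–82 nodes, 20-realisation null ensembles, 200-replicate
  recovery loops — were chosen as the smallest sizes at which the checked
  quantities stabilise; the full `analysis/` chain at study scale (82
  nodes, 80 subjects) runs in about a minute.

# Known limitations

* The acceptance-grade group-difference and correlation numbers of the
  motivating study derive from undeposited MRI data; they enter here only
  as generator calibration constants, and the package makes no claim of
  reproducing them from real data.
* At study scale the injected global deficits are detected at essentially
  every node (the generator's noise is clean relative to real data), so the
  "27 significant nodes" figure is a calibration input, not an emergent
  output.
* The TRK adapter reads the common little-endian, header-size-1000 layout
  and takes the seed voxel as the first-point voxel ($P_{voxel}$ must be
  supplied); scanner-specific orientation metadata is not interpreted.
* Small-worldness inherits the max-normalisation sensitivity discussed
  above; compare values only across graphs with similar weight tails.
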