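---
title: "Methods: single-subject connectome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-subject connectome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(graphme)
```

`graphme` profiles one patient's weighted structural connectome against a
healthy-control cohort. This vignette documents the model, the parameters
that matter, the numerical conventions, and the design decisions taken where
more than one defensible choice existed. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## Input model and assumptions

The unit of analysis is an N×N symmetric non-negative matrix of connection
weights (SIFT2-filtered streamline counts between parcellated regions; the
reference parcellation is the 84-region Desikan–Killiany atlas, but any
N ≥ 3 is accepted). Ingestion enforces the invariants every downstream step
assumes: squareness, finiteness, non-negativity, a zero diagonal, and exact
symmetry. Asymmetry up to a relative 1e-6 is treated as serialization
round-off and repaired by averaging `(A + t(A))/2`; anything larger is an
error, because tractography connectomes are symmetric by construction and a
grossly asymmetric file indicates a corrupted export, not noise. Fully
disconnected rows are accepted with a warning rather than rejected:
anatomically constrained tractography legitimately assigns no streamlines to
severely lesioned regions, and keeping the matrix dimension fixed is what
makes patient-versus-control comparison possible at all.

A cohort is ≥ 2 controls plus one patient sharing the node table's dimension.
Two controls is the mathematical minimum for a per-edge standard deviation;
the reference analyses use 12, and all calibration simulations in this
package are run at n = 12.

## The eight global metrics

Edge weights are remapped to lengths by the reciprocal, `l = 1/w` (absent
edges have infinite length). This is the standard remap for
streamline-weighted connectomes: stronger connections are shorter.

* **Strength**: row sums of the weight matrix; reported as the node mean.
* **Characteristic path length** `L`: mean Dijkstra shortest-path length
  over unordered pairs. Unreachable pairs are *excluded* from the mean and
  their count reported, rather than forcing `L = Inf`; the efficiency
  metrics already encode disconnection as zeros, so `L` stays interpretable
  on lesioned networks.
* **Global efficiency**: mean of `1/d_ij` with `1/Inf = 0`.
* **Navigation efficiency**: decentralized greedy routing. For every ordered
  pair (s, t) the walker repeatedly hops to the connected neighbor whose
  centroid is Euclidean-closest to the target; the walk fails if it would
  revisit a node or reaches a node with no neighbors. Pairwise efficiency
  is the reciprocal of the sum of reciprocal-weight edge lengths along the
  walk (a hop-count variant is exposed via `measure = "hops"`), zero on
  failure. Ties in the greedy choice are broken by lowest node index, so
  the metric is deterministic.
* **Local efficiency**: for each node, the global efficiency of the
  subgraph induced by its neighbors (weights restricted to that subgraph);
  zero for degree < 2.
* **Clustering**: the Onnela geometric-mean triangle form on max-normalized
  weights, `C_i = Σ_{j,h} (w̃_ij w̃_jh w̃_hi)^{1/3} / (k_i(k_i−1))`, with
  `C_i = 0` for degree < 2. Max-normalization makes `C` invariant to
  uniform weight scaling, which the test suite asserts.
* **Normalized clustering** `C/C_rand`: the observed mean clustering divided
  by the mean clustering of degree-preserving rewired surrogates.
* **Betweenness centrality**: Brandes accumulation on reciprocal-weight
  lengths, *unnormalized*, so values are raw counts of unordered shortest
  paths (fractionally split over equal-length multiplicities). Raw counts
  are what hub analyses in this literature report (hub values in the
  hundreds to thousands on 84 nodes), and the hub rule only needs ranks.

Dijkstra and Brandes run through igraph; both are cross-checked in the test
suite against exhaustive path-enumeration oracles on small random graphs.

### The rewiring null model

The surrogate for `C_rand` preserves exactly what it should and nothing
more: double-edge swaps `(a–b, c–d) → (a–d, c–b)` keep every node's degree
and the multiset of edge weights, rejecting swaps that would create
self-loops or duplicate edges. Defaults: 100 surrogates, 10 attempted swaps
per edge, driven by R's RNG so a profile is bit-reproducible given
`(matrix, seed)`. These two knobs are exposed (`n_nulls`,
`rewires_per_edge`) because they trade precision of `C_rand` against run
time; 100 × 10 is standard practice and gives a null-ensemble SEM far below
between-subject differences in the simulated cohorts. The swap loop is
implemented in C++ (`src/rewire.cpp`): it is the only part of the profile
whose cost is attempts × nulls rather than matrix-sized.

Degenerate case: a complete graph admits no legal swap, surrogates equal the
original, and `C/C_rand = 1` exactly. A null ensemble with zero mean
clustering (only possible on triangle-free degenerate inputs) raises a
metric-undefined error rather than returning `Inf`.

## The GraphMe profile

Three metrics are "lower is better" (`L`, `C/C_rand`, mean `BC`); they are
inverted (1/x) for display so that on the radar every axis reads
"higher = better". The inversion is an involution and is tested as such.
Inverting a zero-valued metric is an error, not an `Inf`.

**ICV correction.** The head-size correction is stated in the source
literature as "dividing each graph metric by the inverse of the total
intracranial volume", which read literally is multiplication by ICV and is
dimensionally odd. `icv_mode` therefore exposes `divide` (metric/ICV, the
conventional size correction), `multiply` (the literal reading), and `none`
(the default, appropriate for synthetic cohorts where no head-size construct
exists). Correction is applied after inversion; since both orders differ
only by ICV ↔ 1/ICV on the inverted metrics, the switch covers both
readings. Categorization is unaffected as long as patient and controls are
transformed identically, which `graphme_profile()` guarantees by
construction.

**The reference band.** Three interval constructions are exposed:

* `t_mean` (default): `mean ± t(0.975, n−1)·sd/√n` — the literal "95%
  confidence interval of the control mean".
* `normal_mean`: the same with 1.96 in place of the t quantile.
* `prediction`: `mean ± t(0.975, n−1)·sd·√(1 + 1/n)` — the t prediction
  interval for one new individual.

The default follows the literal description, but classifying an *individual*
against a CI of the *mean* is statistically narrow: with n = 12 the mean-CI
has width ~0.6 SD, so even a healthy control drawn from the same population
falls outside it roughly half the time. The prediction interval is the
calibrated choice for individual-level categorization, and the test suite
verifies its calibration: over 500 simulated cohorts, a held-out control is
categorized "normal" at the nominal 95% rate within binomial 99% bounds.
Band boundaries are inclusive ("within the interval" = normal). Zero-variance
metrics collapse the band to the mean with a warning.

One caveat: mean ± t·sd intervals are equivariant under increasing *affine*
maps only; categorization is therefore invariant to affine rescaling of the
metric (tested), but not to arbitrary nonlinear monotone transforms of the
display scale.

## Regional deviation maps

Per edge, `Z_ij = (T_ij − μ_ij)/σ_ij` with μ and σ the control sample mean
and SD (denominator n−1). Positive z = stronger edge in the patient,
negative = weaker. p-values are two-sided standard normal,
`p = 2·Φ(−|z|)`, computed through the lower-tail CDF directly so far-tail
values retain full relative accuracy (verified against an independent
quadrature of the normal density to 1e-12 relative error for |z| ≤ 10).
A small-sample t correction is deliberately *not* applied: the z→p pairs
this analysis is defined by are exact under the normal reference, and the
package reproduces them. The consequence — mildly anti-conservative tails
when n = 12 controls estimate σ — is quantified below rather than hidden.

**Multiplicity.** BH-FDR (step-up, `stats::p.adjust`, cross-checked against
a literal implementation of the step-up definition) is applied over the
family of unique upper-triangle edges. Edges with σ = 0 and `T = μ`
(typically structurally absent edges, zero in everyone) get z = 0 and stay
in the family; edges with σ = 0 and `T ≠ μ` cannot be tested parametrically
and are excluded with reason `"zero-variance"` and flagged. For N = 84 the
family is C(84,2) = 3486 unique edges. Node-strength z-scores get the same
treatment over the N-node family; node-level FDR can be disabled
(`correct_nodes = FALSE`) for fidelity with analyses that report raw nodal
p-values.

**Hubs.** The top `round-half-up(0.10·N)` nodes by betweenness — 8 of 84 —
with ties broken by higher strength then lower index. The reference hub set
defaults to the hubs of the group-average control connectome (matching how a
single control hub set is usually displayed); a per-control consensus option
ranks nodes by how often they are hubs across controls. Hub alterations are
the plain set differences (gained/lost).

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's statistical behavior is assessed.

* **Geometry**: centroids uniform in a brain-sized half-ellipsoid
  (semi-axes 70 × 85 × 60 mm) mirrored across the midsagittal plane, so
  navigation has meaningful coordinates and hub fixtures can be bilateral.
* **Template weights**: `w_ij = w0 · exp(−d_ij/λ)` with `w0 = 1000`
  (streamline-count scale) and `λ = 35` mm, thresholded to the strongest
  35% of pairs (`density = 0.35`). Distance decay is the dominant
  regularity of structural connectomes; the density and decay scale were
  fixed once at values typical of thresholded streamline-count matrices on
  this atlas.
* **Subject noise**: per-edge multiplicative lognormal noise, symmetric,
  with mean 1 and CV 0.15 (`sdlog = sqrt(log(1 + CV²))`,
  `meanlog = −sdlog²/2`). Mean-one (rather than median-one)
  parameterization makes the per-edge sample mean converge exactly to the
  template, which the cohort tests assert; right-skewed multiplicative
  noise keeps weights positive and mimics streamline-count variability.
  Defaults: 12 controls, CV 0.15.
* **Lesions**: all edges incident to chosen target nodes multiplied by
  `a ∈ [0,1]` (or zeroed), with the exact altered-edge mask returned as
  ground truth. This models the *network consequence* of a focal lesion —
  attenuated streamline counts on every tract touching the damaged
  regions — not the imaging.

What the generator does **not** emulate: between-edge correlation of
individual differences (real subjects vary coherently, e.g. global scaling
with head size), topological individuality (everyone shares one template),
heavy-tailed outlier subjects, scanner/site effects, and lesion-induced
*re-routing* (real injury can strengthen alternative pathways; here
non-lesioned edges are untouched). Consequently, passing calibration tests
here demonstrates correctness of the statistical machinery under its own
assumptions — not clinical validity on real cohorts, which the source
framework itself defers to larger normative samples.

## Calibration behavior under the study conditions

With 12 controls, CV 0.15, and normal-reference p-values, the edge z of a
null patient is approximately `t_11 · √(1 + 1/12)` rather than standard
normal, so tail p-values are anti-conservative by a factor that grows in the
tail. The acceptance suite measures the practical consequence: across 200
simulated non-lesioned patients the mean FDR-rejected edge fraction stays
two orders of magnitude below the nominal q = 0.05 (BH at q = 0.05 over
3486 edges demands p ≤ 1.4e-5 for the first rejection, which even inflated
t-tails rarely reach). For injected lesions (attenuation 0.3 on 4 nodes,
expected |z| ≈ 0.7/0.15 ≈ 4.7), edge recovery sensitivity and precision both
exceed 0.8 averaged over 100 seeds — the false positives admitted by the
anti-conservative tails cost precision only a few points at this effect
size.

## Numerical conventions and degenerate inputs

* Symmetry repair tolerance: relative 1e-6; beyond it, error.
* Matrix text format: comma/tab/whitespace delimited, no header; 12
  significant digits on write, so write∘read round-trips to 1e-11.
* Node indices are 0-based internally and in tidy outputs; CSV exports
  print 1-based node numbers alongside labels.
* All unordered-pair means run over the upper triangle once.
* Greedy-navigation and hub ties break deterministically (lowest index /
  higher strength then lowest index).
* Every stochastic step (null ensemble, synthetic generation) derives from
  an explicit seed; a profile recomputed with the same seed is
  bit-identical, and `run_full_profile()` outputs are byte-identical across
  reruns.
* Problem sizes in the test suite were chosen to keep the default run
  brief while leaving no code path untested: oracle equivalence uses
  exhaustive enumeration on 4–7-node graphs across 100 seeds, BH against
  its literal definition on up to 1000 p-values across 1000 seeds,
  calibration on 84-node cohorts (200 null replicates, 100 lesion seeds,
  500 band-coverage cohorts), and end-to-end runs on a 10-node preset.

## Known limitations

* The normal-reference p-values are anti-conservative for small control
  cohorts (quantified above); a t-reference or permutation option would be
  the natural extension for n = 12 reference groups.
* Characteristic path length on fragmented networks depends on the
  exclusion convention; the exclusion count is always reported so users can
  detect when `L` summarizes only part of the network.
* The prediction-interval calibration assumes approximately normal metric
  distributions across controls; global metrics average thousands of edges
  and are close to normal under the generator, but single-edge weights are
  not, which is why edges are tested with z-scores rather than banded.
* No directed-graph support, no alternative parcellations, no
  streamline-count-to-volume normalization variants, and no cluster-level
  (NBS-style) edge inference — deviations are reported edge by edge.
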