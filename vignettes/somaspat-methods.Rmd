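---
title: "Methods: 3D spatial statistics for neuronal soma distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D spatial statistics for neuronal soma distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaspat)
```

## The scientific problem

Cholinergic neurons in the basal forebrain and striatum are sparse
(roughly 100-700 cells per mm^3) and their spatial arrangement carries
information about the circuits they support. Given the 3D coordinates of
every cholinergic soma in a structure (caudate-putamen CPu, nucleus basalis
NB, globus pallidus GP, nucleus accumbens NA, septum S), the questions this
package answers are:

* Are the somata **clustered**, **random**, or **regular** relative to a
  uniform (CSR) arrangement with the same count, volume and shape?
* Is an apparent clustering **genuine**, or an artefact of a large-scale
  **density gradient** (e.g. anterior-posterior) within the structure?
* How do physical constraints — the **axonal fibre bundles** that occupy
  roughly 27% of the CPu and exclude somata — change the null expectation?
* How is the **territory** around each soma (Voronoi volume) distributed,
  and how large are nearest-neighbour clusters?

## Estimators

### Uncorrected Ripley K in 3D

For a pattern of $n$ points in a region of volume $|V|$ (mm^3),

$$\hat K(r) = |V|\,\frac{\sum_i \sum_{j \ne i} \mathbf 1[D(i,j) \le r]}{n^2},$$

with exact Euclidean distances and ties $D = r$ counted as $\le r$
(`k_function()`). **No edge correction is applied.** The estimator is
negatively biased near the boundary (pairs are lost across it), but every
hypothesis test in the package compares the observed curve against
simulations drawn in the *same* region with the *same* $n$, so observed and
null curves share the bias. This is the standard Monte Carlo argument for
uncorrected summaries; the acceptance tests verify both the small-$r$
agreement of the simulated mean with $\tfrac43\pi r^3$ (within 5% for
$r$ below ~5% of the region size) and the direction of the bias at large
$r$.

The default radii grid is 100 equally spaced radii from 0 to half the
region's maximum chord, under which the paired-$t$ comparison of observed
and simulated-mean curves (`paired_t_compare()`) has 99 degrees of freedom.
The per-radius pairs are strongly autocorrelated, so the paired $t$ is
reported descriptively; calibrated inference comes from the envelope and
rank tests.

Pointwise envelopes use order statistics: with `n_sims` simulations the
band at each radius is the $m$-th smallest to $m$-th largest simulated
value, $m = \lfloor 0.025\,(n_\text{sims}+1)\rfloor$, giving an exact 5%
two-sided pointwise exceedance rate (e.g. $m = 5$ at 199 simulations).

### Kernel intensity and the inhomogeneous K

Local intensity $\lambda(x)$ (points per mm^3) is estimated with an
isotropic Gaussian kernel whose bandwidth follows Silverman's 3D
rule-of-thumb, $h = \left(\tfrac{4}{d+2}\right)^{1/(d+4)} n^{-1/(d+4)}
\bar\sigma$ with $d = 3$ and $\bar\sigma$ the geometric mean of the
per-axis standard deviations (`kernel_intensity()`).

Two numerical choices matter here:

* **Boundary mass correction.** Kernels near the boundary leak mass
  outside the region; with Silverman bandwidths the loss is ~20% of total
  mass in compact regions. Each kernel is therefore divided by its
  in-region mass (estimated once by fixed-seed Monte Carlo, floored at 0.05
  to keep weights finite). Every point then contributes one unit of mass,
  so the field integrates to $n$ over the region *and* interior values
  remain consistent — a single global renormalisation cannot achieve both.
* **Leave-one-out evaluation.** When the field is evaluated at its own
  source points (as K_inhom requires), the self-kernel is excluded: at
  $n \approx 80$ the self-term alone is ~20% of $\lambda$.

The inhomogeneous K follows the per-pair reciprocal-weight form

$$\hat K_\text{inhom}(r) = \sum_i \sum_{j \ne i}
\frac{\mathbf 1[D(i,j) \le r]}{\hat\lambda_i\,\hat\lambda_j},$$

again uncorrected for edges and with no volume prefactor
(`k_inhom()`). With constant intensity $\lambda = n/|V|$ it reduces
*algebraically* to $|V|\hat K(r)$; the test suite asserts this identity to
1e-9 relative at every grid point.

### The Monte Carlo rank test

`inhom_analysis()` is the full gradient-vs-clustering pipeline: estimate
the intensity from the complete pattern; optionally restrict the analysis
to a boundary-avoiding ball (default radius 1 mm, centred by a 0.1 mm grid
search for maximal boundary clearance) while the generating intensity is
kept from the full pattern; simulate 99 fixed-count inhomogeneous-Poisson
realisations by thinning; reduce every curve to a one-dimensional
criterion (default: integrated absolute deviation from the null mean,
`"max"` available) and rank the observed criterion among the nulls. With
99 nulls the smallest attainable p is 0.01.

**Intensity re-estimation (the key validity choice).** The classical
construction freezes the observed field and weighs all curves with it. At
moderate $n$ this is not a valid test: null points are sampled
proportionally to the estimated field and therefore feel its noise bumps
in a size-biased way, while the observed points do not. In a calibration
experiment (gradient-only data, $n = 80$, 99 nulls, 30 replicates) the
frozen-field variants rejected 78-93% of the time at nominal 5%. The
package therefore computes each curve's weights from an intensity
estimated from that pattern itself — the identical statistic applied to
every pattern, exchangeable under the null — which brought the empirical
type-I rate to 3% (and, at the package's reduced acceptance scale, into
the [1%, 12%] band at nominal 5%). In ball mode the same logic applies:
the observed curve is weighted with a field estimated from the
ball-restricted pattern. `reestimate = FALSE` restores the frozen-field
behaviour for comparison with the original construction; at the source
study's scale ($n$ in the thousands, field noise small) the two variants
converge.

### Density homogeneity (Illian F-test)

For two windows with counts $n_1, n_2$ and volumes $v_1, v_2$, the
statistic is reported in the orientation that reproduces the published
per-structure values ($F > 1$ means window 1 denser):

$$F = \frac{v_2\,(2n_1+1)}{v_1\,(2n_2+1)}, \qquad
\text{df} = (2n_1+1,\; 2n_2+1),$$

with a one-sided p from the F distribution. The algebraic reciprocal
(window 2 in the numerator, the form the displayed equation in the source
takes once its `v(2)` typo is read as $v(W_2)$) is returned as `F_alt`;
the product of the two orientations is exactly 1. With equal volumes and
$n_1 = 51$, $n_2 = 43$ this gives $F = 103/87 = 1.18$, df $(103, 87)$,
$p = 0.21$, matching the published GP row. Type-I error is verified at
~5% over 1000 simulated equal-intensity window pairs.
`split_anterior_posterior()` builds the windows: the default split plane
is the volume-median plane perpendicular to the anterior-posterior (Y)
axis, since the source does not state how its sub-windows were defined
(its anterior/posterior comparisons are consequently reproduced in
direction and calibration, not in exact F values).

### Neighbours, clusters, Voronoi territories

* `knn_distances()` returns exact k-nearest-neighbour distances (kd-tree,
  verified against exhaustive comparison), with per-k mean, SD and SE.
* `nn_graph()` joins every point to its nearest neighbour (undirected,
  deduplicated; exact ties resolved to the lowest index so lattice
  fixtures are deterministic) and reports connected components as
  clusters. Because the union of directed NN choices is symmetrised,
  component sizes of 3 and more arise naturally; every component has at
  least 2 members. A mutual-NN-only graph cannot produce size-3
  components, which is why it is not used.
* `noise_robustness()` perturbs coordinates with isotropic Gaussian noise
  and reports the total-variation distance between cluster-size frequency
  distributions. Note that the NN-graph size histogram is nearly
  scale-invariant, so "washout to CSR" is judged against the CSR-vs-CSR
  sampling spread.
* `voronoi_volumes()` assigns voxel centres (default 20 um) to their exact
  nearest generator and counts voxels per cell — a clipping strategy that
  works for arbitrary region shapes, conserves the region volume to
  within the discretisation error (asserted at 1%), and is verified
  against an independent voxel-labelling oracle and against exact
  symmetric configurations. Cells owning a voxel adjacent to the outside
  are flagged `clipped`; `mode = "interior_only"` summarises unflagged
  cells only. Published mean Voronoi volumes are *not* reproduction
  targets: they are inconsistent with volume conservation (CPu mean
  0.002 mm^3 versus $|V|/n \approx 0.0036$ mm^3), implying an unstated
  boundary rule; both summary modes are provided instead.

## Region geometry

Regions are analytic shapes (box, ellipsoid, sphere), voxel masks,
watertight triangle meshes (ASCII PLY/OFF IO), or alpha-complexes built
from the data: `build_region()` runs an internal Bowyer-Watson Delaunay
tetrahedralisation and keeps tetrahedra with circumradius at most `alpha`
(`Inf` = convex hull; volume = sum of retained tetrahedra; boundary =
faces used once). A deterministic symbolic jitter of 1e-8 of the cloud
diameter breaks exact cosphericality (cube corners, lattices); its effect
on volumes is at the 1e-7 relative level. Hull volumes are verified
against an independent computational-geometry implementation. All lengths
are micrometres internally; all volumes are reported in mm^3.

Exclusion zones (axonal bundles) attach to any region as analytic
Y-parallel tubes or voxel masks; membership tests, uniform sampling and
volume computations honour them on request. Boundary points count as
inside everywhere (deterministic tie-break).

## The synthetic data generator

`generate_bilateral_dataset()` emulates the published census: ellipsoidal
fixtures (1:2:1 axes, elongated along the anterior-posterior axis) whose
volumes equal the published per-structure volumes exactly, per-structure
counts as printed (total 13,989; hemispheric difference 557), CPu and NB
with linear anterior-posterior gradients at the published
anterior:posterior ratios (2.10/1.51 and 1.38/2.43, oriented
anterior-dense), the other structures CSR, and somal diameters Gaussian
around the published means (SD 3 um, truncated at the 15 um detection
threshold; the published "± SD" values are SEM-sized, so a realistic
biological SD was chosen once). The gradient generator defines `ratio` as
the anterior:posterior expected count ratio at the axis-midpoint split —
the quantity the published F statistics measure — and calibrates its
linear intensity slope by fixed-seed Monte Carlo quadrature over the
region (slopes that would need negative intensity are truncated at zero).
`generate_bundles()` adds Y-parallel tubes (default radius 100 um) until
the measured excluded fraction is within 1 percentage point of target
(26.81% for the CPu), bisecting the final tube's radius when a whole tube
would overshoot.

What the generator does **not** emulate: true anatomical boundary shapes,
the NB's regularity (its modal cluster size of 3), curved or branching
fibre bundles, somal shapes, or staining artefacts. Passing tests
therefore demonstrate the correctness and calibration of the estimators
under controlled conditions, not the anatomical conclusions themselves.

## Problem sizes used in the test suite

The statistical machinery is validated at reduced scale so the complete
suite runs in minutes on one CPU: envelope coverage with 199 simulations
at $n = 300$ over 200 replicates; rank-test calibration at $n = 80$ with
99 nulls over 200 replicates; the gradient-vs-clustering contrast on a
CPu fixture at $n = 400$, ratio 2.1, over 50 replicates (the homogeneous
pipeline flags clustering while the inhomogeneous one does not reject);
the Illian F-test over 1000 window pairs. Oracle equivalence (K, K_inhom,
k-NN, components, Voronoi) uses 20 random instances each with
$n \le 200$. These sizes were chosen once, for power and runtime, and are
part of the package's study design.

## Known limitations

* The alpha parameter of the boundary reconstruction is data-dependent
  and no default other than the convex hull is offered.
* Voronoi volumes are voxel-limited; halving `voxel_size_um` quarters the
  per-cell error but multiplies memory by 8.
* Mesh regions read from files must be watertight and consistently
  oriented; open meshes are rejected for volume computations.
* The paired-$t$ p-values inherit the autocorrelation caveat above.
* The frozen-field variant of the rank test (`reestimate = FALSE`) is
  anticonservative at small $n$ and is provided for methodological
  comparison only.
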