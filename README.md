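# somaspat

Three-dimensional spatial point-pattern analysis of neuronal soma
distributions.

## What it is for

Whole-structure microscopy can now deliver the 3D coordinates of every
cell of a given type in a brain region — for example, every cholinergic
neuron in the caudate-putamen (CPu), nucleus basalis (NB), globus pallidus
(GP), nucleus accumbens (NA) and septum (S). `somaspat` provides the
statistics needed to turn such a coordinate table into inferences about
spatial organisation:

- **Second-order structure.** The uncorrected 3D Ripley K-function
  `K(r) = |V| Σᵢ Σⱼ≠ᵢ 1[D(i,j) ≤ r] / n²` with Monte Carlo envelopes from
  uniform (CSR) simulations in the same region — observed and simulated
  estimators share the window, count and edge bias, so no edge correction
  is needed for testing. Envelopes can honour *exclusion zones*
  (axonal fibre bundles modelled as tube unions or voxel masks) so the
  null respects the space cells can actually occupy.
- **Gradients vs genuine clustering.** Gaussian-kernel intensity
  estimation (Silverman bandwidth, boundary mass correction), the
  inhomogeneous K-function `K_inhom(r) = Σᵢ Σⱼ≠ᵢ 1[D(i,j) ≤ r]/(λᵢλⱼ)`,
  fixed-count inhomogeneous-Poisson simulation by thinning, and the
  standard 99-realisation Monte Carlo rank test. A density gradient that
  masquerades as clustering under homogeneous K is correctly absorbed by
  the inhomogeneous null.
- **Density homogeneity.** The quadrat F-test
  `F = v₂(2n₁+1) / (v₁(2n₂+1))`, df `(2n₁+1, 2n₂+1)`, for comparing point
  densities of two sub-windows (anterior vs posterior, left vs right),
  plus per-structure and hemispheric density summaries.
- **Neighbourhoods and territories.** Exact k-nearest-neighbour profiles
  with CSR envelopes, the undirected nearest-neighbour graph whose
  connected components define clusters (minimum size 2), cluster-size
  histograms and their robustness to coordinate noise, and 3D Voronoi
  cell volumes clipped to the region.
- **Geometry.** Regions as analytic shapes, voxel masks, watertight
  meshes (ASCII PLY/OFF), or alpha-complexes/convex hulls built from the
  coordinates by an internal 3D Delaunay tetrahedralisation; uniform
  sampling under exclusion constraints; boundary-avoiding ball
  sub-regions.
- **A synthetic-data generator** reproducing the published study
  conditions (per-structure counts and volumes, anterior-posterior
  gradients, ~27% bundle occupancy of the CPu, Thomas-clustered
  alternatives), so the entire pipeline is testable without the original
  microscopy data.

## Worked example

```r
library(somaspat)

gp <- make_region_fixture("GP", "L")     # ellipsoid, published GP volume
cells <- generate_csr(gp, 308, seed = 1) # 308 somata, the published count

env <- csr_envelope(cells, gp, n_sims = 199, seed = 2)
env
#> K-function CSR envelope: 199 simulations, n = 308 points, |V| = 2.74 mm^3
#>   observed K above band at 0 radii, below at 0 of 100
```

The observed K stays inside the pointwise 95% band at all 100 radii: no
evidence against CSR, as expected for a uniform simulation. The paired-t
comparison over the same radii gives `t(99) = -14.79` — an illustration of
why that statistic is reported descriptively: its 100 "observations" are
strongly autocorrelated radii of one curve, so even a null pattern
produces huge |t|. Inference belongs to the envelope and rank tests.

```r
g <- nn_graph(cells)
g
#> nearest-neighbour graph: 308 somata in 91 clusters
#>   cluster-size histogram:
#>  2  3  4  5  6  7  8  9
#> 32 22 21  8  5  1  1  1

knn_distances(cells, 1)$summary$mean_um
#> [1] 121.5
```

Clusters are the connected components of the nearest-neighbour graph:
91 clusters, most of size 2-4, none large — the generic signature of a
random pattern. The mean 1-NN spacing of ~120 µm matches the Poisson
closed form Γ(4/3)·(4πλ/3)^(-1/3) at the GP's density of ~112 cells/mm³.

The gradient-vs-clustering contrast, the core inferential move:

```r
cpu <- make_region_fixture("CPu", "L")
grad <- generate_gradient(cpu, 400, ratio = 2.1, seed = 7)  # no clustering
env <- csr_envelope(grad, cpu, n_sims = 99, seed = 8)
any(env$k_obs > env$k_hi)        # TRUE  -- homogeneous K cries "clustering"
inhom_analysis(grad, cpu, use_ball_subregion = TRUE, seed = 9)$p
# > 0.05 -- the inhomogeneous null explains it
```

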