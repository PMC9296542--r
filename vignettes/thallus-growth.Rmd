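---
title: "Modelling thallus growth and branching angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thallus growth and branching angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thallus)
```

## The growth model

The vegetative body (thallus) of a filamentous fungus such as *Podospora
anserina* grows by two elementary processes: apical growth, in which each
hyphal tip (apex, a degree-one vertex `V1`) extends, and branching.  The
package models the thallus as a lattice-free planar network built as a
*full binary tree*: at every growth pass each apex divides into exactly
two daughter branches, creating a degree-three vertex `V3`.  The two
daughters are not equivalent.  The *exploratory* branch deviates from the
extension of the mother hypha by a small angle $\theta_e$ and perpetuates
its direction (colonization of new territory); the *operating* branch
deviates by a wide angle $\theta_o$ and densifies the neighbourhood
(exploitation of captured territory).

Growth starts from a germinating ascospore as `nGerm = 3` branches
separated by about 120 degrees, the configuration seen at germination.
Generation `g = 2` denotes this germination state (3 apexes, no
branchings), so after `g - 2` passes a purely apical network carries
exactly $N_{V1} = 3 \cdot 2^{g-2}$ apexes and $3\,(2^{g-1} - 1)$
segments.

The random elements are:

* **Branch lengths** follow a Gamma law with shape $k$ and scale
  $\theta$ (mm).  Special cases: $k = 1$ is the exponential law,
  $k = 3/2$, $\theta = 2a^2$ the Maxwell–Boltzmann law, and
  $\theta = 2$ the chi-square law.  Defaults $k = 3$,
  $\theta = 0.2/3$ mm give a mean inter-vertex length of 0.2 mm, the
  order observed in the exponential growth phase (about 600 mm of
  network per ~1500 apexes gives $r_1 \approx 0.4$ mm, i.e.
  $\langle\ell\rangle \approx 0.2$ mm).
* **Branching angles** are Gaussian.  Defaults use the measured apical
  populations: $\theta_e = 10^\circ$ ($\sigma_e = 8.7^\circ$) and
  $\theta_o = 71^\circ$ ($\sigma_o = 12^\circ$).  A Bernoulli draw
  (`apicalSideProb`, default 1/2) decides which side of the mother's
  extension carries the operating branch, so no chirality is imposed.
  By default the exploratory daughter deviates on the *opposite* side,
  which is the configuration the direct measurements show (wide angle
  positive, small angle negative); `apicalSameSide = TRUE` places both
  daughters on the same rotation sense (see the occupancy section).
* **Lateral branching**: a segment bounded by two existing vertices can
  additionally spawn a side branch at a later pass, creating a `V3l`
  branch point and a `V1l` apex.  The per-pass probability is the power
  law $p = p_0 (x/x_0)^\alpha$ of the current segment length $x$, with
  defaults $p_0 = 1/2$, $\alpha = 2$ and $x_0 = k\theta +
  3\sqrt{k}\,\theta$ (the largest length the Gamma law realistically
  draws), recomputed after every generation.  The branching point is
  uniform along the segment outside a censorship zone covering 10% of
  the length at each end (the law names the zone but not its extent;
  one tenth keeps branch points visibly separated from vertices at
  every scale).  Lateral angles and lengths reuse the operating laws.

Lateral apexes keep branching apically, and their whole lineage keeps
the lateral kinds (`V3l` branch points, `V1l` apexes).  Two invariants
follow for every seed: the apical apex count is exactly
$3 \cdot 2^{g-2}$ whether or not lateral branching is enabled, and
$N_{V1l} = N_{V3l}$ always.

Curvature is deliberately absent: the mean curvature between vertices is
locally zero in the data, so segments are straight and any global
curvature effect can be re-introduced by biasing the side probabilities.
Velocities are stored only as annotations; one generation is one nominal
time step, and mapping to real hours is the calibration's job.

## The observation layer

Measurements never see the true network; they see its convolution with
the acquisition chain.  `observeThallus()` applies, in order: an
isotropic Gaussian position blur (`resolutionSigma`, default half a
hyphal width); detection of *geometric crossings* — pairs of branches
that properly cross in the 2D projection, each reconstructed as
`crossingMultiplicity = 2` apparent 3-degree vertices (`V3i`) unless a
rare hyphal fusion records it as a single `V3o`
(`fuseProb`, default 0: anastomosis is marginal); merging of apexes
that pass within `mergeDistance` (default one hyphal width) of a
non-incident branch, each removed from the observed apexes and counted
as one more `V3i`; and Poisson ghost vertices (`ghostRate`, default 0).
With all artifact parameters zero the observation is the identity on
counts, which the tests assert.  The realized decomposition
$N_{V1ob} = N_{V1} + N_{V1l} + N_{V1g} - \text{merged}$ is reported
directly rather than through free artifact coefficients.

## Calibration

Observed series of apex counts, 3-degree counts and total length grow as
a base-2 exponential $X(t) = X_0\,2^{(t+t_0)/\tau}$ during the
exponential phase.  With the temporal offset $t_0$ fixed, the weighted
least-squares fit is linear in the log2 domain; weights map relative
uncertainties as $\sigma/(X \ln 2)$ and are rebuilt once from the fitted
curve (weights built from the observed counts correlate with their own
noise and understate the covariance — the reweighting restores the
nominal coverage of the confidence intervals, which a simulation test
verifies on Poisson-noised series).  Points outside a fit window
(default 2–15 h) are excluded as lag-phase or post-exponential.  The
3-degree count, dominated by crossings, is fitted with a first-order
polynomial correction $2^{(t+t_0)/\tau}(c_0 + c_1 t)$, and a bounded
saturating law $1/(b + c\,2^{-at})$ is available for long times; while
$c \gg b$ it reduces to the binary-tree law.  `scanT0()` automates the
manual offset adjustment by scanning a grid and keeping the offset whose
onset amplitude lands nearest its expected value (about 3 apexes, about
1 branch point, 10–20 hyphal diameters of length).  Both the total and
reduced chi-square are reported, since published goodness-of-fit values
do not state which convention they use.

`timeScaleMap()` equates fitted data and simulation laws,
$(A 2^{at})_{data} = (A 2^{at'})_{sim}$, giving the linear clock map
$t' = (\tau_{sim}/\tau_{data})\,t + \tau_{sim}\log_2(A_{data}/A_{sim})$.
The space scale uses the length-per-apex ratio $r_1 = L/N_{V1ob}$, which
plateaus at $\langle\ell\rangle (2 - 2^{2-g})(1+p)/(1+2p)$ for deep
trees; the measured lateral fraction `p` is defined as lateral-origin
drawn branches per apical-origin drawn branch, the estimator under which
the plateau form is exact to $O(1/N)$ in this generator.  Cloud shape is
summarized by the inertia tensor of the vertex positions and its
sphericity $s = 2\lambda_2/(\lambda_1+\lambda_2)$ (1 disk-like, 0
collinear), with bootstrap uncertainties; the apex-cloud sphericity of
isotropic germinations is stationary across the developed generations.

## Why two distinct angles: the occupancy argument

At fixed total length $L$ the thallus covers the ribbon area
$S_{bio} = L\,w$ minus whatever overlaps itself:
$S_{occ} = S_{bio} - N_{V3i}\,\Delta S$.  Two constant-width ribbons
crossing at angle $\phi$ overlap in a rhombus of area $w^2/\sin\phi$;
the package caps this at $w\,\min(\ell_a, \ell_b)$, the ribbon area
available at grazing incidence, and pairs that are exactly parallel and
stacked contribute the $\phi \to 0$ limit $(w - d)\,\ell_{overlap}$.
The stacked term matters because the sweep uses a deterministic toy
geometry — equal branch lengths, zero angle variance — in which two
branching orders that commute place branches exactly on top of one
another; without it the most degenerate angle pairs would spuriously
score as the least overlapping.

`sweepOptimize()` grows networks to nine generations over a grid of
angle pairs (the same seed set in every cell), averages the overlap
measure, smooths with a 3×3 cell window and reports the grid minimum.
Two conventions were examined for the toy.  With opposite-side
daughters the measure is symmetric under swapping the two angle labels
(the swap merely mirrors the ensemble), so it cannot single out a
(wide, small) pair; its minimum sits near equal moderate angles.  With
both daughters on the same rotation sense, equal angle means collapse
the two daughter sub-trees onto each other and the measure rises
steeply along the diagonal and along $\theta_e = 0$ (where commuting
branching orders stack branches), leaving a clear interior minimum at a
wide angle near 70–80 degrees and a small angle near 10–15 degrees —
the configuration in which exploration keeps its direction while the
operating branches fill the space between the exploratory rays.  The
sweep therefore defaults to `sameSide = TRUE`, while the data-facing
generator keeps the measured opposite-side convention; since the
operating branch is by definition the wider-angled one, the minimum is
located on the $\theta_o > \theta_e$ wedge of the grid.

## Measuring angles on observed material

Two measurement pipelines mirror the two experimental protocols.

**Direct circle method.**  A circle of radius five hyphal widths is
centred on an apical branching; the intersections of the circle with
the mother path and the two daughter paths give, relative to the
extension of the mother, a signed small angle and a signed wide angle
(the wide angle fixes the positive rotation sense).  Vertices whose
circle is crossed by a non-incident branch, or whose daughters end
inside the circle, are skipped with a flag — the same clean-vertex
selection the manual protocol applies.  Per-experiment Gaussian
population fits deconvolve the measurement error
($\delta\theta = 4^\circ$, set by the hyphal diameter) from the
width, and quote the mean uncertainty with the systematic folded in,
$\sqrt{\delta\theta^2 + \hat\sigma^2/n}$.  `combineEstimates()` pools
experiments as i.i.d. estimates: simple average of means, mean
uncertainty over $\sqrt{n}$ as the statistical part, and the
systematic re-folded for the total (inverse-variance weighting is
available but the simple average is the reference behaviour).

**Raster (GIS) method.**  The simulated network is rasterized as
constant-width ribbons (5 px per hyphal width by default), thinned to a
one-pixel centreline (Zhang–Suen passes followed by a connectivity-safe
removal of the two-pixel staircases thinning leaves on diagonals), and
pruned: spurs shorter than `prunePx` and centreline tips inside the
boundary-erosion zone (`trimErosionPx`) are removed, which slightly
shortens the apexes, as in the original geoprocessing.  Endpoints
become observed apexes `V1ob`; branch pixels are dissolved within a
2-px radius into observed branch points `V3ob`, with multi-arm
crossing blobs flagged.  Discs centred on the vertices are split by the
skeleton; by default each arm inside the disc is fitted with a
total-least-squares line, the branching point is re-estimated as the
least-squares intersection of the arm lines, and the arcs between
consecutive arm directions are the angle samples.  The correction step
exists because thinning displaces a junction's triple point toward the
narrowest inter-arm wedge by about half a ribbon width; raw sector
areas measured about the displaced point squeeze large arcs toward the
middle of the spectrum (the pure area estimator remains available as
`method = "area"`).  A clean apex contributes a single 360-degree
sample; vertices closer than `minSeparationPx` and multi-arm blobs are
flagged, and flagged samples are excluded from the spectrum fit by
default since they are dominated by geometric-crossing artifacts.

The angular spectrum inside a window excluding the 0/360-degree
artifact peaks is fitted by three Gaussians of which the third is fully
constrained by circle closure: $\mu_3 = 360 - \mu_1 - \mu_2$, width
$\sqrt{w_1^2 + w_2^2}$ (the daughters' arc is the sum of two deviations,
so its width adds in quadrature; the closure constraint fixes only the
mean), amplitude free.  Initialization tries pairs drawn from histogram
peaks padded with sample quantiles, prefers converged candidates whose
free means lie in the mother-arc range (90°, 180°), and keeps the best
chi-square.  `resolveScenario()` applies the unique geometric reading:
the free means are the mother–daughter arcs, so
$\theta_e = 180^\circ - \max(\mu_1, \mu_2)$ and
$\theta_o = 180^\circ - \min(\mu_1, \mu_2)$, with the plausibility
check $0 < \theta_e < \theta_o < 90^\circ$ enforced and all three
candidate assignments reported on failure.

## What the synthetic generator does and does not emulate

The generator reproduces the network topology and geometry of the
exponential growth phase: binary apical branching, power-law lateral
branching, the measured angle laws, germination geometry, and (through
the observer) the artifact structure of the imaging chain.  It does not
model nutrient fields, tropisms, hyphal death, growth interruption
during branching, curvature, three-dimensional growth, or the
deceleration and stationary phases; and real micrograph binarization
is out of scope (masks enter as clean ribbons).  Passing tests
therefore validate the algorithms against the model's own ground truth,
not against biological images; in particular the raster pipeline's
accuracy is quoted for ribbon masks of known width, and the crossing
density of the toy thallus (segment length 0.2 mm inside a ~1–2 mm
canvas) is higher than in a spread-out Petri-dish thallus, which is why
flag-based exclusion of crossing artifacts matters more here than in
the original workflow.

## Numerical choices and problem sizes

* Crossing detection treats pairs with $|\sin\phi| \le 10^{-9}$ as
  parallel and endpoint contacts as non-crossings (branching points are
  shared vertices, never geometric crossings); the exact brute-force
  oracle used in the tests works on integer coordinates where every
  predicate is exact in double arithmetic.
* The sweep is evaluated at 5-degree spacing over
  $\theta_o \in [10, 90]$, $\theta_e \in [0, 60]$, nine generations,
  with 16 seeds per cell in the test suite and 32 in the reproduction
  script (ties broken toward larger $\theta_o - \theta_e$); property
  tests use coarser grids and fewer seeds.
* Raster tests run at generations 6–7 (canvases of roughly a thousand
  pixels square); the spectrum fit requires at least 200 in-window
  samples and is binned at 10 degrees, giving about 30 degrees of
  freedom.
* Direct-measurement recovery simulates triples of experiments with two
  fields of view each, pooling the clean vertices; growth-curve
  recovery uses series of 27 time points over 2–15 h with Poisson
  noise, 100 replicates.
* Every stochastic routine takes a seed and derives internal seeds below
  $2^{31}$; identical seeds give byte-identical networks.

## Known limitations

* The occupancy optimum is a shallow basin: the reported grid minimum
  wobbles by one 5-degree cell between seed sets at 10 seeds per cell;
  16 or more seeds per cell stabilize it.
* The raster pipeline's small-angle estimate retains a positive bias of
  a few degrees at realistic angle variance (near-collinear
  mother/exploratory arms are the hardest configuration for any
  centreline method); the original automatic measurements show the same
  direction of disagreement with the direct protocol, far more
  strongly.
* SWC export cannot carry branch types, generations or split branch
  identities; the CSV pair preserves them.
* The saturating growth law is fitted only as a check of the
  exponential regime; the deceleration and later phases are out of
  scope.
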