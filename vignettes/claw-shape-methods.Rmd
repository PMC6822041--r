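---
title: "Claw shape, ecology, and phylogeny: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claw shape, ecology, and phylogeny: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`clawmorph` analyzes the shape of avian pedal claws — the internal bony
core (the ungual) and the keratinous sheath that envelops it — and asks
whether shape tracks coarse ecological mode (predatory, ground-dwelling,
flying generalist) once body size and phylogenetic relatedness are
controlled. This vignette is the package's own account of the models it
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices a
maintainer should know about. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The two measurement traditions

**Traditional arc protocol.** Seven points are taken per claw: the tips of
the sheath and core, the midpoint of the crescent-shaped articulation
surface, the dorsal lips of core and sheath, and approximate midpoints of
the two dorsal arcs. Each dorsal arc angle is the central angle of the
circumcircle through (lip, arc midpoint, tip), with the arc chosen through
the midpoint — an explicit "through" point rather than an orientation
convention, so measurements are invariant under rigid motion and
reflection-free digitization order. Structure lengths are arc lengths on
the circle through (articulation midpoint, arc midpoint, tip); a
chord-length alternative is available (`length_method = "chord"`) because
the original protocol's supplementary definition is not restated in the
main text. The core/sheath length ratio is dimensionless and
scale-invariant. The protocol assumes the dorsal surfaces inscribe
circles; the generator can violate this deliberately (below).

Near-flat claws (ground birds) approach collinearity; the circle fit
rejects triples whose doubled triangle area falls below 1e-9 times the
squared largest pairwise distance, and batch measurement
(`measure_claws()`) excludes such specimens with a logged warning rather
than aborting, so simulated and analyzed specimen counts always
reconcile.

**Geometric morphometrics.** 83 landmarks per claw in a fixed canonical
order: LM1–LM6 (fixed), then the dorsal bony core (13 semilandmarks),
ventral bony core (18), dorsal keratinous sheath (28), ventral keratinous
sheath (18). Core curves precede sheath curves so the conventional module
index sets (core = {1,2,3,4} ∪ 7–37; sheath = {5,6} ∪ 38–83) are literally
true. All user-facing indices are 1-based.

## 2. Superimposition and sliding

GPA centers each configuration, scales it to unit centroid size, and
iteratively rotates to the running mean (rotations only, determinant +1:
radiographs digitized from either side should be reflected explicitly via
`allow_reflection`, not silently). Convergence is declared when the mean
moves less than `tol` (default 1e-8), but iteration continues to 1e-14 so
the fixed point — after a canonical final rotation (principal axis of the
mean along x, farthest landmark on positive x) — is independent of input
order and of rigid motion plus scaling of any input. Claw samples converge
in under ten iterations; weakly structured (random) configurations can
need several hundred, hence `max_iter = 1000` rather than a conventional
100. Analyses operate on Procrustes-aligned coordinates without an
explicit tangent-space projection; at the shape variation scale of claws
the difference is far below the statistical noise.

A note on centroid size: the traditional literature sometimes describes CS
via "the sum of squared interlandmark distances". The two definitions
differ by the constant factor √k (k = 83); we implement the standard
centroid size (root summed squared distances from the centroid), and all
downstream uses are scale-free or log-linear, so the constant is
irrelevant.

**Sliding semilandmarks.** Per outer iteration (default 3), each
specimen's semilandmarks slide along tangent directions (central
differences of curve neighbours, with the curve's fixed endpoints as
terminal neighbours) to minimize the bending energy of the thin-plate
spline from the current grand mean to the specimen; the slide amounts
solve the tangent-basis generalized least squares problem in closed form.
Kernel: U(r) = r² log r² with U(0) = 0; the bending-energy matrix is the
upper-left block of the inverse bordered TPS system and annihilates affine
deformations. Fixed landmarks never move; sliding is strictly 2D.

The raw closed-form minimizer is untrustworthy far from the current
configuration: bending energy is indifferent to near-affine collective
slides, and the tangent-line linearization of the curve only holds
locally, so the unconstrained step can drift semilandmarks many
inter-landmark spacings and destabilize the outer loop. We therefore cap
each specimen's step at one tenth of the median neighbour half-spacing;
scaling the exact minimizer by any factor in (0, 1] still strictly
decreases the quadratic energy, so the within-iteration descent guarantee
is preserved, and empirically the post-slide total energy is monotone
across outer iterations (audited in the acceptance tests). Degenerate
tangent systems fall back to a zero slide with a warning.

## 3. Statistical models

All permutation and simulation tests use the (count + 1)/(n + 1) p-value
convention, mandatory seeds recorded in their results, and n_perm = 999 /
n_sim = 1000 defaults.

* **PGLS with ML Pagel's λ** — for a fixed λ the GLS estimator uses the
  λ-transformed phylogenetic covariance (off-diagonals scaled, tip
  variances kept); the profile log-likelihood (ML variance, not REML) is
  maximized over [0, 1] by bounded scalar optimization (tolerance 1e-6)
  plus endpoint checks. R² compares the GLS residual sum of squares with
  the intercept-only GLS fit at the same λ̂. Factors are dummy-coded;
  coefficient p-values use t statistics on n − p degrees of freedom.
* **Phylogenetic ANOVA** — observed one-way F on species means; the null
  is built by simulating Brownian motion on the tree at the trait's ML
  rate. Pairwise t statistics are referred to their simulated nulls with
  Holm correction.
* **K_mult** — the multivariate Blomberg's K generalization, exactly 1 on
  a star phylogeny and ≈1 in expectation under Brownian motion; permuting
  tip rows gives its null.
* **Phylogenetic Procrustes ANOVA** — shapes and design are transformed by
  the symmetric inverse square root of the phylogenetic covariance
  (eigendecomposition, eigenvalues clipped at 1e-12 × trace — symmetric
  rather than Cholesky so the transform is rotation-consistent across
  permutations), with sequential (type-I) sums of squares, covariate (log
  centroid size) entered before group, Goodall-style F summed over all
  shape dimensions, and RRPP: each term's null permutes the residual rows
  of its reduced model. Pairwise group differences are distances between
  size-adjusted group GLS means against the same permuted distribution.
  The shape model uses the Brownian covariance by default; a λ-transformed
  covariance can be supplied instead via `lambda_transform()`.
* **Disparity** — Procrustes variance with divisor n_g (not n_g − 1),
  matching the convention of the comparative-morphometrics literature this
  package follows; group labels are permuted for pairwise |ΔPV| tests.
* **CR modularity** — covariance ratio on the (evolutionary, when a tree
  is supplied) covariance of flattened coordinates, with each within-module
  per-landmark 2×2 block zeroed so CR ignores within-landmark variance.
  The null reassigns whole landmarks (x,y pairs) to modules of the
  original sizes; modularity is supported when CR sits in the lower tail.
* **Two-block PLS** — SVD of the cross-block evolutionary covariance;
  r-PLS is the correlation of the paired first scores of GLS-transformed
  centered blocks. The permutation scheme permutes the tip rows of one
  block (the standard scheme; the originating description's "permuting
  landmarks" phrasing is read this way, as landmark-level permutation
  would break the paired structure the statistic depends on). Effect sizes
  are standardized positions of the Fisher-z-transformed observed
  correlation within its permuted null.
* **compare_pls** — pairwise |Δ(z_obs − mean z_null)| / √(sd₁² + sd₂²)
  with a two-sided normal p. This normal approximation is well calibrated
  when the compared integrations are weak or absent, and grows
  anticonservative as the common true integration strengthens (the
  permutation null then understates the sampling variance of the observed
  correlation); treat strong-integration comparisons as descriptive.
* **Phylogenetic paired t** — ML λ for the paired difference, GLS mean,
  and t = μ̂ / √(σ̂²_ML · n/(n−1) · (1ᵀC_λ̂⁻¹1)⁻¹) on n − 1 degrees of
  freedom; exactly the ordinary paired t on a star tree.

A deliberate spec-level correction: the claim that any full-rank linear
map between blocks yields r-PLS = 1 is false (PLS maximizes covariance,
not correlation); exactness holds for similarity maps, which is what the
"perfect integration" tests use.

## 4. The synthetic world

`make_claw()` builds claws from exact nested circular arcs, so the
traditional protocol's inscribed-circle assumption holds by construction:
the dorsal sheath arc has angle θ_sheath and radius R; the dorsal core arc
is concentric with angle θ_core and radius chosen so its arc length is
`length_ratio` times the sheath's; ventral curves offset inward by
base_width · (1 − s)^taper along arc fraction s, meeting the tips; all
semilandmarks are placed at equal arc-length spacing. The articulation
midpoint is placed on the core circle, proximal of the dorsal lip, by a
one-dimensional root solve so that the *protocol's* arc-length ratio
equals the requested `length_ratio` exactly — noise-free claws therefore
recover all three traditional metrics to 1e-6 through the full
extract/measure path. Isotropic Gaussian landmark noise and a random rigid
motion plus scale (±20% log-uniform) complete a specimen.

Noise propagation is worth stating plainly: the three-point circle fit
amplifies landmark noise by roughly 420° of core arc per unit of noise at
the default geometry, so digitization noise of 0.005·R yields a per-claw
arc standard deviation of 2–3° — which is what published intraspecific
confidence-interval widths (about 2.6–7° for the core arc at n ≈ 20)
imply for real radiograph digitization, and why 0.005 is the scenario
default. Claims of sub-2° recovery at this noise level are not attainable
with the seven-point protocol; the tests verify the linear error scaling
and the 2°/95% bound at 0.002.

`scenario()`/`simulate_dataset()` emulate the sampling design of a
paper-scale claw study: 145 species, 4 specimens each (580 total), a
pure-birth tree rescaled to unit depth, species parameters
(θ_sheath, θ_core, length_ratio, log size) evolving under correlated
Brownian motion with Pagel's λ = 0.7, three ecological groups with
arc-only mean shifts (ground 75°, flying 105°, predatory 150° of sheath
arc; core kept at the 0.72 proportion; no length-ratio shift, consistent
with the non-significant ecological signal in the ratio), weak allometry
(6°/4° of sheath/core arc per unit log size; log-size tip sd 0.8, spanning
roughly ±2 orders of magnitude of mass via the size proxy), and
intraspecific parameter noise (8° sheath arc per specimen) large enough
that within-species spread rivals between-species spread within a group.
Two structural choices deserve emphasis:

* *Within-specimen arc noise is correlated (ρ_block, default 0.9).* The
  core is physically nested in the sheath, so a specimen with a more
  recurved sheath has a correspondingly recurved core. With independent
  within-specimen arc noise, relative core-radius mismatch becomes the
  dominant principal component of species-mean shape — contradicting the
  strong core–sheath integration (r-PLS ≈ 0.98) the suite is designed to
  detect.
* *Group assignment is clade-biased by default* (`group_rule = "clade"`):
  predatory and ground species are drawn from single clades, mimicking
  real datasets where predatory birds are mostly one order. Shared
  Brownian drift of those clades then rotates the group axis away from
  PC1 in roughly one seed in ten — the same phylogenetic confounding real
  studies report — so the acceptance check of PC1 group ordering uses
  `group_rule = "random"`, which isolates the ordering question from
  clade drift.

What a green test does *not* establish: the generator's claws are exact
circular arcs (real claws are not — set `spiral`-like violations by
varying taper and ratio, or extend the generator), its noise is isotropic
and Gaussian, group differences are pure mean shifts, and evolution is
homogeneous-rate Brownian with a single λ. Conclusions about real
radiographs require the real data.

## 5. Numerical choices and degenerate inputs

* Collinearity tolerance 1e-9 (relative) in circle fitting; arc endpoints
  coinciding with the "through" point are errors, not guesses.
* Circle-equidistance precondition for arc angles: all three points within
  1% of the mean radius.
* Phylogenetic covariances are validated symmetric PSD; inverse square
  roots clip eigenvalues at 1e-12 × trace; Cholesky failures surface as
  "singular phylogenetic covariance" errors rather than silent fallbacks.
* Pruning a tree keeps the basal path above the retained clade as a root
  edge (added back by `phylo_covariance()`), so pruning never changes the
  covariance structure among retained tips.
* PCA axis signs are fixed by making each component's largest-magnitude
  loading positive; permutation p-values are bit-reproducible given
  (seed, n_perm, input order).
* λ̂ recovery (mean absolute error < 0.15 at λ ∈ {0, 0.5, 1} on 128-tip
  trees) and slope recovery (mean within 0.05) are audited in the
  acceptance tests at exactly those settings.
* Confidence intervals for traditional metrics are t-based by default
  (`ci_method = "percentile"` for the empirical alternative).

## 6. Known limitations

Two-dimensional shapes only (real claws are 3D; lateral projections lose
mediolateral asymmetry); no missing-landmark estimation; no OU or
early-burst models; the traditional protocol's length definition follows
the arc-through-articulation reading of the original supplementary
protocol, with chord lengths as an explicit alternative rather than a
default; and `compare_pls` inherits the anticonservatism of the
effect-size comparison under strong common integration, as noted above.
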