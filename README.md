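# clawmorph

Quantifying avian pedal claw shape — the bony core and its keratinous
sheath — and testing how shape relates to ecology once body size and
phylogeny are accounted for.

Bird claws have long been used to infer the ecology of extinct taxa from
claw geometry, usually through "traditional" arc measurements that treat
the dorsal claw surface as a circular arc. `clawmorph` implements, in one
tested toolchain, both measurement traditions and the comparative
statistics needed to interpret them:

* **Traditional protocol** — seven named points per claw; the inscribed
  circle of the dorsal bony core and of the keratinous sheath; the central
  angles of their dorsal arcs (claw arc, in degrees: higher = more
  recurved) and the core-to-sheath arc-length ratio.
* **Geometric morphometrics** — an 83-point landmark scheme (6 fixed
  landmarks + 77 semilandmarks in four curves covering the dorsal/ventral
  bony core and keratinous sheath), generalized Procrustes analysis (GPA),
  and sliding of semilandmarks by the thin-plate-spline bending-energy
  criterion.
* **Phylogenetic comparative statistics** — PGLS with maximum-likelihood
  Pagel's λ; simulation-based phylogenetic ANOVA with pairwise tests;
  multivariate phylogenetic signal K_mult; phylogenetic Procrustes ANOVA
  (GLS + residual randomization, RRPP); Procrustes-variance disparity; the
  covariance-ratio (CR) modularity test; phylogenetic two-block partial
  least squares (r-PLS) with effect-size comparison across groups; and a
  phylogenetic paired *t* test.
* **Synthetic ground truth** — a parametric claw generator (nested
  circular arcs with specified arc angles and length ratio), pure-birth
  trees, Brownian-motion species means with tunable λ, three ecological
  groups with shifted mean arcs, weak allometry, and realistic
  intraspecific noise, so every stage is testable without any downloads.

In the field's notation: centroid size is CS = √Σᵢ‖xᵢ − x̄‖²; the PGLS
estimator is β̂ = (XᵀC_λ⁻¹X)⁻¹XᵀC_λ⁻¹y with C_λ the λ-transformed
phylogenetic covariance; K_mult = [tr(EᵀE)/tr(EᵀC⁻¹E)] /
[(tr C − n/(1ᵀC⁻¹1))/(n−1)]; CR = ‖S₁₂‖_F / √(‖S₁₁°‖_F‖S₂₂°‖_F); and
r-PLS is the correlation of the paired first singular-vector scores of the
cross-block evolutionary covariance.

## Worked example

Measure a synthetic claw with known geometry, then run a reduced
end-to-end study (40 species, 160 specimens, 199 permutations):

```r
library(clawmorph)

cl <- make_claw(claw_params(theta_sheath = 105, theta_core = 76,
                            length_ratio = 0.70), seed = 42)
measure_claw(extract_seven_points(cl$config))
#> arc_measurement: core 76.00 deg, sheath 105.00 deg, length ratio 0.7000

cfg <- run_config(scenario = scenario(n_species = 40, specimens_per_species = 4),
                  n_perm = 199, n_sim = 200, seed = 7)
report <- run_pipeline(cfg)
report
#> study_report: 160 specimens, 40 species (0 excluded)
#>   K_mult = 0.155 (p = 0.015); allometry R2 = 0.322 (p = 0.005)
#>   core~sheath PGLS: lambda = 0.306, m = 0.931, R2 = 0.941
#>   CR = 1.011 (p = 0.01); core-sheath r-PLS = 0.994 (p = 0.005)
```

Reading the numbers: the noise-free claw measurement recovers the
generator's arc angles and length ratio exactly (the inscribed-circle
assumption holds by construction). In the simulated study, claw shape
carries phylogenetic signal (K_mult > 0, permutation p < 0.05, though well
below the Brownian expectation of 1 because intraspecific noise dilutes
species means); the sheath arc tracks the core arc almost linearly on the
log scale (PGLS slope m near 1, high R²); the core and sheath are strongly
integrated (r-PLS near 1) and do *not* form separate modules (CR near 1,
lower-tail p not small — here p = 0.01 reflects the mild extra within-curve
covariance of the generator); and the phylogenetic paired *t* test (in
`report$core_sheath$paired_t`) confirms the sheath arc exceeds the core
arc. `report$gm$pca_species` holds the morphospace summary used to inspect
ground → flying → predatory ordering along PC1.

Every number above is computed by the code in this repository; seeds make
runs bit-reproducible.

## Command line

```sh
Rscript -e 'clawmorph::cli_main()' simulate --species 30 --specimens 3 --seed 1 --out data/
Rscript -e 'clawmorph::cli_main()' measure  --tps data/claws.tps --metadata data/metadata.csv --out trad.csv
Rscript -e 'clawmorph::cli_main()' gpa      --tps data/claws.tps --out aligned.csv
Rscript -e 'clawmorph::cli_main()' analyze  --species 30 --n-perm 199 --seed 1 --out report/
```

## Layout

* `R/` — implementation (data model and TPS/Newick I/O, arc protocol, GPA
  and sliding, shape statistics, phylogenetic statistics, modularity and
  integration, synthetic data, pipeline, CLI)
* `tests/testthat/` — unit, property, and acceptance tests
* `vignettes/claw-shape-methods.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
* `scripts/acceptance.R` — acceptance report entry point
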