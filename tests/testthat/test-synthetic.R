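# Synthetic-data generator: claw outlines, trees, Brownian traits, and the
# full scenario simulator.

test_that("make_claw is reproducible and noise-free claws align exactly", {
  p <- claw_params(theta_sheath = 105, theta_core = 76, noise_sd = 0)
  a <- make_claw(p, seed = 1)
  b <- make_claw(p, seed = 2)
  # identical geometry up to the random placement: align the pair
  arr <- array(NA_real_, c(2, 83, 2))
  arr[1, , ] <- a$config$coords; arr[2, , ] <- b$config$coords
  s <- gpa(arr, tol = 1e-12)
  expect_lt(procrustes_distance(s$aligned[1, , ], s$aligned[2, , ]), 1e-8)
  expect_identical(make_claw(p, seed = 5)$config$coords,
                   make_claw(p, seed = 5)$config$coords)
  expect_error(claw_params(theta_sheath = 5), "\\[10, 350\\]")
  expect_error(claw_params(length_ratio = 0.1), "\\[0.3, 1.1\\]")
  expect_error(make_claw(claw_params(base_width = 0.95), seed = 1),
               "impossible")
})

test_that("arc recovery degrades linearly with digitization noise", {
  # The three-point circle fit amplifies landmark noise by a fixed factor
  # (about 420 degrees of core arc per unit of noise at these defaults), so
  # recovery error sd should scale linearly with noise_sd, and at
  # noise_sd = 0.002 essentially all draws recover both arcs within 2
  # degrees. (At the more realistic within-specimen level of 0.005 the arc
  # sd is 2-3 degrees, matching published intraspecific spreads.)
  err_at <- function(ns, n_try, seed0) {
    vapply(seq_len(n_try), function(i) {
      cl <- make_claw(claw_params(noise_sd = ns), seed = seed0 + i)
      m <- tryCatch(measure_claw(extract_seven_points(cl$config)),
                    error = function(e) NULL)
      if (is.null(m)) return(c(NA, NA))
      c(m$core_arc_deg - cl$truth$core_arc_deg,
        m$sheath_arc_deg - cl$truth$sheath_arc_deg)
    }, numeric(2))
  }
  e_small <- err_at(0.002, 150, 7000)
  hit <- mean(abs(e_small[1, ]) < 2 & abs(e_small[2, ]) < 2, na.rm = TRUE)
  expect_gte(hit, 0.95)
  e_big <- err_at(0.004, 150, 9000)
  ratio <- sd(e_big[1, ], na.rm = TRUE) / sd(e_small[1, ], na.rm = TRUE)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})

test_that("simulate_tree yields unit-depth ultrametric Yule trees", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:2]), c(1, 1))
  tr64 <- simulate_tree(64, seed = 2)
  expect_equal(unname(diag(phylo_covariance(tr64))), rep(1, 64),
               tolerance = 1e-10)
  expect_error(simulate_tree(1, seed = 1), "at least 2")
  expect_identical(ape::write.tree(simulate_tree(16, seed = 9)),
                   ape::write.tree(simulate_tree(16, seed = 9)))
})

test_that("simulated tree imbalance is consistent with the Yule process", {
  # oracle: independent forward-in-time Yule topology sampler
  n_trees <- 250L; n_tips <- 32L
  set.seed(99)
  oracle <- vapply(seq_len(n_trees), function(i) yule_topology_oracle(n_tips), 0L)
  obs <- vapply(seq_len(n_trees), function(i)
    colless_of_tree(simulate_tree(n_tips, seed = 5000 + i)), 0L)
  se <- sqrt(var(oracle) / n_trees + var(obs) / n_trees)
  expect_lt(abs(mean(obs) - mean(oracle)), 4 * se)
})

test_that("simulate_bm_traits has the requested moments", {
  tr <- simulate_tree(8, seed = 3)
  X <- simulate_bm_traits(tr, c(5, -2), matrix(0, 2, 2), 1, seed = 1)
  expect_equal(unname(X), matrix(c(5, -2), 8, 2, byrow = TRUE))
  expect_error(simulate_bm_traits(tr, 0, matrix(-1, 1, 1), 1, 1),
               "semi-definite")

  # Monte-Carlo: tip covariance matches sigma2 * C entrywise within 10%
  C <- phylo_covariance(tr)
  sig2 <- 0.8
  reps <- 2000L
  draws <- vapply(seq_len(reps), function(i)
    drop(simulate_bm_traits(tr, 0, matrix(sig2), 1, seed = 10000 + i)),
    numeric(8))
  Chat <- tcrossprod(draws - rowMeans(draws)) / (reps - 1)
  scale_ref <- sig2 * max(C)
  expect_lt(max(abs(Chat - sig2 * C)), 0.1 * scale_ref)

  # lambda = 0 destroys phylogenetic signal
  tr64 <- simulate_tree(64, seed = 4)
  C64 <- phylo_covariance(tr64)
  ks <- vapply(1:200, function(i) {
    y <- simulate_bm_traits(tr64, 0, matrix(1), lambda_true = 0, seed = 300 + i)
    k_mult(y, C64, n_perm = 0, seed = 1)$statistic
  }, 0)
  expect_lt(mean(ks), 0.5)
})

test_that("simulate_dataset is reproducible and satisfies its invariants", {
  scn <- scenario(n_species = 12, specimens_per_species = 3)
  d1 <- simulate_dataset(scn, seed = 21)
  d2 <- simulate_dataset(scn, seed = 21)
  expect_identical(d1$configs[[17]]$coords, d2$configs[[17]]$coords)
  expect_identical(d1$metadata, d2$metadata)
  expect_length(d1$configs, 36)
  expect_identical(sort(unique(d1$metadata$ecology)),
                   sort(c("predatory", "ground", "flying")))
  # every configuration passed claw_config validation on construction
  expect_true(all(vapply(d1$configs, inherits, TRUE, "claw_config")))
  # the truth record reproduces the specimen parameters used
  expect_identical(nrow(d1$truth$specimen_params), 36L)
  expect_identical(rownames(d1$truth$specimen_params),
                   d1$metadata$specimen_id)
})

test_that("within-species spread rivals between-species spread in its group", {
  # one heavily sampled species against its group mates, as in studies of
  # individual variation
  scn <- scenario(n_species = 24,
                  specimens_per_species = c(25, rep(3, 23)))
  d <- simulate_dataset(scn, seed = 31)
  s <- gpa(d$configs)
  pc <- shape_pca(s)
  sp1 <- d$metadata$species[1]
  grp1 <- unique(d$metadata$ecology[d$metadata$species == sp1])
  within_sd <- sd(pc$scores[d$metadata$species == sp1, 1])
  sp_means <- species_means(s)
  same_group <- sp_means$ecology == grp1
  # project species means on the same axis as the individual PCA
  sc <- sweep(as_shape_matrix(sp_means), 2, pc$center) %*% pc$loadings[, 1]
  between_sd <- sd(sc[same_group])
  expect_gte(within_sd, 0.5 * between_sd)
})
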