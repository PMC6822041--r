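# Domain types, TPS I/O, tree I/O, and species-mean aggregation.

test_that("claw_config enforces the 83-point invariants", {
  X <- matrix(rnorm(83 * 2), 83, 2)
  cfg <- claw_config(X, specimen_id = "a")
  expect_s3_class(cfg, "claw_config")
  expect_identical(sum(cfg$roles == "fixed"), 6L)
  expect_identical(as.integer(table(cfg$curve_id)[c("SL1", "SL2", "SL3", "SL4")]),
                   c(13L, 18L, 28L, 18L))
  expect_error(claw_config(X[1:82, ]), "83")
  X_bad <- X; X_bad[5, 1] <- NaN
  expect_error(claw_config(X_bad), "non-finite")
  expect_error(claw_config(X, scale = -1), "positive")
})

test_that("landmark_partition default matches the published index sets", {
  p <- landmark_partition()
  expect_identical(p$core, c(1:4, 7:37))
  expect_identical(p$sheath, c(5:6, 38:83))
  expect_error(landmark_partition(core = 1:40, sheath = 40:83), "disjoint")
  expect_error(landmark_partition(core = 1:4, sheath = 7:83), "cover")
})

test_that("TPS write/read round trip is lossless for both dialects", {
  claws <- make_test_claws(3, seed = 11)
  claws[[2]]$scale <- 0.037
  tf <- tempfile(fileext = ".tps")
  write_tps(claws, tf)
  back <- read_tps(tf)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_lt(max(abs(back[[i]]$coords - claws[[i]]$coords)), 1e-12)
    expect_identical(back[[i]]$specimen_id, claws[[i]]$specimen_id)
    expect_equal(back[[i]]$scale, claws[[i]]$scale)
  }
  # dialect (b): fixed landmarks + POINTS blocks in SL1..SL4 order
  cfg <- claws[[1]]
  raw <- cfg$coords
  fmt <- function(m) sprintf("%.17g %.17g", m[, 1], m[, 2])
  lines <- c("LM=6", fmt(raw[1:6, , drop = FALSE]), "CURVES=4",
             "POINTS=13", fmt(raw[7:19, , drop = FALSE]),
             "POINTS=18", fmt(raw[20:37, , drop = FALSE]),
             "POINTS=28", fmt(raw[38:65, , drop = FALSE]),
             "POINTS=18", fmt(raw[66:83, , drop = FALSE]),
             "IMAGE=claw.jpg", "ID=dialect_b", "SCALE=1.0")
  tf2 <- tempfile(fileext = ".tps")
  writeLines(lines, tf2)
  back2 <- read_tps(tf2)[[1]]
  expect_lt(max(abs(back2$coords - raw)), 1e-12)
  expect_identical(back2$specimen_id, "dialect_b")
})

test_that("TPS reader applies SCALE and reports malformed records", {
  claws <- make_test_claws(1, seed = 3)
  raw <- claws[[1]]$coords
  fmt <- sprintf("%.10f %.10f", raw[, 1], raw[, 2])
  tf <- tempfile(fileext = ".tps")
  writeLines(c("LM=83", fmt, "SCALE=2.5"), tf)
  expect_lt(max(abs(read_tps(tf)[[1]]$coords - 2.5 * raw)), 1e-8)

  writeLines(c("LM=82", fmt[1:82]), tf)
  expect_error(read_tps(tf), "record 1")
  writeLines(c("LM=83", fmt[1:40], "12.0 oops", fmt[42:83]), tf)
  expect_error(read_tps(tf), "line 42")
  writeLines(character(0), tf)
  expect_identical(read_tps(tf), list())
  # empty write -> empty file
  write_tps(list(), tf)
  expect_identical(readLines(tf), character(0))
})

test_that("read_newick validates trees and round-trips simulated trees", {
  tf <- newick_abc()
  tr <- read_newick(tf)
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(unname(depths), c(2, 2, 2))

  writeLines("((A:1,A:1):1,C:2);", tf)
  expect_error(read_newick(tf), "duplicate")
  writeLines("((A:1,B),C:2);", tf)
  expect_error(read_newick(tf), "branch length")

  tr64 <- simulate_tree(64, seed = 9)
  tf2 <- tempfile(fileext = ".nwk")
  ape::write.tree(tr64, tf2)
  back <- read_newick(tf2)
  # identical topology and branch lengths (tip storage order may differ)
  expect_setequal(back$tip.label, tr64$tip.label)
  expect_equal(phylo_covariance(back)[tr64$tip.label, tr64$tip.label],
               phylo_covariance(tr64), tolerance = 1e-8)
})

test_that("prune_tree preserves root-to-tip paths and covariance structure", {
  tr <- read_newick(newick_abc())
  expect_identical(ape::Ntip(prune_tree(tr, tr$tip.label)), 3L)
  pr <- prune_tree(tr, c("A", "C"))
  d <- ape::node.depth.edgelength(pr)[seq_len(2)]
  expect_equal(unname(d), c(2, 2))
  expect_error(prune_tree(tr, c("A", "Z")), "Z")
  expect_error(prune_tree(tr, character(0)), "at least one")

  tr64 <- simulate_tree(40, seed = 2)
  keep <- tr64$tip.label[c(3, 7, 11, 20, 33, 40)]
  C_full <- phylo_covariance(tr64)[keep, keep]
  C_sub <- phylo_covariance(prune_tree(tr64, keep))[keep, keep]
  expect_equal(C_sub, C_full, tolerance = 1e-10)
})

test_that("species_means averages shapes and metrics correctly", {
  claws <- make_test_claws(6, seed = 21)
  sp <- rep(c("sp1", "sp2", "sp3"), each = 2)
  for (i in seq_along(claws)) claws[[i]]$species <- sp[i]
  s <- gpa(claws)
  sm <- species_means(s)
  expect_identical(sm$species, c("sp1", "sp2", "sp3"))
  # brute-force column-wise average of aligned coordinates
  expect_equal(sm$aligned["sp2", , ],
               (s$aligned[3, , ] + s$aligned[4, , ]) / 2, tolerance = 1e-12)
  # centroid size averaged on the raw scale
  expect_equal(unname(sm$centroid_sizes["sp1"]),
               mean(s$centroid_sizes[1:2]))
  # permutation invariance of the result
  s2 <- gpa(claws[c(4, 2, 6, 1, 3, 5)])
  sm2 <- species_means(s2)
  expect_equal(sm2$aligned, sm$aligned, tolerance = 1e-7)

  df <- data.frame(specimen_id = c("a", "b", "c"),
                   species = c("x", "x", "y"),
                   ecology = c("flying", "flying", "ground"),
                   metric = c(70, 80, 55))
  dm <- species_means(df)
  expect_equal(dm$metric, c(75, 55))
  expect_equal(dm$n_specimens, c(2L, 1L))
  df$ecology[2] <- "ground"
  expect_error(species_means(df), "conflicting")
})
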