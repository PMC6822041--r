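# Fixtures built in code: synthetic claws, random configurations, and small
# hand-specified trees. Everything is deterministic given the seeds below.

make_test_claws <- function(n, seed = 1, noise_sd = 0.01,
                            theta_sheath = 105, theta_core = 76,
                            spread = 8) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    lapply(seq_len(n), function(i) {
      p <- claw_params(
        theta_sheath = theta_sheath + stats::rnorm(1, 0, spread),
        theta_core = theta_core + stats::rnorm(1, 0, spread * 0.7),
        length_ratio = min(1.05, max(0.4, 0.7 + stats::rnorm(1, 0, 0.03))),
        noise_sd = noise_sd)
      cfg <- make_claw(p, seed = seed * 1000 + i)$config
      cfg$specimen_id <- sprintf("claw_%03d", i)
      cfg
    })
  })
}

# Random (non-claw) 83 x 2 configurations as an n x 83 x 2 array.
random_config_array <- function(n, seed = 1, k = 83) {
  set.seed(seed)
  arr <- array(stats::rnorm(n * k * 2), c(n, k, 2))
  dimnames(arr) <- list(sprintf("cfg_%03d", seq_len(n)), NULL, c("x", "y"))
  arr
}

# Apply a random rigid motion + positive scaling to every configuration.
jitter_placement <- function(arr, seed = 1, reflect = FALSE) {
  set.seed(seed)
  out <- arr
  for (i in seq_len(dim(arr)[1])) {
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    if (reflect) R[, 2] <- -R[, 2]
    s <- exp(stats::runif(1, -1, 1))
    out[i, , ] <- s * arr[i, , ] %*% t(R) +
      rep(stats::runif(2, -5, 5), each = dim(arr)[2])
  }
  out
}

# Inverse of as_shape_matrix for constructing shape_sample fixtures.
shape_matrix_to_array_test <- function(m) {
  n <- nrow(m); k <- ncol(m) / 2L
  aperm(array(as.numeric(m), c(n, 2L, k)), c(1, 3, 2))
}

newick_abc <- function() {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tf
}

star_covariance <- function(n, labels = sprintf("s%03d", seq_len(n))) {
  C <- diag(n)
  dimnames(C) <- list(labels, labels)
  C
}

# Independent forward-in-time Yule topology sampler (oracle for tree-shape
# checks): repeatedly split a uniformly chosen lineage.
yule_topology_oracle <- function(n_tips) {
  children <- list()
  next_id <- 2L
  tips <- c(1L)
  while (length(tips) < n_tips) {
    pick <- tips[sample.int(length(tips), 1L)]
    kids <- c(next_id, next_id + 1L)
    children[[as.character(pick)]] <- kids
    tips <- c(setdiff(tips, pick), kids)
    next_id <- next_id + 2L
  }
  # Colless imbalance: sum over internal nodes of |left tips - right tips|
  count_tips <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(1L)
    count_tips(kids[1L]) + count_tips(kids[2L])
  }
  colless <- 0L
  for (nd in names(children)) {
    kids <- children[[nd]]
    colless <- colless + abs(count_tips(kids[1L]) - count_tips(kids[2L]))
  }
  colless
}

colless_of_tree <- function(tr) {
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(tr$tip.label)
  size <- c(rep(1L, ntip), rep(0L, tr$Nnode))
  imbalance <- 0L
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  for (nd in as.integer(names(kids))) NULL
  # accumulate sizes in postorder
  for (i in seq_len(nrow(tr$edge))) {
    size[tr$edge[i, 1]] <- size[tr$edge[i, 1]] + size[tr$edge[i, 2]]
  }
  for (nd in names(kids)) {
    ch <- kids[[nd]]
    if (length(ch) == 2L)
      imbalance <- imbalance + abs(size[ch[1L]] - size[ch[2L]])
  }
  imbalance
}
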