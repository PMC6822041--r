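# Ground-truth synthetic data: parametric nested circular-arc claw outlines,
# simulated pure-birth trees, Brownian-motion species parameters with
# ecological group structure, weak allometry, and intraspecific noise.
#
# Dorsal curves are exact concentric circular arcs so the traditional
# inscribed-circle protocol holds by construction; the articulation point is
# placed (by a one-dimensional solve) so that the protocol's arc-length
# ratio equals the requested core/sheath length ratio exactly on noise-free
# claws.

#' Parameters of a synthetic claw outline
#'
#' Defaults are centred on published confidence intervals for real bird
#' claws: sheath arc about 105 degrees, core arc about 76 degrees, and a
#' core-to-sheath length ratio near 0.70.
#'
#' @param theta_sheath Dorsal keratinous-sheath arc angle, degrees in
#'   \[10, 350\].
#' @param theta_core Dorsal bony-core arc angle, degrees in \[10, 350\].
#' @param length_ratio Core/sheath arc-length ratio, in \[0.3, 1.1\].
#' @param radius Sheath dorsal arc radius (length units); the claw's size.
#' @param base_width Proximal claw depth (dorsal-to-ventral offset).
#' @param taper Exponent (>= 1) controlling how thickness decays to the tip.
#' @param noise_sd Isotropic per-landmark digitization noise sd (length units).
#' @return A validated list of class `claw_params`.
#' @export
claw_params <- function(theta_sheath = 105, theta_core = 76,
                        length_ratio = 0.70, radius = 1,
                        base_width = 0.25, taper = 1.5, noise_sd = 0) {
  p <- list(theta_sheath = theta_sheath, theta_core = theta_core,
            length_ratio = length_ratio, radius = radius,
            base_width = base_width, taper = taper, noise_sd = noise_sd)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE)))
    stop("all claw parameters must be single finite numbers", call. = FALSE)
  if (theta_sheath < 10 || theta_sheath > 350 || theta_core < 10 || theta_core > 350)
    stop("arc angles must lie in [10, 350] degrees", call. = FALSE)
  if (length_ratio < 0.3 || length_ratio > 1.1)
    stop("length_ratio must lie in [0.3, 1.1]", call. = FALSE)
  if (radius <= 0 || base_width <= 0)
    stop("radius and base_width must be positive", call. = FALSE)
  if (taper < 1) stop("taper must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(p, class = "claw_params")
}

# Arc length from M through `mid` to `tip` on their circumcircle.
arc_length_through <- function(M, mid, tip) {
  circ <- fit_circle(M, mid, tip)
  circ$radius * deg2rad(subtended_arc_deg(circ$center, M, tip, mid))
}

#' Generate one synthetic claw configuration
#'
#' Builds an exact nested-arc claw outline (dorsal sheath arc of angle
#' `theta_sheath` and radius `radius`; concentric dorsal core arc of angle
#' `theta_core` with arc length `length_ratio` times the sheath arc length;
#' ventral curves offset inward with a taper so they meet the respective
#' tips), samples the canonical 83 landmarks with equal arc-length spacing,
#' adds isotropic Gaussian noise, and applies a random rigid motion plus
#' scale. The returned ground truth holds the exact pre-noise arc angles and
#' protocol lengths (in final units).
#'
#' @param params A [claw_params()] object.
#' @param seed Seed for noise and placement.
#' @return A list with `config` (a [claw_config()]) and `truth`
#'   (an `arc_measurement`).
#' @export
make_claw <- function(params, seed = 1) {
  stopifnot(inherits(params, "claw_params"))
  R <- params$radius
  ths <- deg2rad(params$theta_sheath)
  thc <- deg2rad(params$theta_core)
  ratio <- params$length_ratio
  bw <- params$base_width
  rc <- ratio * R * ths / thc                 # concentric core arc radius
  if (bw >= 0.95 * min(rc, R))
    stop(sprintf(
      "geometrically impossible claw: ventral offset %.3g exceeds arc radius %.3g",
      bw, min(rc, R)), call. = FALSE)

  pt <- function(r, ang) c(r * cos(ang), r * sin(ang))
  n3 <- CURVE_SIZES[["SL3"]]
  mid3_frac <- (n3 - floor((n3 + 2) / 2) + 1) / n3  # angular fraction of SL3 midpoint
  sheath_mid <- pt(R, ths * mid3_frac)
  tip_sheath <- pt(R, 0)

  # Place the articulation midpoint M on the core circle, proximal of the
  # dorsal lip, such that the seven-point protocol's length ratio equals
  # `ratio` exactly: rc * tm = ratio * sheath_protocol_length(tm).
  f <- function(tm) {
    M <- pt(rc, tm)
    rc * tm - ratio * arc_length_through(M, sheath_mid, tip_sheath)
  }
  # f is negative for small tm and crosses zero once in the geometrically
  # meaningful range; for strongly recurved claws it turns negative again
  # when the fitted arc flips orientation near 360 degrees, so bracket the
  # first negative-to-positive crossing on a grid before root-finding.
  grid <- seq(0.05 * thc, deg2rad(350), length.out = 72L)
  fg <- vapply(grid, function(tm) tryCatch(f(tm), error = function(e) NA_real_),
               0)
  cross <- which(!is.na(fg[-length(fg)]) & !is.na(fg[-1L]) &
                   fg[-length(fg)] < 0 & fg[-1L] >= 0)
  if (length(cross) == 0L)
    stop("cannot place the articulation point for these claw parameters",
         call. = FALSE)
  tm <- stats::uniroot(f, grid[c(cross[1L], cross[1L] + 1L)], tol = 1e-13)$root
  M <- pt(rc, tm)

  core_len <- rc * tm
  sheath_len <- core_len / ratio

  X <- matrix(NA_real_, N_LANDMARKS, 2L)
  X[1L, ] <- pt(rc, thc)                       # LM1 dorsal lip of bony core
  X[2L, ] <- 2 * M - X[1L, ]                   # LM2: articulation mid = M
  X[3L, ] <- pt(rc - bw, thc)                  # LM3 flexor tubercle region
  X[4L, ] <- pt(rc, 0)                         # LM4 bony core tip
  X[5L, ] <- pt(R - bw, ths)                   # LM5 ventral sheath meets bone
  X[6L, ] <- tip_sheath                        # LM6 sheath tip

  rng <- curve_ranges()
  put <- function(curve, xy) {
    i <- seq(rng$start[rng$curve == curve], rng$stop[rng$curve == curve])
    X[i, ] <<- xy
  }
  n1 <- CURVE_SIZES[["SL1"]]
  a1 <- thc * (n1:1) / (n1 + 1)                # interior, equal spacing
  put("SL1", cbind(rc * cos(a1), rc * sin(a1)))
  a3 <- ths * (n3:1) / n3                      # first point at the sheath lip
  put("SL3", cbind(R * cos(a3), R * sin(a3)))
  n2 <- CURVE_SIZES[["SL2"]]
  s2 <- (1:n2) / (n2 + 1)                      # LM3 (s=0) -> LM4 (s=1)
  r2 <- rc - bw * (1 - s2)^params$taper
  put("SL2", cbind(r2 * cos(thc * (1 - s2)), r2 * sin(thc * (1 - s2))))
  n4 <- CURVE_SIZES[["SL4"]]
  s4 <- (1:n4) / (n4 + 1)                      # LM5 (s=0) -> LM6 (s=1)
  r4 <- R - bw * (1 - s4)^params$taper
  put("SL4", cbind(r4 * cos(ths * (1 - s4)), r4 * sin(ths * (1 - s4))))

  with_seed(seed, {
    if (params$noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, params$noise_sd), ncol = 2L)
    rot <- stats::runif(1, 0, 2 * pi)
    sc <- exp(stats::runif(1, -0.2, 0.2))
    shift <- stats::runif(2, -2 * R, 2 * R)
    Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L, 2L)
    X <- sc * (X %*% t(Rm)) + rep(shift, each = nrow(X))
    truth <- structure(list(core_arc_deg = params$theta_core,
                            sheath_arc_deg = params$theta_sheath,
                            core_length = sc * core_len,
                            sheath_length = sc * sheath_len,
                            length_ratio = ratio, length_method = "arc"),
                       class = "arc_measurement")
    list(config = claw_config(X, specimen_id = sprintf("synthetic_%d", seed)),
         truth = truth)
  })
}

#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) tree on `n_tips` species, rescaled to unit root-to-tip
#' depth (hence ultrametric with unit tip variances).
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed RNG seed.
#' @return An `ape::phylo` tree with tips `s001, s002, ...`.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (!is.numeric(n_tips) || n_tips < 2)
    stop("`n_tips` must be at least 2", call. = FALSE)
  n_tips <- as.integer(n_tips)
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("s%03d", seq_len(n_tips))
  tr
}

#' Simulate multivariate Brownian-motion tip values
#'
#' Draws tip values from a matrix normal with row covariance equal to the
#' lambda-transformed phylogenetic covariance and column covariance `Sigma`.
#'
#' @param tree An `ape::phylo` tree.
#' @param mean Length-p trait mean vector.
#' @param Sigma p x p PSD evolutionary rate matrix.
#' @param lambda_true Pagel's lambda used for the row covariance, in \[0, 1\].
#' @param seed RNG seed.
#' @return An n x p matrix with tip-label rownames.
#' @export
simulate_bm_traits <- function(tree, mean, Sigma, lambda_true = 1, seed = 1) {
  validate_tree(tree)
  mean <- as.numeric(mean)
  Sigma <- as.matrix(Sigma)
  p <- length(mean)
  if (!all(dim(Sigma) == p)) stop("`Sigma` must be p x p", call. = FALSE)
  eg <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1e-300))
    stop("`Sigma` must be positive semi-definite", call. = FALSE)
  C <- lambda_transform(phylo_covariance(tree), lambda_true)
  Lc <- psd_factor(C)
  Ls <- psd_factor(Sigma)
  n <- nrow(C)
  Z <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  X <- matrix(mean, n, p, byrow = TRUE) + Lc %*% Z %*% t(Ls)
  rownames(X) <- tree$tip.label
  X
}

#' Synthetic study scenario
#'
#' Describes a full simulated claw dataset: a pure-birth species tree,
#' Brownian-motion evolution of claw parameters with tunable phylogenetic
#' signal, three ecological groups with shifted mean arcs (ground 75, flying
#' 105, predatory 150 degrees of sheath arc by default), weak allometric
#' coupling of arc angles to log size, and intraspecific parameter noise
#' large enough that within-species spread rivals between-species spread
#' within a group.
#'
#' @param n_species Number of species (>= 4).
#' @param specimens_per_species Scalar or length-`n_species` vector.
#' @param lambda_true Pagel's lambda of the generating process.
#' @param group_rule `"clade"` (predatory and ground taxa drawn from single
#'   clades, mimicking real clade-biased group membership) or `"random"`.
#' @param group_props Proportions for predatory/ground/flying groups.
#' @param group_offsets 3 x 3 matrix (rows predatory, ground, flying; columns
#'   theta_sheath, theta_core, length_ratio) of group mean shifts. The
#'   default shifts the arcs only (core kept proportional to the sheath at
#'   0.72); the length ratio carries no ecological signal, consistent with
#'   the non-significant ecological differences reported for it.
#' @param bm_sd Per-trait Brownian tip sd on the unit-depth tree for
#'   (theta_sheath, theta_core, length_ratio, log_size).
#' @param rho_block Evolutionary correlation between sheath and core arcs
#'   (the integration coupling), in \[0, 1\].
#' @param allometry_coef Degrees of (sheath, core) arc per unit log size.
#' @param within_sd Intraspecific sd of (theta_sheath, theta_core,
#'   length_ratio, log_size).
#' @param noise_sd Landmark digitization noise sd, as a fraction of claw radius.
#' @param base_params Baseline [claw_params()] for the flying group.
#' @return A list of class `claw_scenario`.
#' @export
scenario <- function(n_species = 145,
                     specimens_per_species = 4,
                     lambda_true = 0.7,
                     group_rule = c("clade", "random"),
                     group_props = c(predatory = 0.2, ground = 0.2, flying = 0.6),
                     group_offsets = rbind(predatory = c(45, 32.4, 0),
                                           ground = c(-30, -21.6, 0),
                                           flying = c(0, 0, 0)),
                     bm_sd = c(theta_sheath = 9, theta_core = 6.5,
                               length_ratio = 0.03, log_size = 0.8),
                     rho_block = 0.9,
                     allometry_coef = c(theta_sheath = 6, theta_core = 4),
                     within_sd = c(theta_sheath = 8, theta_core = 5.8,
                                   length_ratio = 0.025, log_size = 0.15),
                     noise_sd = 0.005,
                     base_params = claw_params()) {
  group_rule <- match.arg(group_rule)
  if (n_species < 4) stop("`n_species` must be >= 4", call. = FALSE)
  if (any(specimens_per_species < 1))
    stop("`specimens_per_species` must be >= 1", call. = FALSE)
  if (rho_block < 0 || rho_block > 1)
    stop("`rho_block` must lie in [0, 1]", call. = FALSE)
  if (lambda_true < 0 || lambda_true > 1)
    stop("`lambda_true` must lie in [0, 1]", call. = FALSE)
  colnames(group_offsets) <- c("theta_sheath", "theta_core", "length_ratio")
  structure(list(n_species = as.integer(n_species),
                 specimens_per_species = specimens_per_species,
                 lambda_true = lambda_true, group_rule = group_rule,
                 group_props = group_props, group_offsets = group_offsets,
                 bm_sd = bm_sd, rho_block = rho_block,
                 allometry_coef = allometry_coef, within_sd = within_sd,
                 noise_sd = noise_sd, base_params = base_params),
            class = "claw_scenario")
}

# Assign tips to ecological groups; "clade" biases predatory and ground
# membership to single clades (as real predatory birds cluster in one order).
assign_groups <- function(tree, props, rule, seed) {
  n <- length(tree$tip.label)
  n_pred <- max(1L, round(n * props[["predatory"]]))
  n_ground <- max(1L, round(n * props[["ground"]]))
  groups <- stats::setNames(rep("flying", n), tree$tip.label)
  if (rule == "random") {
    idx <- with_seed(seed, sample.int(n, n_pred + n_ground))
    groups[idx[seq_len(n_pred)]] <- "predatory"
    groups[idx[n_pred + seq_len(n_ground)]] <- "ground"
    return(groups)
  }
  internal <- (n + 1L):(n + tree$Nnode)
  clades <- lapply(internal, function(nd) ape::extract.clade(tree, nd)$tip.label)
  sizes <- lengths(clades)
  pick <- function(target, forbidden) {
    ok <- which(vapply(clades, function(tp) !any(tp %in% forbidden), TRUE) &
                  sizes <= max(2L * target, 3L))
    if (length(ok) == 0L) return(NULL)
    ok[which.min(abs(sizes[ok] - target))]
  }
  i_pred <- pick(n_pred, character(0))
  pred_tips <- if (is.null(i_pred)) character(0) else clades[[i_pred]]
  i_ground <- pick(n_ground, pred_tips)
  ground_tips <- if (is.null(i_ground)) character(0) else clades[[i_ground]]
  # top up by random draws if the clades were smaller than the targets
  with_seed(seed, {
    free <- setdiff(tree$tip.label, c(pred_tips, ground_tips))
    if (length(pred_tips) < n_pred) {
      extra <- sample(free, n_pred - length(pred_tips))
      pred_tips <- c(pred_tips, extra); free <- setdiff(free, extra)
    }
    if (length(ground_tips) < n_ground) {
      extra <- sample(free, n_ground - length(ground_tips))
      ground_tips <- c(ground_tips, extra)
    }
  })
  groups[pred_tips] <- "predatory"
  groups[ground_tips] <- "ground"
  groups
}

#' Simulate a complete synthetic claw study
#'
#' Evolves species-level claw parameters (sheath arc, core arc, length
#' ratio, log size) under correlated Brownian motion with the scenario's
#' lambda, shifts group means, couples size into the arcs (weak allometry),
#' adds intraspecific parameter noise per specimen, and renders every
#' specimen with [make_claw()]. The `truth` element records every latent
#' value needed to recompute expected results independently.
#'
#' @param scn A [scenario()].
#' @param seed RNG seed; all stage seeds derive from it.
#' @return A list with `configs`, `metadata`, `tree`, and `truth`.
#' @export
simulate_dataset <- function(scn, seed = 1) {
  stopifnot(inherits(scn, "claw_scenario"))
  seed <- as.integer(seed)
  n <- scn$n_species
  tree <- simulate_tree(n, seed = seed)
  groups <- assign_groups(tree, scn$group_props, scn$group_rule, seed + 1L)

  sdv <- scn$bm_sd
  Sigma <- diag(sdv^2)
  dimnames(Sigma) <- list(names(sdv), names(sdv))
  Sigma[1, 2] <- Sigma[2, 1] <- scn$rho_block * sdv[1] * sdv[2]
  base <- scn$base_params
  mu <- c(base$theta_sheath, base$theta_core, base$length_ratio, 0)
  sp_traits <- simulate_bm_traits(tree, mu, Sigma, scn$lambda_true,
                                  seed = seed + 2L)
  colnames(sp_traits) <- names(sdv)
  off <- scn$group_offsets[groups[rownames(sp_traits)], , drop = FALSE]
  sp_traits[, 1:3] <- sp_traits[, 1:3] + off
  # weak allometry: arcs respond to (species) log size
  sp_traits[, 1] <- sp_traits[, 1] + scn$allometry_coef[[1]] * sp_traits[, 4]
  sp_traits[, 2] <- sp_traits[, 2] + scn$allometry_coef[[2]] * sp_traits[, 4]

  nspec <- rep(scn$specimens_per_species, length.out = n)
  total <- sum(nspec)
  wsd <- scn$within_sd
  # Within-species noise on the two arcs shares the integration correlation
  # rho_block: the bony core is physically nested inside the sheath, so a
  # specimen with a more recurved sheath has a correspondingly recurved
  # core. Independent within-specimen arc noise would make core/sheath
  # mismatch the dominant axis of shape variance, contradicting the strong
  # functional integration this world is built to exhibit.
  Sw <- diag(wsd^2)
  Sw[1, 2] <- Sw[2, 1] <- scn$rho_block * wsd[1] * wsd[2]
  noise <- with_seed(seed + 3L,
                     matrix(stats::rnorm(total * 4), total, 4) %*%
                       t(psd_factor(Sw)))
  sp_index <- rep(seq_len(n), nspec)
  spec_par <- sp_traits[sp_index, , drop = FALSE] + noise
  # clamp to the generator's valid parameter ranges
  spec_par[, 1] <- pmin(pmax(spec_par[, 1], 15), 345)
  spec_par[, 2] <- pmin(pmax(spec_par[, 2], 10), 0.95 * spec_par[, 1])
  spec_par[, 3] <- pmin(pmax(spec_par[, 3], 0.3), 1.1)
  species <- tree$tip.label[sp_index]
  within_i <- stats::ave(sp_index, sp_index, FUN = seq_along)
  spec_id <- sprintf("%s_%02d", species, within_i)
  rownames(spec_par) <- spec_id

  configs <- vector("list", total)
  truth_rows <- vector("list", total)
  for (i in seq_len(total)) {
    sz <- exp(spec_par[i, 4])
    pars <- tryCatch(
      claw_params(theta_sheath = spec_par[i, 1], theta_core = spec_par[i, 2],
                  length_ratio = spec_par[i, 3], radius = base$radius * sz,
                  base_width = base$base_width * sz, taper = base$taper,
                  noise_sd = scn$noise_sd * base$radius * sz),
      error = function(e)
        stop(sprintf("species %s, specimen %s: %s", species[i], spec_id[i],
                     conditionMessage(e)), call. = FALSE))
    cl <- tryCatch(make_claw(pars, seed = seed + 10L + i),
                   error = function(e)
                     stop(sprintf("species %s, specimen %s: %s", species[i],
                                  spec_id[i], conditionMessage(e)), call. = FALSE))
    cl$config$specimen_id <- spec_id[i]
    cl$config$species <- species[i]
    cl$config$ecology <- unname(groups[species[i]])
    configs[[i]] <- cl$config
    truth_rows[[i]] <- data.frame(specimen_id = spec_id[i],
                                  core_arc_deg = cl$truth$core_arc_deg,
                                  sheath_arc_deg = cl$truth$sheath_arc_deg,
                                  length_ratio = cl$truth$length_ratio,
                                  core_length = cl$truth$core_length,
                                  sheath_length = cl$truth$sheath_length,
                                  stringsAsFactors = FALSE)
  }
  metadata <- data.frame(specimen_id = spec_id, species = species,
                         ecology = unname(groups[species]),
                         stringsAsFactors = FALSE)
  truth <- list(scenario = scn, seed = seed, tree = tree, groups = groups,
                species_params = sp_traits,
                specimen_params = spec_par,
                specimen_truth = do.call(rbind, truth_rows))
  list(configs = configs, metadata = metadata, tree = tree, truth = truth)
}
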