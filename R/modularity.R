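# Modularity (covariance ratio) and integration (two-block partial least
# squares) tests, with effect-size comparison across PLS fits.

# Covariance of flattened coordinates: evolutionary if C is given, ordinary
# (about the mean, divisor n - 1) otherwise.
block_covariance <- function(Y, C = NULL) {
  Y <- as.matrix(Y)
  if (is.null(C)) {
    Yc <- sweep(Y, 2L, colMeans(Y))
    crossprod(Yc) / (nrow(Y) - 1)
  } else evolutionary_covariance(Y, C)
}

# CR from a full coordinate covariance matrix and a landmark partition.
# Within-module matrices have their per-landmark 2x2 diagonal blocks zeroed,
# so CR ignores within-landmark variance entirely.
cr_statistic <- function(S, part_a, part_b) {
  ca <- landmark_cols(part_a); cb <- landmark_cols(part_b)
  S12 <- S[ca, cb, drop = FALSE]
  zero_lm_blocks <- function(M) {
    k <- nrow(M) / 2L
    for (j in seq_len(k)) {
      i <- c(2L * j - 1L, 2L * j)
      M[i, i] <- 0
    }
    M
  }
  S11 <- zero_lm_blocks(S[ca, ca, drop = FALSE])
  S22 <- zero_lm_blocks(S[cb, cb, drop = FALSE])
  sqrt(sum(S12^2)) / sqrt(sqrt(sum(S11^2)) * sqrt(sum(S22^2)))
}

#' Covariance-ratio test of modularity
#'
#' The covariance ratio (CR) is the Frobenius norm of the between-module
#' covariance block over the geometric mean of the within-module norms
#' (within-landmark 2x2 blocks excluded). The null distribution reassigns
#' whole landmarks (x,y pairs) at random to two subsets of the original
#' sizes; modularity is supported when the observed CR is significantly
#' LOWER than the null (small p).
#'
#' @param Y n x 2k flattened coordinate matrix (or `shape_sample`).
#' @param partition A [landmark_partition()] (or list with two landmark
#'   index vectors covering `1..k`).
#' @param C Optional phylogenetic covariance matrix (uses the evolutionary
#'   covariance when given).
#' @param n_perm Number of random partitions.
#' @param seed RNG seed.
#' @return A `claw_test` whose statistic is CR (lower-tail p-value).
#' @export
modularity_cr <- function(Y, partition, C = NULL, n_perm = 999, seed = 1) {
  Y <- as_shape_matrix(Y)
  k <- ncol(Y) / 2L
  part_a <- partition[[1L]]; part_b <- partition[[2L]]
  if (length(part_a) < 2L || length(part_b) < 2L)
    stop("each module must contain at least 2 landmarks", call. = FALSE)
  if (!setequal(c(part_a, part_b), seq_len(k)))
    stop("partition must cover all landmarks of Y exactly once", call. = FALSE)
  S <- block_covariance(Y, C)
  cr_obs <- cr_statistic(S, part_a, part_b)
  na <- length(part_a)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(k)
    cr_statistic(S, pm[seq_len(na)], pm[-seq_len(na)])
  }, 0))
  new_claw_test(statistic = cr_obs, p_value = perm_pval(null, cr_obs, "le"),
                n_perm = n_perm, seed = seed, null = null,
                effect_size_z = (cr_obs - mean(null)) / stats::sd(null),
                test = "modularity (covariance ratio)")
}

# Internal PLS machinery shared by the observed fit and the permutations.
pls_r <- function(Z1, Z2, n) {
  S12 <- crossprod(Z1, Z2) / (n - 1)
  sv <- svd(S12, nu = 1L, nv = 1L)
  s1 <- drop(Z1 %*% sv$u)
  s2 <- drop(Z2 %*% sv$v)
  r <- stats::cor(s1, s2)
  if (is.na(r)) r <- 0
  if (r < 0) { r <- -r; s2 <- -s2; sv$v <- -sv$v }
  list(r = r, u = sv$u, v = sv$v, scores1 = s1, scores2 = s2, d = sv$d)
}

# GLS-centered, transformed block. With C = NULL this is ordinary centering.
pls_transform <- function(Y, U = NULL, Cinv = NULL) {
  Y <- as.matrix(Y)
  if (is.null(U)) return(sweep(Y, 2L, colMeans(Y)))
  a <- colSums(Cinv %*% Y) / sum(Cinv)
  U %*% (Y - matrix(a, nrow(Y), ncol(Y), byrow = TRUE))
}

#' Phylogenetic two-block partial least squares
#'
#' Singular value decomposition of the cross-block (evolutionary)
#' covariance; r-PLS is the correlation of the paired first-axis scores of
#' the GLS-transformed centered blocks. Significance comes from permuting
#' the tip rows of the second block; the effect size is the standardized
#' position of the observed Fisher-z-transformed correlation within its
#' permuted null.
#'
#' @param Y1,Y2 n x p1 and n x p2 blocks (same row order).
#' @param C Optional phylogenetic covariance matrix (`NULL` for the
#'   non-phylogenetic version).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return A `claw_test` with singular vectors, block scores, and the
#'   Fisher-z null summaries needed by [compare_pls()].
#' @export
phylo_two_block_pls <- function(Y1, Y2, C = NULL, n_perm = 999, seed = 1) {
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  n <- nrow(Y1)
  if (nrow(Y2) != n) stop("blocks must have the same specimens", call. = FALSE)
  if (n < 4L) stop("PLS requires at least 4 specimens", call. = FALSE)
  if (any(apply(Y1, 2L, stats::sd) == 0) && ncol(Y1) == 1L ||
      all(apply(Y1, 2L, stats::sd) == 0) || all(apply(Y2, 2L, stats::sd) == 0))
    stop("constant block in PLS", call. = FALSE)
  U <- NULL; Cinv <- NULL
  if (!is.null(C)) {
    C <- check_C(C, n)
    U <- inv_sqrt_psd(C)
    Cinv <- U %*% U
  }
  Z1 <- pls_transform(Y1, U, Cinv)
  obs <- pls_r(Z1, pls_transform(Y2, U, Cinv), n)
  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    Z2p <- pls_transform(Y2[sample.int(n), , drop = FALSE], U, Cinv)
    pls_r(Z1, Z2p, n)$r
  }, 0))
  z_obs <- fisher_z(obs$r)
  z_null <- fisher_z(null_r)
  new_claw_test(statistic = obs$r, p_value = perm_pval(null_r, obs$r, "ge"),
                n_perm = n_perm, seed = seed, null = null_r,
                effect_size_z = (z_obs - mean(z_null)) / stats::sd(z_null),
                test = "two-block PLS (r-PLS)",
                left_vectors = obs$u, right_vectors = obs$v,
                scores1 = obs$scores1, scores2 = obs$scores2,
                singular_values = obs$d,
                z_obs = z_obs, null_mean_z = mean(z_null),
                null_sd_z = stats::sd(z_null))
}

#' Compare integration strength across PLS fits
#'
#' Pairwise two-sample comparison of PLS effect sizes: the difference of
#' the centered Fisher-z statistics over the combined null standard
#' deviations, with a two-sided normal p-value.
#'
#' @param ... Two or more results from [phylo_two_block_pls()] (or a single
#'   list of them). Names are used as labels.
#' @return A data frame with one row per pair (`z`, `p`).
#' @export
compare_pls <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "claw_test")) fits <- fits[[1L]]
  if (length(fits) < 2L) stop("need at least 2 PLS fits", call. = FALSE)
  ok <- vapply(fits, function(f) !is.null(f$z_obs) && !is.null(f$null_sd_z), TRUE)
  if (!all(ok)) stop("all inputs must carry PLS permutation nulls", call. = FALSE)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("fit", seq_along(fits))
  delta <- vapply(fits, function(f) f$z_obs - f$null_mean_z, 0)
  se <- vapply(fits, function(f) f$null_sd_z, 0)
  pairs <- utils::combn(seq_along(fits), 2L)
  z <- abs(delta[pairs[1L, ]] - delta[pairs[2L, ]]) /
    sqrt(se[pairs[1L, ]]^2 + se[pairs[2L, ]]^2)
  data.frame(pair = paste(names(fits)[pairs[1L, ]], names(fits)[pairs[2L, ]],
                          sep = ":"),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}
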