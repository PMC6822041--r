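# Non-phylogenetic shape statistics: PCA of Procrustes coordinates, the
# common allometric component, and Procrustes-variance disparity.

#' Principal component analysis of shape data
#'
#' Eigendecomposition of the covariance of column-centered flattened
#' Procrustes coordinates. Deterministic up to per-axis sign, which is fixed
#' by making each component's largest-magnitude loading positive.
#'
#' @param x A `shape_sample`, a flattened specimen-by-coordinate matrix, or
#'   an n x k x 2 array.
#' @return A list of class `pca_result` with `scores`, `loadings`,
#'   `eigenvalues`, `percent_variance`, and `center`.
#' @export
shape_pca <- function(x) {
  Y <- as_shape_matrix(x)
  n <- nrow(Y)
  if (n < 2L) stop("PCA requires at least 2 specimens", call. = FALSE)
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr)
  S <- crossprod(Yc) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  total <- sum(pmax(eg$values, 0))
  d <- min(n - 1L, ncol(Y))
  vals <- pmax(eg$values[seq_len(d)], 0)
  vecs <- eg$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- Yc %*% vecs
  colnames(scores) <- colnames(vecs) <- paste0("PC", seq_len(d))
  rownames(vecs) <- colnames(Y)
  structure(list(scores = scores, loadings = vecs, eigenvalues = vals,
                 percent_variance = 100 * vals / total, center = ctr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  d <- min(5L, length(x$eigenvalues))
  cat("Shape PCA\n")
  for (j in seq_len(d))
    cat(sprintf("  PC%d: %.1f%% of variance\n", j, x$percent_variance[j]))
  invisible(x)
}

#' Common allometric component and allometry test
#'
#' Regresses shape on centered log centroid size: the CAC direction is the
#' normalized vector of covariances of each shape coordinate with log size;
#' the Procrustes R-squared is the regression sum of squares over the total
#' sum of squares; significance comes from permuting specimen rows of the
#' shape matrix against size.
#'
#' @param sample A `shape_sample` (must carry centroid sizes).
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutations.
#' @return A list with `cac_scores`, `direction`, `r2`, `p_value`, and the
#'   permutation summary.
#' @export
common_allometric_component <- function(sample, n_perm = 999, seed = 1) {
  stopifnot(inherits(sample, "shape_sample"))
  Y <- as_shape_matrix(sample)
  n <- nrow(Y)
  if (n < 3L) stop("allometry test requires at least 3 specimens", call. = FALSE)
  logcs <- log(sample$centroid_sizes)
  cc <- logcs - mean(logcs)
  if (sum(cc^2) == 0) stop("zero variance in log centroid size", call. = FALSE)
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_tot <- sum(Yc^2)
  r2_of <- function(cvec) {
    b <- crossprod(Yc, cvec)
    sum(b^2) / sum(cvec^2) / ss_tot
  }
  r2 <- r2_of(cc)
  b <- drop(crossprod(Yc, cc)) / sum(cc^2)
  direction <- b / sqrt(sum(b^2))
  scores <- drop(Yc %*% direction)
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) r2_of(cc[sample.int(n)]), 0))
  new_claw_test(statistic = r2, p_value = perm_pval(null, r2, "ge"),
                n_perm = n_perm, seed = seed, null = null,
                effect_size_z = (r2 - mean(null)) / stats::sd(null),
                test = "allometry (common allometric component)",
                cac_scores = scores, direction = direction, r2 = r2,
                log_centroid_size = logcs)
}

#' Morphological disparity (Procrustes variance) by group
#'
#' Procrustes variance of group g is the mean squared Procrustes distance of
#' its members from the group mean shape (divisor n_g). Pairwise absolute
#' differences in Procrustes variance are tested by permuting group labels.
#'
#' @param sample A `shape_sample` or flattened shape matrix.
#' @param groups Group labels (defaults to the sample's ecology).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return A list of class `disparity_result` with `group_pv`, `pairwise_p`
#'   and `pairwise_diff`.
#' @export
morphological_disparity <- function(sample, groups = NULL, n_perm = 999, seed = 1) {
  Y <- as_shape_matrix(sample)
  if (is.null(groups) && inherits(sample, "shape_sample")) groups <- sample$ecology
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2L))
    stop(sprintf("groups with fewer than 2 members: %s",
                 paste(names(tab)[tab < 2L], collapse = ", ")), call. = FALSE)
  pv_by_group <- function(g) {
    vapply(levels(g), function(lv) {
      Yg <- Y[g == lv, , drop = FALSE]
      ctr <- colMeans(Yg)
      sum(sweep(Yg, 2L, ctr)^2) / nrow(Yg)
    }, 0)
  }
  pv <- pv_by_group(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  obs_diff <- abs(pv[pairs[1L, ]] - pv[pairs[2L, ]])
  null_diff <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, ncol(pairs))
    for (i in seq_len(n_perm)) {
      pvp <- pv_by_group(groups[sample.int(length(groups))])
      out[i, ] <- abs(pvp[pairs[1L, ]] - pvp[pairs[2L, ]])
    }
    out
  })
  pair_names <- paste(pairs[1L, ], pairs[2L, ], sep = ":")
  pairwise_p <- stats::setNames(
    vapply(seq_len(ncol(pairs)),
           function(j) perm_pval(null_diff[, j], obs_diff[j], "ge"), 0),
    pair_names)
  structure(list(group_pv = pv,
                 pairwise_diff = stats::setNames(obs_diff, pair_names),
                 pairwise_p = pairwise_p, n_perm = n_perm, seed = seed),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Procrustes-variance disparity\n")
  for (g in names(x$group_pv)) cat(sprintf("  %s: PV = %.4g\n", g, x$group_pv[g]))
  for (p in names(x$pairwise_p))
    cat(sprintf("  %s: p = %.4g\n", p, x$pairwise_p[p]))
  invisible(x)
}
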