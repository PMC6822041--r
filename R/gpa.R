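# Generalized Procrustes Analysis: translation, scale, and rotation removal
# (rotation only, determinant +1 by default -- no reflections), with a
# canonical final orientation so results are invariant to input order and to
# rigid motions of the inputs.

#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid (standard centroid size; proportional, by a factor
#' sqrt(k), to the root of the summed squared interlandmark distances).
#'
#' @param config A k x 2 coordinate matrix or a [claw_config()].
#' @return A positive number.
#' @export
centroid_size <- function(config) {
  X <- if (is_claw_config(config)) config$coords else as.matrix(config)
  ctr <- colMeans(X)
  cs <- sqrt(sum((X - rep(ctr, each = nrow(X)))^2))
  if (cs == 0) stop("degenerate configuration: all landmarks identical", call. = FALSE)
  cs
}

# Optimal rotation of X onto M (both centered). det +1 unless allow_reflection.
optimal_rotation <- function(X, M, allow_reflection = FALSE) {
  H <- crossprod(X, M)
  sv <- svd(H)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u; u[, 2L] <- -u[, 2L]
    R <- u %*% t(sv$v)
  }
  R
}

# Deterministic canonical orientation: principal axis of the mean along x,
# with the mean's farthest-from-centroid landmark on the positive x side.
canonical_rotation <- function(M) {
  eg <- eigen(crossprod(M), symmetric = TRUE)
  V <- eg$vectors
  if (det(V) < 0) V[, 2L] <- -V[, 2L]
  M2 <- M %*% V
  ref <- which.max(rowSums(M2^2))
  if (M2[ref, 1L] < 0) V <- -V
  V
}

#' Generalized Procrustes Analysis
#'
#' Centers each configuration, scales it to unit centroid size, and
#' iteratively rotates all configurations to the running Procrustes mean
#' (itself renormalized to unit centroid size each iteration) until the mean
#' changes by less than `tol`. A final canonical rotation makes the output
#' invariant (to numerical tolerance) under permutation of the inputs and
#' under rigid motion plus positive scaling of any input.
#'
#' @param configs A list of [claw_config()] objects, or an n x k x 2 array.
#' @param tol Convergence tolerance on the mean shape (Frobenius norm).
#' @param max_iter Maximum number of alignment iterations. Claw-like samples
#'   converge in a handful of iterations; weakly structured (random)
#'   configurations can need several hundred, hence the generous default.
#' @param allow_reflection Permit improper rotations (for real radiographs
#'   digitized from either side); off by default.
#' @return A `shape_sample`: list with `aligned` (n x k x 2), `centroid_sizes`
#'   (pre-scaling), `mean_shape`, metadata vectors, and convergence info.
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 1000L, allow_reflection = FALSE) {
  meta <- NULL
  if (is.list(configs) && length(configs) > 0 && is_claw_config(configs[[1L]])) {
    meta <- configs_to_array(configs)
    arr <- meta$coords
  } else if (is.array(configs) && length(dim(configs)) == 3L) {
    arr <- configs
  } else stop("`configs` must be a list of claw_config objects or an n x k x 2 array",
              call. = FALSE)
  n <- dim(arr)[1L]; k <- dim(arr)[2L]
  if (n < 2L) stop("GPA requires at least 2 configurations", call. = FALSE)

  ids <- dimnames(arr)[[1L]]
  if (is.null(ids)) ids <- sprintf("specimen_%d", seq_len(n))
  cs <- numeric(n)
  Xs <- vector("list", n)
  for (i in seq_len(n)) {
    X <- arr[i, , ]
    if (any(!is.finite(X)))
      stop(sprintf("configuration '%s' has non-finite coordinates", ids[i]),
           call. = FALSE)
    ctr <- colMeans(X)
    X <- X - rep(ctr, each = k)
    cs[i] <- sqrt(sum(X^2))
    if (cs[i] == 0)
      stop(sprintf("configuration '%s' is degenerate (zero centroid size)", ids[i]),
           call. = FALSE)
    Xs[[i]] <- X / cs[i]
  }

  M <- Xs[[1L]]
  M <- M / sqrt(sum(M^2))
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) Xs[[i]] <- Xs[[i]] %*% optimal_rotation(Xs[[i]], M, allow_reflection)
    Mnew <- Reduce(`+`, Xs) / n
    Mnew <- Mnew / sqrt(sum(Mnew^2))
    delta <- sqrt(sum((Mnew - M)^2))
    M <- Mnew
    # refine well past `tol` so the fixed point -- and hence the output
    # after canonical rotation -- is independent of input order
    if (delta < 1e-14) { converged <- TRUE; break }
    if (delta < tol) converged <- TRUE
    if (iter >= max_iter) break
  }

  V <- canonical_rotation(M)
  M <- M %*% V
  aligned <- array(NA_real_, c(n, k, 2L), dimnames = list(ids, NULL, c("x", "y")))
  for (i in seq_len(n)) aligned[i, , ] <- Xs[[i]] %*% V

  structure(list(aligned = aligned,
                 centroid_sizes = stats::setNames(cs, ids),
                 mean_shape = M,
                 specimen_id = ids,
                 species = if (is.null(meta)) rep(NA_character_, n) else meta$species,
                 ecology = if (is.null(meta)) rep(NA_character_, n) else meta$ecology,
                 iterations = iter, converged = converged, slid = FALSE),
            class = "shape_sample")
}

#' @export
print.shape_sample <- function(x, ...) {
  cat(sprintf("shape_sample: %d configurations x %d landmarks%s (GPA %sconverged in %d iterations)\n",
              dim(x$aligned)[1L], dim(x$aligned)[2L],
              if (isTRUE(x$slid)) ", semilandmarks slid" else "",
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#'
#' @param X,Y k x 2 coordinate matrices (already superimposed).
#' @return The square root of the summed squared coordinate differences.
#' @export
procrustes_distance <- function(X, Y) sqrt(sum((X - Y)^2))
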