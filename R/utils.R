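# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Permutation p-value, (count + 1)/(n + 1) convention.
perm_pval <- function(null, obs, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  k <- if (tail == "ge") sum(null >= obs) else sum(null <= obs)
  (k + 1) / (length(null) + 1)
}

null_summary <- function(null) {
  null <- null[is.finite(null)]
  if (length(null) == 0L) return(NULL)
  list(mean = mean(null), sd = stats::sd(null),
       quantiles = stats::quantile(null, c(0.025, 0.05, 0.5, 0.95, 0.975)))
}

new_claw_test <- function(statistic, p_value, n_perm, seed, null,
                          effect_size_z = NULL, ...) {
  structure(
    c(list(statistic = statistic, p_value = p_value,
           effect_size_z = effect_size_z, n_perm = n_perm, seed = seed,
           null_summary = null_summary(null)),
      list(...)),
    class = "claw_test")
}

#' @export
print.claw_test <- function(x, ...) {
  cat(sprintf("%s test\n", if (is.null(x$test)) "Permutation/simulation" else x$test))
  cat(sprintf("  statistic = %.6g, p = %.4g", x$statistic, x$p_value))
  if (!is.null(x$effect_size_z)) cat(sprintf(", z = %.4g", x$effect_size_z))
  if (!is.null(x$n_perm))
    cat(sprintf("\n  n_perm = %d, seed = %s", x$n_perm, format(x$seed)))
  cat("\n")
  invisible(x)
}

# Symmetric inverse square root of a PSD matrix; eigenvalues clipped at
# 1e-12 * trace so near-singular phylogenetic covariances stay usable.
inv_sqrt_psd <- function(C) {
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  clip <- 1e-12 * sum(diag(C))
  vals <- pmax(eg$values, clip)
  eg$vectors %*% ((1 / sqrt(vals)) * t(eg$vectors))
}

# Lower-triangular-like factor L with L %*% t(L) = M for PSD M.
psd_factor <- function(M) {
  M <- (M + t(M)) / 2
  out <- tryCatch(t(chol(M)), error = function(e) NULL)
  if (!is.null(out)) return(out)
  eg <- eigen(M, symmetric = TRUE)
  tol <- 1e-12 * max(abs(eg$values), 1e-300)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("matrix is not positive semi-definite", call. = FALSE)
  eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(M))
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

# Interleaved flattening of an n x k x 2 array into n x 2k (x1,y1,x2,y2,...).

#' Flatten shape data to a specimen-by-coordinate matrix
#'
#' Converts a [gpa()] result or an `n x k x 2` coordinate array into an
#' `n x 2k` matrix with interleaved columns `x1, y1, x2, y2, ...`, the layout
#' expected by the statistical routines.
#'
#' @param x A `shape_sample` or a 3-d array of landmark coordinates.
#' @return A numeric matrix with one row per specimen.
#' @export
as_shape_matrix <- function(x) {
  if (inherits(x, "shape_sample")) x <- x$aligned
  if (is.matrix(x)) return(x)
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3] == 2L)
  n <- dim(x)[1]; k <- dim(x)[2]
  m <- matrix(aperm(x, c(1, 3, 2)), n, 2L * k)
  colnames(m) <- as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
  rownames(m) <- dimnames(x)[[1]]
  m
}

# Inverse of as_shape_matrix().
shape_matrix_to_array <- function(m) {
  n <- nrow(m); k <- ncol(m) / 2L
  arr <- aperm(array(as.numeric(m), c(n, 2L, k)), c(1, 3, 2))
  dimnames(arr) <- list(rownames(m), NULL, c("x", "y"))
  arr
}

# Column indices (interleaved layout) belonging to a set of landmark indices.
landmark_cols <- function(lm_idx) {
  as.vector(rbind(2L * lm_idx - 1L, 2L * lm_idx))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
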