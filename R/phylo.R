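# Phylogenetic comparative statistics: PGLS with maximum-likelihood Pagel's
# lambda, simulation-based phylogenetic ANOVA, multivariate phylogenetic
# signal (K-mult), phylogenetic Procrustes ANOVA (GLS + residual
# randomization), the evolutionary covariance matrix, and a phylogenetic
# paired t test.

check_C <- function(C, n) {
  C <- as.matrix(C)
  if (nrow(C) != n || ncol(C) != n)
    stop("phylogenetic covariance has the wrong dimension", call. = FALSE)
  C
}

# GLS building blocks at a fixed lambda. Uses the Cholesky factor of the
# transformed covariance; errors if that is singular.
gls_pieces <- function(C, lam) {
  Cl <- lambda_transform(C, lam)
  R <- tryCatch(chol(Cl), error = function(e)
    stop("singular phylogenetic covariance", call. = FALSE))
  list(R = R, logdet = 2 * sum(log(diag(R))))
}

gls_transform <- function(R, M) backsolve(R, M, transpose = TRUE)

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Profiles the Gaussian log-likelihood over lambda in \[0, 1\] (bounded
#' scalar optimization plus endpoint checks), with GLS coefficient
#' estimates and the ML variance at each lambda. R-squared compares the
#' GLS residual sum of squares to that of the intercept-only GLS fit at the
#' same lambda; coefficient p-values use t statistics with n - p degrees of
#' freedom.
#'
#' @param y Response vector (species means).
#' @param X Predictors: `NULL` for intercept-only, a numeric vector/matrix,
#'   or a data frame (factors are dummy-coded). An intercept is always added.
#' @param C Phylogenetic covariance matrix in the same species order as `y`.
#' @return A list of class `pgls_fit`.
#' @export
pgls_ml_lambda <- function(y, X = NULL, C) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)
  C <- check_C(C, n)
  Xm <- if (is.null(X)) matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
        else stats::model.matrix(~ ., data = as.data.frame(X))
  p <- ncol(Xm)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)

  fit_at <- function(lam) {
    gp <- gls_pieces(C, lam)
    yt <- gls_transform(gp$R, y)
    Xt <- gls_transform(gp$R, Xm)
    qr_x <- qr(Xt)
    if (qr_x$rank < p) stop("singular design matrix in PGLS", call. = FALSE)
    beta <- qr.coef(qr_x, yt)
    e <- yt - Xt %*% beta
    sigma2 <- sum(e^2) / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + gp$logdet + n)
    list(lambda = lam, beta = beta, rss = sum(e^2), sigma2 = sigma2,
         loglik = ll, qr = qr_x, yt = yt, Xt = Xt, R = gp$R)
  }
  opt <- stats::optimize(function(l) fit_at(l)$loglik, c(0, 1),
                         maximum = TRUE, tol = 1e-6)
  cand <- list(fit_at(0), fit_at(1), fit_at(opt$maximum))
  best <- cand[[which.max(vapply(cand, `[[`, 0, "loglik"))]]

  # R^2 against the intercept-only GLS fit at the same lambda
  ones_t <- gls_transform(best$R, matrix(1, n, 1L))
  mu0 <- sum(ones_t * best$yt) / sum(ones_t^2)
  rss0 <- sum((best$yt - ones_t * mu0)^2)
  r2 <- 1 - best$rss / rss0

  s2_unb <- best$rss / (n - p)
  XtX_inv <- chol2inv(qr.R(best$qr))
  se <- sqrt(pmax(diag(XtX_inv), 0) * s2_unb)
  tval <- best$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coef_table <- cbind(estimate = best$beta, se = se, t = tval, p = pval)
  rownames(coef_table) <- colnames(Xm)

  fitted <- drop(Xm %*% best$beta)
  structure(list(coefficients = coef_table, lambda = best$lambda,
                 log_likelihood = best$loglik, r2 = r2,
                 sigma2_ml = best$sigma2, fitted = fitted,
                 residuals = y - fitted, df_residual = n - p, n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (ML lambda = %.4f, logLik = %.3f, R2 = %.4f)\n",
              x$lambda, x$log_likelihood, x$r2))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

# One-way ANOVA F for one or more response columns at once.
anova_F_cols <- function(Ymat, groups) {
  groups <- as.factor(groups)
  n <- nrow(Ymat); k <- nlevels(groups)
  gm <- colMeans(Ymat)
  tot <- colSums(sweep(Ymat, 2L, gm)^2)
  means <- rowsum(Ymat, groups) / as.vector(table(groups))
  ssb <- colSums((means - matrix(gm, k, ncol(Ymat), byrow = TRUE))^2 *
                   as.vector(table(groups)))
  ssw <- tot - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

pairwise_t_stats <- function(Ymat, groups) {
  groups <- as.factor(groups)
  lv <- levels(groups); k <- length(lv)
  tab <- as.vector(table(groups))
  n <- nrow(Ymat)
  means <- rowsum(Ymat, groups) / tab
  ssw <- matrix(0, 1L, ncol(Ymat))
  for (g in seq_len(k))
    ssw <- ssw + colSums(sweep(Ymat[groups == lv[g], , drop = FALSE], 2L,
                               means[g, ])^2)
  sp2 <- ssw / (n - k)
  pairs <- utils::combn(k, 2L)
  out <- matrix(NA_real_, ncol(pairs), ncol(Ymat))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    out[j, ] <- (means[a, ] - means[b, ]) /
      sqrt(sp2 * (1 / tab[a] + 1 / tab[b]))
  }
  rownames(out) <- paste(lv[pairs[1L, ]], lv[pairs[2L, ]], sep = ":")
  out
}

#' Simulation-based phylogenetic ANOVA
#'
#' The observed statistic is the ordinary one-way ANOVA F on species means;
#' the null distribution is built by simulating Brownian motion on the tree
#' (rate from the ML estimate for the trait) and recomputing F. Pairwise
#' group t statistics are compared against their simulated nulls with Holm
#' correction.
#'
#' @param y Trait vector (species means, ordered as `C`).
#' @param groups Group labels.
#' @param C Phylogenetic covariance matrix.
#' @param n_sim Number of Brownian simulations.
#' @param seed RNG seed.
#' @return A `claw_test` with a `pairwise` data frame.
#' @export
phylo_anova_sim <- function(y, groups, C, n_sim = 1000, seed = 1) {
  y <- as.numeric(y)
  n <- length(y)
  C <- check_C(C, n)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  F_obs <- anova_F_cols(matrix(y, ncol = 1L), groups)
  t_obs <- pairwise_t_stats(matrix(y, ncol = 1L), groups)[, 1L]

  Cinv <- chol2inv(chol(C))
  mu <- sum(Cinv %*% y) / sum(Cinv)
  d <- y - mu
  sig2 <- drop(t(d) %*% Cinv %*% d) / n     # ML Brownian rate
  L <- psd_factor(sig2 * C)
  sims <- with_seed(seed, L %*% matrix(stats::rnorm(n * n_sim), n, n_sim) + mu)
  F_null <- anova_F_cols(sims, groups)
  t_null <- pairwise_t_stats(sims, groups)

  p_pairs <- vapply(seq_along(t_obs), function(j)
    perm_pval(abs(t_null[j, ]), abs(t_obs[j]), "ge"), 0)
  pairwise <- data.frame(pair = names(t_obs), t = unname(t_obs),
                         p = p_pairs, p_holm = stats::p.adjust(p_pairs, "holm"),
                         stringsAsFactors = FALSE)
  if (all(is.na(F_obs)) || !is.finite(F_obs)) F_obs <- 0
  new_claw_test(statistic = unname(F_obs),
                p_value = if (F_obs == 0 && stats::var(y) == 0) 1
                          else perm_pval(F_null, F_obs, "ge"),
                n_perm = n_sim, seed = seed, null = F_null,
                effect_size_z = (F_obs - mean(F_null)) / stats::sd(F_null),
                test = "phylogenetic ANOVA (Brownian simulation)",
                pairwise = pairwise)
}

#' Multivariate phylogenetic signal (K-mult)
#'
#' The multivariate generalization of Blomberg's K: the ratio of observed to
#' Brownian-expected phylogenetic signal, equal to 1 in expectation under
#' Brownian motion. Significance comes from permuting specimen rows of the
#' data across the tips.
#'
#' @param Y n x p trait or shape matrix (species rows, ordered as `C`).
#' @param C Phylogenetic covariance matrix.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return A `claw_test` whose statistic is K-mult.
#' @export
k_mult <- function(Y, C, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 4L) stop("K-mult requires at least 4 species", call. = FALSE)
  C <- check_C(C, n)
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e)
    stop("singular phylogenetic covariance", call. = FALSE))
  denom <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  k_of <- function(Ym) {
    a <- colSums(Cinv %*% Ym) / sum(Cinv)
    E <- Ym - matrix(a, n, ncol(Ym), byrow = TRUE)
    (sum(E * E) / sum(E * (Cinv %*% E))) / denom
  }
  K_obs <- k_of(Y)
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) k_of(Y[sample.int(n), , drop = FALSE]), 0))
  new_claw_test(statistic = K_obs, p_value = perm_pval(null, K_obs, "ge"),
                n_perm = n_perm, seed = seed, null = null,
                effect_size_z = (K_obs - mean(null)) / stats::sd(null),
                test = "phylogenetic signal (K-mult)")
}

#' Evolutionary covariance matrix
#'
#' The trait covariance matrix conditioned on the phylogeny under Brownian
#' motion: deviations from the phylogenetic (GLS) mean, weighted by the
#' inverse phylogenetic covariance, with divisor n - 1.
#'
#' @param Y n x p trait/shape matrix.
#' @param C Phylogenetic covariance matrix (identity gives the ordinary
#'   covariance).
#' @return A p x p symmetric PSD matrix.
#' @export
evolutionary_covariance <- function(Y, C) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 species", call. = FALSE)
  C <- check_C(C, n)
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e)
    stop("singular phylogenetic covariance", call. = FALSE))
  a <- colSums(Cinv %*% Y) / sum(Cinv)
  E <- Y - matrix(a, n, ncol(Y), byrow = TRUE)
  S <- crossprod(E, Cinv %*% E) / (n - 1)
  (S + t(S)) / 2
}

#' Phylogenetic Procrustes ANOVA with residual randomization
#'
#' GLS-transforms shapes and the design by the inverse square root of the
#' phylogenetic covariance, computes sequential (type-I) sums of squares for
#' the covariate then the group term (each summed across all shape
#' dimensions, Goodall-style F), and tests each term by residual
#' randomization of its reduced model (RRPP). Pairwise group differences are
#' distances between size-adjusted group GLS means against their permuted
#' distribution, with Holm correction.
#'
#' @param Y n x p shape matrix (species rows).
#' @param covariate Numeric covariate (log centroid size).
#' @param groups Group labels.
#' @param C Phylogenetic covariance matrix; identity gives an ordinary
#'   Procrustes ANOVA.
#' @param n_perm Number of RRPP permutations.
#' @param seed RNG seed.
#' @return A list of class `procrustes_anova` with per-term `claw_test`s
#'   (`covariate`, `group`), an ANOVA table, and a `pairwise` data frame.
#' @export
phylo_procrustes_anova <- function(Y, covariate, groups, C, n_perm = 999,
                                   seed = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  C <- check_C(C, n)
  groups <- as.factor(groups)
  covariate <- as.numeric(covariate)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  U <- inv_sqrt_psd(C)
  Yt <- U %*% Y
  X_full <- stats::model.matrix(~ covariate + groups)
  if (qr(X_full)$rank < ncol(X_full))
    stop("rank-deficient design (covariate confounded with groups?)",
         call. = FALSE)
  Xt <- U %*% X_full
  qrf <- qr(Xt)
  Q <- qr.Q(qrf)                 # ordered: intercept | covariate | groups
  idx_int <- 1L
  idx_cov <- 2L
  idx_grp <- 2L + seq_len(k - 1L)
  df_cov <- 1L; df_grp <- k - 1L
  df_res <- n - ncol(X_full)

  ss_parts <- function(Ym) {
    Qy <- crossprod(Q, Ym)
    ss_cov <- sum(Qy[idx_cov, ]^2)
    ss_grp <- sum(Qy[idx_grp, , drop = FALSE]^2)
    ss_res <- sum(Ym^2) - sum(Qy^2)
    c(cov = ss_cov, grp = ss_grp, res = ss_res)
  }
  obs <- ss_parts(Yt)
  F_cov <- (obs["cov"] / df_cov) / (obs["res"] / df_res)
  F_grp <- (obs["grp"] / df_grp) / (obs["res"] / df_res)

  # group GLS means adjusted to the mean covariate (for pairwise distances)
  beta_of <- function(Ym) qr.coef(qrf, Ym)
  group_means <- function(B) {
    out <- matrix(NA_real_, k, ncol(Y))
    cbar <- mean(covariate)
    for (g in seq_len(k)) {
      xrow <- numeric(ncol(X_full))
      xrow[1L] <- 1; xrow[2L] <- cbar
      if (g > 1L) xrow[2L + g - 1L] <- 1
      out[g, ] <- drop(xrow %*% B)
    }
    rownames(out) <- levels(groups)
    out
  }
  gm_obs <- group_means(beta_of(Yt))
  pairs <- utils::combn(levels(groups), 2L)
  d_obs <- vapply(seq_len(ncol(pairs)), function(j)
    sqrt(sum((gm_obs[pairs[1L, j], ] - gm_obs[pairs[2L, j], ])^2)), 0)

  # RRPP: permute reduced-model residuals (GLS scale) for each term
  H_int <- tcrossprod(Q[, idx_int, drop = FALSE])
  Q_ic <- Q[, c(idx_int, idx_cov), drop = FALSE]
  H_ic <- tcrossprod(Q_ic)
  fit_int <- H_int %*% Yt;  res_int <- Yt - fit_int
  fit_ic <- H_ic %*% Yt;    res_ic <- Yt - fit_ic

  F_cov_null <- numeric(n_perm)
  F_grp_null <- numeric(n_perm)
  d_null <- matrix(NA_real_, n_perm, ncol(pairs))
  with_seed(seed, for (i in seq_len(n_perm)) {
    pm <- sample.int(n)
    Y1 <- fit_int + res_int[pm, , drop = FALSE]      # null for covariate
    s1 <- ss_parts(Y1)
    F_cov_null[i] <- (s1["cov"] / df_cov) / (s1["res"] / df_res)
    Y2 <- fit_ic + res_ic[pm, , drop = FALSE]        # null for group term
    s2 <- ss_parts(Y2)
    F_grp_null[i] <- (s2["grp"] / df_grp) / (s2["res"] / df_res)
    gm <- group_means(beta_of(Y2))
    d_null[i, ] <- vapply(seq_len(ncol(pairs)), function(j)
      sqrt(sum((gm[pairs[1L, j], ] - gm[pairs[2L, j], ])^2)), 0)
  })

  p_pairs <- vapply(seq_len(ncol(pairs)), function(j)
    perm_pval(d_null[, j], d_obs[j], "ge"), 0)
  pairwise <- data.frame(pair = paste(pairs[1L, ], pairs[2L, ], sep = ":"),
                         distance = d_obs, p = p_pairs,
                         p_holm = stats::p.adjust(p_pairs, "holm"),
                         stringsAsFactors = FALSE)
  tab <- data.frame(term = c("covariate", "group", "residual"),
                    df = c(df_cov, df_grp, df_res),
                    SS = unname(obs),
                    F = c(F_cov, F_grp, NA),
                    p = c(perm_pval(F_cov_null, F_cov, "ge"),
                          perm_pval(F_grp_null, F_grp, "ge"), NA),
                    stringsAsFactors = FALSE)
  structure(list(
    covariate = new_claw_test(unname(F_cov), tab$p[1L], n_perm, seed,
                              F_cov_null,
                              effect_size_z = (F_cov - mean(F_cov_null)) /
                                stats::sd(F_cov_null),
                              test = "phylogenetic Procrustes ANOVA: covariate"),
    group = new_claw_test(unname(F_grp), tab$p[2L], n_perm, seed, F_grp_null,
                          effect_size_z = (F_grp - mean(F_grp_null)) /
                            stats::sd(F_grp_null),
                          test = "phylogenetic Procrustes ANOVA: group"),
    table = tab, pairwise = pairwise, n_perm = n_perm, seed = seed),
    class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Phylogenetic Procrustes ANOVA (RRPP)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Phylogenetic paired t test
#'
#' Tests whether the mean of the paired difference is zero under a
#' lambda-transformed Brownian model: lambda is estimated by ML for the
#' differences, the mean is the GLS mean, and the t statistic uses the
#' (bias-adjusted) ML variance with n - 1 degrees of freedom.
#'
#' @param x1,x2 Paired trait vectors (species means, ordered as `C`).
#' @param C Phylogenetic covariance matrix.
#' @return A list of class `claw_test` (statistic = t, df = n - 1).
#' @export
phylo_paired_t <- function(x1, x2, C) {
  d <- as.numeric(x1) - as.numeric(x2)
  n <- length(d)
  if (n < 3L) stop("paired t test requires at least 3 species", call. = FALSE)
  C <- check_C(C, n)
  if (all(d == 0)) {
    return(structure(list(statistic = 0, p_value = 1, estimate = 0,
                          lambda = 0, df = n - 1L, test = "phylogenetic paired t"),
                     class = "claw_test"))
  }
  fit <- pgls_ml_lambda(d, NULL, C)
  mu <- fit$coefficients[1L, "estimate"]
  gp <- gls_pieces(C, fit$lambda)
  ones_t <- gls_transform(gp$R, matrix(1, n, 1L))
  inv_11 <- 1 / sum(ones_t^2)                # (1' C_lambda^-1 1)^-1
  tstat <- mu / sqrt(fit$sigma2_ml * n / (n - 1) * inv_11)
  structure(list(statistic = unname(tstat),
                 p_value = 2 * stats::pt(-abs(tstat), df = n - 1L),
                 estimate = unname(mu), lambda = fit$lambda, df = n - 1L,
                 test = "phylogenetic paired t"),
            class = "claw_test")
}
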