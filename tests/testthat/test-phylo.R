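# Phylogenetic comparative statistics: covariance construction, PGLS,
# K-mult, evolutionary covariance, Procrustes ANOVA, paired t.

test_that("phylo_covariance matches hand bookkeeping", {
  tr <- read_newick(newick_abc())
  C <- phylo_covariance(tr, c("A", "B", "C"))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)
  # star tree with unit branches -> identity
  tf <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,C:1,D:1);", tf)
  expect_equal(phylo_covariance(read_newick(tf)), diag(4), ignore_attr = TRUE)
  # ultrametric tree -> constant diagonal
  tr2 <- simulate_tree(16, seed = 4)
  expect_equal(unname(diag(phylo_covariance(tr2))), rep(1, 16),
               tolerance = 1e-10)
})

test_that("lambda_transform scales off-diagonals and preserves PSD", {
  tr <- simulate_tree(12, seed = 5)
  C <- phylo_covariance(tr)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  for (lam in c(0.2, 0.5, 0.9)) {
    ev <- eigen(lambda_transform(C, lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-9 * max(ev))
  }
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
})

test_that("PGLS reduces to OLS on a star tree and maximizes the likelihood", {
  set.seed(11)
  n <- 40
  C <- star_covariance(n)
  x <- rnorm(n); g <- factor(rep(c("u", "v"), n / 2))
  y <- 1 + 0.8 * x + 0.5 * (g == "v") + rnorm(n, 0, 0.4)
  fit <- pgls_ml_lambda(y, data.frame(x = x, g = g), C)
  ols <- lm(y ~ x + g)
  expect_equal(unname(fit$coefficients[, "estimate"]), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(fit$r2, summary(ols)$r.squared, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[, "p"]),
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-8)

  # optimality audit: profile logLik at lambda_hat beats random lambdas
  tr <- simulate_tree(48, seed = 6)
  Ct <- phylo_covariance(tr)
  yv <- drop(simulate_bm_traits(tr, 0, matrix(1), lambda_true = 0.6, seed = 7))
  xv <- drop(simulate_bm_traits(tr, 0, matrix(1), lambda_true = 1, seed = 8))
  fit2 <- pgls_ml_lambda(yv, xv, Ct)
  ll_at <- function(lam) {
    Cl <- lambda_transform(Ct, lam)
    R <- chol(Cl)
    yt <- backsolve(R, yv, transpose = TRUE)
    Xt <- backsolve(R, cbind(1, xv), transpose = TRUE)
    e <- yt - Xt %*% qr.coef(qr(Xt), yt)
    s2 <- sum(e^2) / 48
    -0.5 * (48 * log(2 * pi * s2) + 2 * sum(log(diag(R))) + 48)
  }
  expect_equal(fit2$log_likelihood, ll_at(fit2$lambda), tolerance = 1e-9)
  set.seed(13)
  for (lam in runif(100)) expect_gte(fit2$log_likelihood + 1e-6, ll_at(lam))
  expect_error(pgls_ml_lambda(c(yv[1:4], NA), NULL, Ct[1:5, 1:5]), "non-finite")
})

test_that("K-mult is exactly 1 on a star tree and matches univariate K", {
  set.seed(21)
  n <- 24
  C <- star_covariance(n)
  Y <- matrix(rnorm(n * 6), n)
  expect_equal(k_mult(Y, C, n_perm = 9, seed = 1)$statistic, 1,
               tolerance = 1e-12)

  tr <- simulate_tree(32, seed = 9)
  Ct <- phylo_covariance(tr)
  yv <- simulate_bm_traits(tr, 0, matrix(1), 1, seed = 10)
  K <- k_mult(yv, Ct, n_perm = 9, seed = 2)$statistic
  # independent univariate Blomberg's K (explicit-inverse formula)
  Ci <- solve(Ct)
  a <- sum(Ci %*% yv) / sum(Ci)
  d <- yv - a
  K_uni <- (sum(d^2) / drop(t(d) %*% Ci %*% d)) /
    ((sum(diag(Ct)) - 32 / sum(Ci)) / 31)
  expect_equal(K, K_uni, tolerance = 1e-10)
})

test_that("evolutionary covariance reduces to ordinary covariance and matches oracle", {
  set.seed(31)
  Y <- matrix(rnorm(20 * 4), 20)
  C <- star_covariance(20)
  expect_equal(evolutionary_covariance(Y, C), cov(Y), tolerance = 1e-10,
               ignore_attr = TRUE)
  tr <- simulate_tree(6, seed = 11)
  Ct <- phylo_covariance(tr)
  Y6 <- matrix(rnorm(6 * 3), 6)
  Ci <- solve(Ct)
  a <- drop(rep(1, 6) %*% Ci %*% Y6) / sum(Ci)
  E <- sweep(Y6, 2, a)
  S_oracle <- t(E) %*% Ci %*% E / 5
  S <- evolutionary_covariance(Y6, Ct)
  expect_equal(S, (S_oracle + t(S_oracle)) / 2, tolerance = 1e-10)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9 * max(abs(ev)))
})

test_that("phylogenetic paired t reduces to the ordinary paired t", {
  set.seed(41)
  n <- 20
  C <- star_covariance(n)
  x1 <- rnorm(n); x2 <- x1 + rnorm(n, 0.3, 0.5)
  res <- phylo_paired_t(x1, x2, C)
  tt <- t.test(x1, x2, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-8)
  expect_identical(phylo_paired_t(x1, x1, C)$statistic, 0)
  expect_identical(phylo_paired_t(x1, x1, C)$p_value, 1)
  expect_error(phylo_paired_t(1:2, 2:3, diag(2)), "at least 3")
})

test_that("phylo_anova_sim handles trivial and separated data", {
  tr <- simulate_tree(24, seed = 13)
  C <- phylo_covariance(tr)
  g <- rep(c("a", "b", "c"), each = 8)
  y0 <- rep(1, 24)
  res0 <- phylo_anova_sim(y0, g, C, n_sim = 99, seed = 3)
  expect_identical(res0$statistic, 0)
  expect_identical(res0$p_value, 1)
  # strongly separated groups: smallest attainable p
  set.seed(14)
  y1 <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1), rnorm(8, 20, 0.1))
  res1 <- phylo_anova_sim(y1, g, C, n_sim = 199, seed = 4)
  expect_equal(res1$p_value, 1 / 200)
  expect_true(all(res1$pairwise$p_holm <= 0.05))
  expect_error(phylo_anova_sim(y1, rep("a", 24), C, seed = 1), "2 groups")
  # determinism: same seed, identical null
  res2 <- phylo_anova_sim(y1, g, C, n_sim = 199, seed = 4)
  expect_identical(res1$p_value, res2$p_value)
  expect_identical(res1$null_summary$mean, res2$null_summary$mean)
})

test_that("phylogenetic Procrustes ANOVA: orthogonal covariate, group power", {
  set.seed(51)
  n <- 30; p <- 10
  C <- star_covariance(n)
  cov_x <- rnorm(n)
  # zero-allometry construction: shapes orthogonal to the covariate
  Y <- matrix(rnorm(n * p), n)
  Y <- qr.resid(qr(cbind(1, cov_x)), Y)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  res <- phylo_procrustes_anova(Y, cov_x, g, C, n_perm = 199, seed = 5)
  expect_lt(res$table$SS[1], 1e-20)
  expect_lt(res$covariate$statistic, res$covariate$null_summary$mean)

  # injected group mean shift of ~5 within-group sd: smallest attainable p
  Y2 <- matrix(rnorm(n * p), n)
  Y2[g == "b", 1] <- Y2[g == "b", 1] + 5
  Y2[g == "c", 2] <- Y2[g == "c", 2] + 5
  res2 <- phylo_procrustes_anova(Y2, cov_x, g, C, n_perm = 199, seed = 6)
  expect_equal(res2$group$p_value, 1 / 200)
  expect_true(any(res2$pairwise$p_holm <= 0.05))
  expect_error(phylo_procrustes_anova(Y2, rep(1, n) + as.numeric(g == "b"),
                                      factor(c("a", "b")[1 + (g == "b")]),
                                      C, n_perm = 9, seed = 1))
})
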