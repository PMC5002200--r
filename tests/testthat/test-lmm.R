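test_that("boundary fits collapse to ordinary least squares", {
  set.seed(11)
  n <- 40
  tree <- factor(sprintf("T%02d", 1:n))  # one observation per tree
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- 2 + 0.5 * X[, 2] + rnorm(n)
  fit <- fit_lmm(y, X, tree)
  ols <- lm(y ~ X[, 2])
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$sigma2_tree, 0)
})

test_that("balanced intercept-only REML equals the ANOVA closed form", {
  set.seed(12)
  q <- 10; r <- 4
  tree <- factor(rep(1:q, each = r))
  y <- rnorm(q, sd = 1.2)[tree] + rnorm(q * r, sd = 0.7)
  fit <- fit_lmm(y, cbind("(Intercept)" = rep(1, q * r)), tree)
  oracle <- anova_oracle(y, tree)
  expect_equal(fit$sigma2_tree, oracle$sigma2_b, tolerance = 1e-6)
  expect_equal(fit$sigma2_err, oracle$sigma2_e, tolerance = 1e-6)
})

test_that("adding a constant to y shifts only the intercept", {
  set.seed(13)
  tree <- factor(rep(1:8, each = 3))
  X <- cbind("(Intercept)" = 1, x = rnorm(24))
  y <- rnorm(8)[tree] + rnorm(24)
  f1 <- fit_lmm(y, X, tree)
  f2 <- fit_lmm(y + 5, X, tree)
  expect_equal(f2$beta[["(Intercept)"]] - f1$beta[["(Intercept)"]], 5,
               tolerance = 1e-6)
  expect_equal(f2$beta[["x"]], f1$beta[["x"]], tolerance = 1e-6)
  expect_equal(f2$sigma2_tree, f1$sigma2_tree, tolerance = 1e-6)
})

test_that("marginal R2 follows the variance-share formula", {
  mk <- function(fix, rand, err) structure(
    list(sigma2_fix = fix, sigma2_tree = rand, sigma2_err = err),
    class = "plast_lmm")
  expect_equal(marginal_r2(mk(1, 1, 2)), 0.25)
  expect_equal(marginal_r2(mk(0, 1, 1)), 0)
  expect_equal(marginal_r2(mk(3, 0, 0)), 1)
  expect_error(marginal_r2(mk(0, 0, 0)), "undefined")
})

test_that("rank-deficient designs error naming the aliased columns", {
  tree <- factor(rep(1:5, each = 2))
  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_lmm(rnorm(10), X, tree), "dup")
})

test_that("KR test equals the classical F-test on balanced designs", {
  set.seed(14)
  q <- 12; r <- 3
  samples <- balanced_samples(q, r)
  tree <- factor(samples$TREE)
  prov <- factor(samples$PROVENANCE)
  y <- rnorm(q, sd = 1)[tree] + 0.5 * (as.integer(prov) - 1) + rnorm(q * r)
  X_full <- model.matrix(~prov)
  X_red <- X_full[, 1, drop = FALSE]
  kr <- kr_ftest(fit_lmm(y, X_full, tree), fit_lmm(y, X_red, tree))
  # classical between-tree analysis: provenance tested on the tree means
  means <- tapply(y, tree, mean)
  pm <- factor(tapply(as.character(prov), tree, unique))
  an <- anova(lm(means ~ pm))
  expect_equal(kr$ddf, q - 2, tolerance = 1e-6)
  expect_equal(kr$F, an$`F value`[1], tolerance = 1e-6)
  expect_equal(kr$p, an$`Pr(>F)`[1], tolerance = 1e-6)
})

test_that("KR reduces to the OLS F-test when the tree variance is zero", {
  set.seed(15)
  n <- 30
  tree <- factor(sprintf("T%02d", 1:n))  # no replication: boundary fit
  x <- rnorm(n); z <- rnorm(n)
  y <- 1 + 0.3 * x + rnorm(n)
  X_full <- cbind("(Intercept)" = 1, x = x, z = z)
  full <- fit_lmm(y, X_full, tree)
  expect_equal(full$sigma2_tree, 0)
  kr <- kr_ftest(full, fit_lmm(y, X_full[, 1:2], tree))
  an <- anova(lm(y ~ x + z), lm(y ~ x))
  expect_equal(kr$F, an$F[2], tolerance = 1e-6)
  expect_equal(kr$ddf, n - 3, tolerance = 1e-6)
  expect_equal(kr$p, an$`Pr(>F)`[2], tolerance = 1e-6)
})

test_that("KR statistics agree with the pbkrtest oracle on unbalanced data", {
  skip_if_not_installed("pbkrtest")
  set.seed(16)
  for (rep in 1:3) {
    n_tree <- 20
    sizes <- sample(1:5, n_tree, replace = TRUE)
    tree <- factor(rep(seq_len(n_tree), sizes))
    n <- length(tree)
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 1 + 0.4 * x1 + rnorm(n_tree, sd = 0.9)[tree] + rnorm(n, sd = 0.7)
    X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
    kr <- kr_ftest(fit_lmm(y, X, tree), fit_lmm(y, X[, c(1, 2)], tree))
    lf <- lme4::lmer(y ~ x1 + x2 + (1 | tree), REML = TRUE)
    lr <- lme4::lmer(y ~ x1 + (1 | tree), REML = TRUE)
    pb <- pbkrtest::KRmodcomp(lf, lr)$stats
    expect_equal(kr$F, pb$Fstat, tolerance = 1e-3)
    expect_equal(kr$ddf, pb$ddf, tolerance = 1e-3)
    expect_equal(kr$p, pb$p.value, tolerance = 1e-3)
  }
})

test_that("ML refits give AICs matching lme4", {
  set.seed(17)
  tree <- factor(rep(1:10, each = 3))
  x <- rnorm(30)
  y <- rnorm(10, sd = 0.8)[tree] + 0.2 * x + rnorm(30)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_lmm(y, X, tree, method = "ML")
  lf <- lme4::lmer(y ~ x + (1 | tree), REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(lf), tolerance = 1e-6)
})
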