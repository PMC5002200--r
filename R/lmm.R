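#' Fit a linear mixed model with a single random intercept
#'
#' Fits `y = X beta + Z u + e` where `Z` is the indicator matrix of a grouping
#' factor (here: the individual tree), `u ~ N(0, sigma2_tree I)` and
#' `e ~ N(0, sigma2_err I)`.  Estimation profiles the likelihood over the
#' variance ratio `gamma = sigma2_tree / sigma2_err`: for a given `gamma` the
#' GLS estimate of `beta` and the residual variance are available in closed
#' form, so only a one-dimensional criterion is optimized.  Boundary fits
#' (`gamma = 0`) collapse to ordinary least squares and are valid results.
#'
#' @param y numeric response vector (log-scale expression of one transcript).
#' @param X fixed-effects design matrix with column names; must be full column
#'   rank.
#' @param tree grouping factor (one level per tree), same length as `y`.
#' @param method `"REML"` (default) or `"ML"`.  REML is used for variance
#'   estimation and Kenward-Roger testing; ML refits are used for AIC.
#' @return An object of class `plast_lmm`: a list with elements `beta`,
#'   `vcov_beta` (GLS covariance of `beta` at the variance optimum),
#'   `sigma2_tree`, `sigma2_err`, `sigma2_fix` (population variance of the
#'   fixed-effect predictor `X beta`, i.e. divided by `n`), `gamma`, `loglik`
#'   (of the requested criterion), `aic` (ML fits only), `n`, `p`, `method`,
#'   plus the design (`X`, `tree`) for downstream tests.
#' @seealso [kr_ftest()], [compare_nested()], [marginal_r2()]
#' @export
fit_lmm <- function(y, X, tree, method = c("REML", "ML")) {
  method <- match.arg(method)
  prep <- lmm_prep(X, tree)
  .lmm_fit(prep, y, reml = identical(method, "REML"))
}

#' Precompute design structures for repeated single-random-intercept fits
#'
#' Per-transcript pipelines fit the same design to thousands of transcripts;
#' this captures everything that depends only on `X` and the grouping factor.
#'
#' @inheritParams fit_lmm
#' @return A list of class `plast_lmm_prep`.
#' @export
lmm_prep <- function(X, tree) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(tree))
    stop("'X' and 'tree' imply different numbers of observations")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  tree <- droplevels(as.factor(tree))
  g <- as.integer(tree)
  q <- nlevels(tree)
  ni <- tabulate(g, q)
  structure(list(
    X = X, tree = tree, g = g, q = q, ni = ni,
    n = nrow(X), p = ncol(X),
    XtX = crossprod(X),
    Sg = rowsum(X, g, reorder = TRUE)  # q x p group sums, level order
  ), class = "plast_lmm_prep")
}

# GLS pieces at a given variance ratio gamma, using the Woodbury identity
#   (I + gamma Z Z')^{-1} = I - Z diag(gamma / (1 + gamma n_i)) Z'
# so every evaluation is O(q p^2), never O(n^2).
.lmm_eval <- function(prep, y, sy, Xty, yty, gamma) {
  gi <- gamma / (1 + gamma * prep$ni)
  A <- prep$XtX - crossprod(prep$Sg * gi, prep$Sg)   # X' V*^{-1} X
  b <- Xty - crossprod(prep$Sg, gi * sy)             # X' V*^{-1} y
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, forwardsolve(t(R), b))
  yViy <- yty - sum(gi * sy^2)
  rss <- max(yViy - sum(b * beta), 1e-300)
  list(gi = gi, beta = drop(beta), rss = rss, R = R,
       logdetV = sum(log1p(gamma * prep$ni)),
       logdetA = 2 * sum(log(diag(R))))
}

.lmm_fit <- function(prep, y, reml = TRUE) {
  n <- prep$n; p <- prep$p
  sy <- rowsum(y, prep$g, reorder = TRUE)[, 1L]
  Xty <- crossprod(prep$X, y)
  yty <- sum(y * y)
  crit <- function(loggamma) {
    ev <- .lmm_eval(prep, y, sy, Xty, yty, exp(loggamma))
    if (is.null(ev)) return(Inf)
    if (reml) (n - p) * log(ev$rss) + ev$logdetV + ev$logdetA
    else n * log(ev$rss) + ev$logdetV
  }
  opt <- stats::optimize(crit, interval = c(-15, 12), tol = 1e-9)
  gamma <- exp(opt$minimum)
  # boundary candidate: no tree variance (ordinary least squares)
  if (crit(-Inf) <= opt$objective + 1e-10) gamma <- 0
  ev <- .lmm_eval(prep, y, sy, Xty, yty, gamma)
  if (is.null(ev)) stop("generalized least squares system is singular")
  df <- if (reml) n - p else n
  s2e <- ev$rss / df
  Ainv <- chol2inv(ev$R)
  fixed <- drop(prep$X %*% ev$beta)
  m2ll <- df * log(2 * pi * s2e) + ev$logdetV + df +
    if (reml) ev$logdetA else 0
  structure(list(
    beta = setNames(ev$beta, colnames(prep$X)),
    vcov_beta = s2e * Ainv,
    sigma2_tree = gamma * s2e,
    sigma2_err = s2e,
    sigma2_fix = sum((fixed - mean(fixed))^2) / n,
    gamma = gamma,
    loglik = -m2ll / 2,
    aic = if (!reml) m2ll + 2 * (p + 2) else NA_real_,
    n = n, p = p,
    method = if (reml) "REML" else "ML",
    prep = prep
  ), class = "plast_lmm")
}

#' Marginal R-squared of a fitted mixed model
#'
#' The fixed-effects share of variance,
#' `R2 = sigma2_fix / (sigma2_fix + sigma2_rand + sigma2_err)`, where
#' `sigma2_fix` is the variance of the fixed-effect linear predictor across
#' libraries, `sigma2_rand` the random-intercept variance and `sigma2_err`
#' the residual variance.
#'
#' @param fit a `plast_lmm` object.
#' @return A number in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "plast_lmm"))
  tot <- fit$sigma2_fix + fit$sigma2_tree + fit$sigma2_err
  if (tot <= 0) stop("all variance components are zero; R-squared undefined")
  fit$sigma2_fix / tot
}

# Generalized inverse via SVD (only used when the variance-parameter
# information matrix is numerically singular, e.g. exact boundary fits).
.ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# First-order Kenward-Roger adjustment for V = s2b ZZ' + s2e I.
# Computes the adjusted covariance of beta and the per-parameter matrices
# needed by the F-test; depends only on the full-model REML fit, so it is
# computed once per transcript and reused across tested terms.
.kr_adjust <- function(fit) {
  prep <- fit$prep
  X <- prep$X; n <- prep$n
  Z <- matrix(0, n, prep$q)
  Z[cbind(seq_len(n), prep$g)] <- 1
  ZZt <- tcrossprod(Z)
  V <- fit$sigma2_tree * ZZt + fit$sigma2_err * diag(n)
  Vi <- chol2inv(chol(V))
  TT <- Vi %*% X
  Phi <- chol2inv(chol(crossprod(X, TT)))    # (X' V^{-1} X)^{-1}
  G <- list(ZZt, diag(n))                    # dV/ds2b, dV/ds2e
  H <- O <- vector("list", 2L)
  for (i in 1:2) {
    H[[i]] <- G[[i]] %*% Vi
    O[[i]] <- H[[i]] %*% X
  }
  P <- Q <- vector("list", 4L)               # Q indexed [i, j] -> 2(i-1)+j
  for (i in 1:2) {
    P[[i]] <- -crossprod(O[[i]], TT)         # -X' V^{-1} G_i V^{-1} X
    for (j in 1:2)
      Q[[2L * (i - 1L) + j]] <- crossprod(O[[i]], Vi %*% O[[j]])
  }
  IE2 <- matrix(0, 2, 2)
  for (i in 1:2) for (j in i:2) {
    IE2[i, j] <- IE2[j, i] <-
      sum(t(H[[i]]) * H[[j]]) -
      2 * sum(Phi * Q[[2L * (i - 1L) + j]]) +
      sum((Phi %*% P[[i]]) * t(P[[j]] %*% Phi))
  }
  W <- tryCatch(2 * solve(IE2), error = function(e) 2 * .ginv(IE2))
  # sum over all ordered (i, j): t(Q_ij - P_i Phi P_j) equals the (j, i)
  # term, so this yields the symmetrized sum without an explicit transpose
  U <- matrix(0, prep$p, prep$p)
  for (i in 1:2) for (j in 1:2)
    U <- U + W[i, j] * (Q[[2L * (i - 1L) + j]] - P[[i]] %*% Phi %*% P[[j]])
  PhiA <- Phi + 2 * Phi %*% U %*% Phi
  list(Phi = Phi, PhiA = PhiA, W = W, P = P, beta = fit$beta)
}

# Scaled F statistic and denominator df for the restriction L beta = 0,
# following Kenward & Roger (1997).
.kr_test <- function(adj, L) {
  q <- nrow(L)
  Phi <- adj$Phi
  Theta <- crossprod(L, solve(L %*% Phi %*% t(L), L))
  ThetaPhi <- Theta %*% Phi
  A1 <- A2 <- 0
  u <- lapply(1:2, function(i) ThetaPhi %*% adj$P[[i]] %*% Phi)
  for (i in 1:2) for (j in i:2) {
    e <- if (i == j) 1 else 2
    A1 <- A1 + e * adj$W[i, j] * sum(diag(u[[i]])) * sum(diag(u[[j]]))
    A2 <- A2 + e * adj$W[i, j] * sum(u[[i]] * t(u[[j]]))
  }
  B <- (A1 + 6 * A2) / (2 * q)
  g <- ((q + 1) * A1 - (q + 4) * A2) / ((q + 2) * A2)
  c1 <- g / (3 * q + 2 * (1 - g))
  c2 <- (q - g) / (3 * q + 2 * (1 - g))
  c3 <- (q + 2 - g) / (3 * q + 2 * (1 - g))
  V0 <- 1 + c1 * B; V1 <- 1 - c2 * B; V2 <- 1 - c3 * B
  if (abs(V0) < 1e-10) V0 <- 0
  EstarInv <- 1 - A2 / q
  rho <- (if (abs(V1) < 1e-12 && abs(EstarInv) < 1e-12) 1
          else (EstarInv / V1)^2) * V0 / V2 / q
  ddf <- 4 + (q + 2) / (q * rho - 1)
  scaling <- if (abs(ddf - 2) < 0.01) 1 else ddf * EstarInv / (ddf - 2)
  Lb <- drop(L %*% adj$beta)
  wald <- drop(crossprod(Lb, solve(L %*% adj$PhiA %*% t(L), Lb)))
  Fstat <- scaling * wald / q
  if (!is.finite(ddf) || ddf <= 0)
    stop("Kenward-Roger denominator df is not positive (ddf = ", ddf,
         "); variance-parameter information may be degenerate")
  list(F = Fstat, ndf = q, ddf = ddf,
       p = stats::pf(Fstat, q, ddf, lower.tail = FALSE))
}

#' Kenward-Roger F-test between nested mixed models
#'
#' Tests the fixed-effect coefficients present in `full` but absent from
#' `reduced`, using the first-order Kenward-Roger small-sample adjustment
#' computed from the full model's REML fit: the covariance of the fixed
#' effects is inflated for the uncertainty of the variance parameters, and a
#' scaled Wald F statistic with an approximate denominator df is returned.
#'
#' @param full,reduced `plast_lmm` REML fits on the same response and
#'   grouping factor; `reduced`'s design columns must be a strict subset of
#'   `full`'s.
#' @return A list with `F`, `ndf`, `ddf` and `p`.
#' @export
kr_ftest <- function(full, reduced) {
  stopifnot(inherits(full, "plast_lmm"), inherits(reduced, "plast_lmm"))
  if (full$method != "REML" || reduced$method != "REML")
    stop("Kenward-Roger testing requires REML fits")
  cn_full <- colnames(full$prep$X)
  cn_red <- colnames(reduced$prep$X)
  if (!all(cn_red %in% cn_full) || length(cn_red) >= length(cn_full))
    stop("models are not strictly nested (reduced columns must be a strict ",
         "subset of full columns)")
  if (full$n != reduced$n || !identical(full$prep$g, reduced$prep$g))
    stop("full and reduced models must share the response and random structure")
  dropped <- setdiff(cn_full, cn_red)
  L <- matrix(0, length(dropped), full$p,
              dimnames = list(dropped, cn_full))
  L[cbind(seq_along(dropped), match(dropped, cn_full))] <- 1
  .kr_test(.kr_adjust(full), L)
}
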