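test_that("penalties at or above lambda_max zero every coefficient", {
  set.seed(2)
  X <- matrix(rnorm(12 * 30), 12, 30)
  y <- rnorm(12)
  lmax <- lambda_max(X, y)
  for (lam in c(lmax, 1.5 * lmax)) {
    f <- fit_lasso(X, y, lambda = lam)
    expect_length(f$selected, 0)
    expect_equal(unname(f$intercept), mean(y))
  }
  f2 <- fit_lasso(X, y, lambda = 0.9 * lmax)
  expect_gt(length(f2$selected), 0)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  for (seed in 1:5) {
    n <- 20; p <- 6
    X <- orthonormal_design(n, p, seed)
    set.seed(seed + 100)
    y <- rnorm(n, sd = 2)
    b_ols <- as.vector(crossprod(X, y - mean(y))) / n
    for (lam in c(0.05, 0.3, 1)) {
      f <- fit_lasso(X, y, lambda = lam)
      expect_equal(unname(f$beta), soft_threshold(b_ols, lam),
                   tolerance = 1e-8)
    }
  }
})

test_that("converged fits satisfy the KKT conditions", {
  set.seed(31)
  for (i in 1:20) {
    n <- 10; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    lam <- 0.3 * lambda_max(X, y)
    f <- fit_lasso(X, y, lambda = lam)
    expect_lt(f$kkt_residual, 1e-6)
  }
})

test_that("no random perturbation improves the lasso objective", {
  set.seed(7)
  n <- 10; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  lam <- 0.2 * lambda_max(X, y)
  f <- fit_lasso(X, y, lambda = lam)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  yc <- y - mean(y)
  b_hat <- unname(f$beta_std)
  obj_hat <- lasso_objective(Xs, yc, b_hat, lam)
  set.seed(8)
  worse <- replicate(500, {
    b_try <- b_hat + rnorm(p, 0, 0.05)
    lasso_objective(Xs, yc, b_try, lam) >= obj_hat - 1e-12
  })
  expect_true(all(worse))
})

test_that("sparsity is monotone along the penalty path", {
  set.seed(12)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- X[, 1] * 2 - X[, 2] + rnorm(30)
  path <- exp(seq(log(lambda_max(X, y)), log(0.01), length.out = 30))
  nnz <- sapply(path, function(l) length(fit_lasso(X, y, lambda = l)$selected))
  expect_true(all(diff(nnz) >= 0)) # path is decreasing in lambda
})

test_that("the solver agrees with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  n <- 40; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1:3] %*% c(1, -2, 0.5) + rnorm(n)
  for (lam in c(0.05, 0.2, 0.6)) {
    mine <- fit_lasso(X, y, lambda = lam)
    g <- glmnet::glmnet(X, y, lambda = lam, standardize = TRUE,
                        thresh = 1e-12)
    expect_equal(unname(mine$beta), as.vector(g$beta), tolerance = 1e-4)
    expect_equal(unname(mine$intercept), as.vector(g$a0), tolerance = 1e-4)
  }
})

test_that("cross-validated penalty choice is deterministic and null-safe", {
  set.seed(14)
  X <- matrix(rnorm(12 * 50), 12, 50)
  y <- rnorm(12)
  cv1 <- select_lambda(X, y, seed = 5)
  cv2 <- select_lambda(X, y, seed = 5)
  expect_identical(cv1$lambda, cv2$lambda)
  expect_identical(cv1$folds, cv2$folds)
  expect_error(select_lambda(X, y, k_folds = 2, seed = 1), "k_folds")
  # pure-noise responses keep the model near-null at the chosen penalty:
  # the minimum-CV rule admits the occasional small spurious model, the
  # one-standard-error rule is reliably conservative
  nsel <- sapply(1:50, function(i) {
    set.seed(2000 + i)
    Xn <- matrix(rnorm(12 * 50), 12, 50)
    yn <- rnorm(12)
    vapply(c("min", "1se"), function(rule) {
      cv <- select_lambda(Xn, yn, seed = 3000 + i, rule = rule)
      length(fit_lasso(Xn, yn, lambda = cv$lambda)$selected)
    }, numeric(1))
  })
  expect_lte(median(nsel["min", ]), 2)
  expect_gte(mean(nsel["1se", ] <= 2), 0.8)
})

test_that("per-variable correlations match the sum-formula oracle", {
  set.seed(10)
  X <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 2 * X[, 1]
  r <- per_variable_correlation(X, y, c("v1", "v2"))
  expect_equal(unname(r["v1"]), 1)
  expect_equal(unname(r["v2"]), pearson_oracle(X[, 2], y), tolerance = 1e-12)
  expect_equal(unname(per_variable_correlation(X, -X[, 3], "v3")["v3"]), -1)
  Xz <- cbind(X, vz = 0)
  expect_warning(rz <- per_variable_correlation(Xz, y, c("v1", "vz")),
                 "zero-variance")
  expect_named(rz, "v1")
})

test_that("consensus keeps only co-selected, sign-consistent predictors", {
  f1 <- fake_fit(c("env:tdn", "rdna:OTU_001", "rrna:OTU_002"))
  f2 <- fake_fit(c("env:tdn", "rdna:OTU_001", "env:si"))
  r1 <- c("env:tdn" = 0.6, "rdna:OTU_001" = 0.6, "rrna:OTU_002" = 0.5)
  r2 <- c("env:tdn" = 0.5, "rdna:OTU_001" = -0.5, "env:si" = 0.9)
  cons <- cross_site_consensus(f1, f2, r1, r2)
  # selected in one site only: dropped; opposite signs: dropped
  expect_identical(cons$predictor, "env:tdn")
  expect_identical(cons$class, "env")
  # mismatched functions refuse to combine
  expect_error(cross_site_consensus(f1, fake_fit("env:tdn", fn = "lipase"),
                                    r1, r2), "different functions")
  # empty consensus reports no model
  expect_message(
    none <- cross_site_consensus(fake_fit("env:si"), fake_fit("env:tdn"),
                                 c("env:si" = 0.2), c("env:tdn" = 0.3)),
    "no model")
  expect_identical(nrow(none), 0L)
})

test_that("pooled metrics classify strength at the 0.4 cutoff", {
  set.seed(16)
  x1 <- rnorm(8); x2 <- rnorm(8)
  # perfect pooled linear relation
  m <- consensus_metrics(x1, 3 * x1 + 2, x2, 5 * x2 - 1)
  expect_equal(m$common_r2, 1)
  expect_equal(m$rmspe, 0, tolerance = 1e-12)
  expect_identical(m$strength, "strong")
  # oracle: squared correlation of the pooled standardized pairs
  y1 <- x1 + rnorm(8); y2 <- x2 + rnorm(8, sd = 2)
  m2 <- consensus_metrics(x1, y1, x2, y2)
  zx <- c(scale(x1), scale(x2)); zy <- c(scale(y1), scale(y2))
  expect_equal(m2$common_r2, cor(zx, zy)^2, tolerance = 1e-12)
  expect_identical(m2$strength, if (m2$common_r2 > 0.4) "strong" else "weak")
  # constructions with exact pooled r: 0.6 -> R2 = 0.36 (weak),
  # 0.7 -> R2 = 0.49 (strong)
  zs <- as.vector(scale(x1))
  es <- as.vector(scale(residuals(lm(rnorm(8) ~ x1))))
  for (rr in c(0.6, 0.7)) {
    yy <- rr * zs + sqrt(1 - rr^2) * es
    mm <- consensus_metrics(x1, yy, x1, yy)
    expect_equal(mm$common_r2, rr^2, tolerance = 1e-12)
    expect_identical(mm$strength, if (rr == 0.7) "strong" else "weak")
  }
  expect_error(consensus_metrics(1:2, 1:2, numeric(0), numeric(0)),
               "at least 4")
})
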