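test_that("design matrix prepends an intercept and validates input", {
  y <- matrix(1:6 / 2, 3, 2, dimnames = list(NULL, c("a", "b")))
  d <- build_design(y)
  expect_equal(dim(d), c(3L, 3L))
  expect_equal(unname(d[, 1]), rep(1, 3))
  expect_equal(unname(d[, -1]), unname(y))
  expect_equal(colnames(d), c("(Intercept)", "a", "b"))

  expect_error(build_design(matrix(numeric(0), 3, 0)), "at least one phenotype")
  expect_error(build_design(matrix(c(1, NA), 2, 1)), "missing")

  # duplicate phenotype columns are the ridge's problem, not the design's
  expect_silent(build_design(cbind(y, y)))
})

test_that("the default penalty grid follows the published log-spacing", {
  g <- lambda_grid()
  expect_length(g, 8L)
  expect_equal(as.numeric(log(unclass(g))), c(0, 1, 2, 3, 3.5, 3.8, 4, 4.5))
  expect_error(lambda_grid(c(1, 1, 2)), "strictly increasing")
})

test_that("ridge fit solves the penalized normal equations", {
  inst <- random_instance(10, 3, seed = 42)

  # lambda = 0 with exact linear data interpolates the generating coefficients
  beta_star <- c(0.5, -1, 2, 0.25)
  x_exact <- drop(inst$design %*% beta_star)
  expect_equal(unname(ridge_fit(inst$design, x_exact, 0)$beta), beta_star,
               tolerance = 1e-10)

  # enormous penalty shrinks every (penalized) coefficient to zero
  expect_lt(max(abs(ridge_fit(inst$design, inst$x, 1e12)$beta)), 1e-9)

  # independent normal-equations oracle at lambda = 2
  a <- t(inst$design) %*% inst$design + 2 * diag(4)
  expected <- unname(drop(qr.solve(a, t(inst$design) %*% inst$x)))
  expect_equal(unname(ridge_fit(inst$design, inst$x, 2)$beta), expected,
               tolerance = 1e-12)

  # rank-deficient design at lambda = 0 is singular, at lambda > 0 fine
  ydup <- cbind(inst$y[, 1], inst$y[, 1])
  expect_error(ridge_fit(build_design(ydup), inst$x, 0), "singular")
  expect_silent(ridge_fit(build_design(ydup), inst$x, 1))
})

test_that("unpenalized-intercept option leaves the intercept free at huge lambda", {
  inst <- random_instance(30, 2, seed = 7)
  fit <- ridge_fit(inst$design, inst$x, 1e12, penalize_intercept = FALSE)
  expect_equal(unname(fit$beta[1]), mean(inst$x), tolerance = 1e-6)
  expect_lt(max(abs(fit$beta[-1])), 1e-9)
})

test_that("naive LOOCV error matches hand-solved leave-one-out fits", {
  # n = 5, K = 1, lambda = 1: verify against five explicit 2x2 solves
  y <- matrix(c(-1, 0, 1, 2, 3), 5, 1)
  x <- c(0, 1, 1, 2, 2)
  d <- build_design(y)
  expected <- 0
  for (i in 1:5) {
    yi <- d[-i, , drop = FALSE]
    a <- t(yi) %*% yi + diag(2)
    beta <- solve(a, t(yi) %*% x[-i])
    expected <- expected + (x[i] - sum(d[i, ] * beta))^2
  }
  got <- loocv_errors_naive(d, x, grid = 1)
  expect_equal(unname(got), expected, tolerance = 1e-12)
})

test_that("constant response still yields positive LOOCV error under penalty", {
  # the penalized intercept cannot reproduce a constant exactly
  y <- matrix(c(0.3, -0.2, 0.5), 3, 1)
  x <- rep(1, 3)
  got <- loocv_errors_naive(build_design(y), x, grid = 5)
  expect_gt(unname(got), 0)
})

test_that("duplicated observations keep the LOOCV error finite and stable", {
  inst <- random_instance(8, 2, seed = 3)
  y2 <- rbind(inst$y, inst$y[1, ])
  x2 <- c(inst$x, inst$x[1])
  got <- loocv_errors_naive(build_design(y2), x2, grid = c(1, 10))
  expect_true(all(is.finite(got)))
})

test_that("SVD cache components satisfy their defining identities", {
  inst <- random_instance(20, 4, seed = 99)
  grid <- lambda_grid()
  cache <- svd_cache(inst$design, grid)
  lam <- as.numeric(unclass(grid))

  expect_equal(crossprod(cache$U), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(cache$C >= 0 & cache$C <= 1))
  # shrinkage strictly decreasing in lambda for every positive singular value
  expect_true(all(apply(cache$C, 1L, diff) < 0))

  # leverage column m equals the diagonal of Y (Y'Y + lambda_m I)^-1 Y'
  for (m in c(1L, 4L, 8L)) {
    hm <- diag(inst$design %*%
                 solve(crossprod(inst$design) + lam[m] * diag(5)) %*%
                 t(inst$design))
    expect_equal(unname(cache$H[, m]), unname(hm), tolerance = 1e-10)
  }
  # trace identity: sum of leverages equals sum of shrinkage factors
  expect_equal(unname(colSums(cache$H)), unname(colSums(cache$C)),
               tolerance = 1e-10)
  expect_true(all(cache$H >= 0 & cache$H < 1))
})

test_that("orthonormal design columns give the closed-form shrinkage factors", {
  set.seed(5)
  q <- qr.Q(qr(matrix(rnorm(60), 20, 3)))   # d_j = 1 for every j
  cache <- svd_cache(q, grid = c(0, 1))
  expect_equal(unname(cache$C[, 1]), rep(1, 3), tolerance = 1e-12)   # lambda = 0
  expect_equal(unname(cache$C[, 2]), rep(0.5, 3), tolerance = 1e-12) # 1/(1+1)
})

test_that("cache construction requires n >= K+1", {
  y <- matrix(rnorm(12), 3, 4)
  expect_error(svd_cache(build_design(y)), "n >= K\\+1")
})

test_that("fast LOOCV agrees with naive refitting and the per-observation identity", {
  for (seed in 1:5) {
    n <- sample(12:40, 1)
    K <- sample(1:6, 1)
    inst <- random_instance(n, K, seed = seed)
    grid <- lambda_grid(log_lambda = c(0, 2, 4))
    cache <- svd_cache(inst$design, grid)
    fast <- loocv_errors_fast(cache, inst$x)
    naive <- loocv_errors_naive(inst$design, inst$x, grid)
    expect_equal(unname(fast), unname(naive), tolerance = 1e-10)

    # (x_i - xhat_i)/(1 - h_i) equals each refit leave-one-out residual
    lam <- exp(2)
    xhat <- drop(inst$design %*% ridge_fit(inst$design, inst$x, lam)$beta)
    closed <- (inst$x - xhat) / (1 - cache$H[, 2])
    refit <- vapply(seq_len(n), function(i) {
      b <- ridge_fit(inst$design[-i, , drop = FALSE], inst$x[-i], lam)$beta
      inst$x[i] - sum(inst$design[i, ] * b)
    }, numeric(1))
    expect_equal(unname(closed), refit, tolerance = 1e-8)
  }
})

test_that("lambda = 0 reproduces the OLS PRESS statistic", {
  inst <- random_instance(30, 4, seed = 21)
  cache <- svd_cache(inst$design, grid = 0)
  fast <- loocv_errors_fast(cache, inst$x)
  # independent route: lm() residuals and hat values
  fit <- lm(inst$x ~ inst$y)
  press <- sum((residuals(fit) / (1 - lm.influence(fit)$hat))^2)
  expect_equal(unname(fast), press, tolerance = 1e-10)
})

test_that("unit leverage is an error naming the offending row", {
  # n = K+1 with lambda = 0: every leverage is exactly 1
  inst <- random_instance(4, 3, seed = 8)
  cache <- svd_cache(inst$design, grid = 0)
  expect_error(loocv_errors_fast(cache, inst$x), "leverage")
})

test_that("matrix input returns one row of errors per genotype column", {
  inst <- random_instance(25, 3, seed = 13)
  cache <- svd_cache(inst$design)
  X <- cbind(inst$x, rev(inst$x))
  T2 <- loocv_errors_fast(cache, X)
  expect_equal(dim(T2), c(2L, 8L))
  expect_equal(T2[1, ], loocv_errors_fast(cache, inst$x))
})
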