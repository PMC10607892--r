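test_that("conventional separation inverts the system matrix per frame", {
  v <- density_series(cbind(c(2, 0), c(3, 0)), 30)
  f_id <- build_forward_matrix(c(1, 0), c(0, 1))
  expect_equal(unclass(conventional_separate(f_id, v)), unclass(v),
               ignore_attr = TRUE)

  f <- build_forward_matrix(c(2, 0), c(0, 1))
  r <- conventional_separate(f, density_series(cbind(2, 3), 30))
  expect_equal(as.numeric(r), c(1, 3))
  expect_identical(attr(r, "method_tag"), "conventional")
})

test_that("pigment autocorrelation matches its closed forms", {
  # degenerate range: deterministic ensemble, exact second moments
  rrr <- build_pigment_autocorrelation(c(0.3, 0.3), 0.4)
  expect_equal(matrix(as.numeric(rrr), 2, 2),
               matrix(c(0.09, 0.12, 0.12, 0.16), 2, 2), tolerance = 1e-12)

  # uniform on [0, 1] with zero shade: E[h^2] = 1/3
  rrr <- build_pigment_autocorrelation(c(0, 1), 0, n_samples = 1e6, seed = 5)
  expect_equal(rrr[1, 1], 1 / 3, tolerance = 0.01)
  expect_equal(rrr[2, 2], 0)

  # symmetry and PSD for arbitrary inputs
  set.seed(8)
  for (i in 1:10) {
    rr <- build_pigment_autocorrelation(sort(runif(2, -1, 1)), runif(1, -1, 1),
                                        n_samples = 1000, seed = i)
    m <- matrix(as.numeric(rr), 2, 2)
    expect_equal(m, t(m))
    expect_gte(min(eigen(m, symmetric = TRUE)$values), -1e-10)
  }

  expect_error(build_pigment_autocorrelation(c(0, 1), 0, n_samples = 0),
               "n_samples")
  expect_error(build_pigment_autocorrelation(c(1, 0), 0), "min <= max")
})

test_that("Wiener matrix reduces to the plain inverse without noise", {
  set.seed(21)
  zero <- autocorrelation_matrix(matrix(0, 2, 2), role = "noise")
  for (i in 1:25) {
    f <- rand_forward()
    rrr <- autocorrelation_matrix(rand_psd2(), role = "pigment")
    est <- wiener_matrix(rrr, f, zero)
    f_inv <- solve(matrix(as.numeric(f), 2, 2))
    expect_equal(est$G, f_inv, tolerance = 1e-10)
  }
})

test_that("Wiener matrix matches the scalar analogue", {
  f <- build_forward_matrix(c(1, 0), c(0, 1))
  est <- wiener_matrix(diag(2), f, diag(2))
  expect_equal(est$G, diag(0.5, 2), tolerance = 1e-12)
})

test_that("Wiener matrix minimizes the ensemble MSE (numeric-optimizer oracle)", {
  set.seed(31)
  for (i in 1:5) {
    f <- rand_forward()
    rrr <- rand_psd2()
    rnn <- rand_psd2(0.5)
    est <- wiener_matrix(autocorrelation_matrix(rrr, "pigment"), f,
                         autocorrelation_matrix(rnn, "noise"))
    # independent oracle: direct numerical minimization over 2x2 matrices
    obj <- function(par) ensemble_mse(matrix(par, 2, 2), f, rrr, rnn)
    opt <- optim(rep(0, 4), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    expect_equal(as.numeric(est$G), opt$par, tolerance = 1e-5)
    expect_lte(ensemble_mse(est$G, f, rrr, rnn), opt$value + 1e-10)
  }
})

test_that("Wiener agrees with the data-driven form Rrv Rvv^-1 on a simulated ensemble", {
  # well-conditioned ensemble so the sample Rvv inverse converges quickly
  set.seed(17)
  f <- build_forward_matrix(c(1, 0.4), c(1, 1))
  fm <- matrix(as.numeric(f), 2, 2)
  n <- 2e5
  h <- runif(n, 0, 1)
  r <- cbind(h, 0.5)
  sigma <- 0.3
  v <- r %*% t(fm) + matrix(rnorm(2 * n, 0, sigma), ncol = 2)
  g_data <- unname((crossprod(r, v) / n) %*% solve(crossprod(v) / n))

  rrr <- build_pigment_autocorrelation(c(0, 1), 0.5, n_samples = 1e6,
                                       seed = 99)
  rnn <- build_noise_autocorrelation(sigma)
  est <- wiener_matrix(rrr, f, rnn)
  expect_equal(est$G, g_data, tolerance = 0.02)
})

test_that("Wiener MSE never exceeds the conventional inverse's, strictly under noise", {
  set.seed(41)
  for (i in 1:10) {
    f <- rand_forward()
    f_inv <- solve(matrix(as.numeric(f), 2, 2))
    rrr <- rand_psd2()
    rnn <- rand_psd2(0.3)
    est <- wiener_matrix(autocorrelation_matrix(rrr, "pigment"), f,
                         autocorrelation_matrix(rnn, "noise"))
    mse_w <- ensemble_mse(est$G, f, rrr, rnn)
    mse_c <- ensemble_mse(f_inv, f, rrr, rnn)
    expect_lt(mse_w, mse_c)  # strict: Rnn is full rank here
  }
})

test_that("perturbing G in any entry does not decrease the ensemble MSE", {
  set.seed(51)
  f <- rand_forward()
  rrr <- rand_psd2()
  rnn <- rand_psd2(0.5)
  est <- wiener_matrix(autocorrelation_matrix(rrr, "pigment"), f,
                       autocorrelation_matrix(rnn, "noise"))
  base <- ensemble_mse(est$G, f, rrr, rnn)
  eps <- 1e-4
  for (k in 1:4) {
    for (s in c(-1, 1)) {
      g2 <- est$G
      g2[k] <- g2[k] + s * eps
      expect_gte(ensemble_mse(g2, f, rrr, rnn), base)
    }
  }
})

test_that("G converges monotonically to the inverse as the noise vanishes", {
  set.seed(61)
  f <- rand_forward()
  f_inv <- solve(matrix(as.numeric(f), 2, 2))
  rrr <- autocorrelation_matrix(rand_psd2(), "pigment")
  dist <- vapply(10^seq(-1, -6), function(sigma) {
    est <- wiener_matrix(rrr, f, build_noise_autocorrelation(sigma))
    max(abs(est$G - f_inv))
  }, numeric(1))
  expect_true(all(diff(dist) < 0))
  expect_lt(dist[length(dist)], 1e-8)
})

test_that("wiener separation applies G per frame and tags the method", {
  f <- build_forward_matrix(c(1, 0), c(0, 1))
  est <- wiener_matrix(autocorrelation_matrix(diag(2), "pigment"), f,
                       build_noise_autocorrelation(0))
  v <- density_series(matrix(rnorm(20), ncol = 2), 30)
  r <- wiener_separate(est, v)
  expect_equal(unclass(r), unclass(v), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(r, "method_tag"), "wiener")
})

test_that("estimator sidecar round-trips the matrices", {
  f <- build_forward_matrix()
  rrr <- build_pigment_autocorrelation(c(0.29, 0.31), 0.4, n_samples = 1000,
                                       seed = 3)
  est <- wiener_matrix(rrr, f, build_noise_autocorrelation(0.0025))
  path <- withr::local_tempfile(fileext = ".json")
  write_estimator_sidecar(est, path)
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(side$G, est$G, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(side$Rrr$n_samples, 1000)
  expect_identical(side$Rnn$provenance, "analytic")
})
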