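random_model <- function(n_atoms, M, seed = 1, temperature = 300) {
  set.seed(seed)
  n3 <- 3L * n_atoms
  V <- qr.Q(qr(matrix(rnorm(n3 * M), n3, M)))
  lambda <- sort(runif(M, 0.1, 5), decreasing = TRUE)
  response_model(rnorm(n3), V, lambda, temperature)
}

test_that("the model constructor enforces its invariants", {
  expect_error(response_model(numeric(9), matrix(1, 9, 1), -1), "negative")
  expect_error(response_model(numeric(9), matrix(0.5, 9, 1), 1), "orthonormal")
  V <- diag(9)[, 1:2]
  expect_error(response_model(numeric(9), V, c(1, 2)), "descending")
  expect_error(response_model(numeric(8), V[1:8, ], c(2, 1)), "3N")
})

test_that("one-mode displacement reproduces the closed form", {
  v <- numeric(9); v[1] <- 1  # unit mode along atom-1 x
  model <- response_model(numeric(9), matrix(v), lambda = 2.0,
                          temperature = 1 / (KB_KJ_MOL_K * 0.4))  # beta = 0.4
  f <- numeric(9); f[1] <- 5
  dr <- displacement(model, f)
  expect_equal(dr[1], 0.4 * 2.0 * 5)  # = 4.0 A
  expect_equal(dr[-1], numeric(8))
  expect_equal(displacement(model, numeric(9)), numeric(9))
})

test_that("sparse-product displacement equals the dense response-matrix oracle", {
  for (seed in 1:5) {
    model <- random_model(20, 7, seed = seed)
    dense <- model$beta * model$V %*% diag(model$lambda) %*% t(model$V)
    set.seed(seed + 50)
    f <- rnorm(60)
    expect_lt(max(abs(displacement(model, f) - as.numeric(dense %*% f))), 1e-10)
  }
})

test_that("displacement is linear and confined to the mode subspace", {
  model <- random_model(15, 5, seed = 3)
  set.seed(99)
  f <- rnorm(45); g <- rnorm(45); a <- 1.7; b <- -0.3
  lhs <- displacement(model, a * f + b * g)
  rhs <- a * displacement(model, f) + b * displacement(model, g)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  dr <- displacement(model, f)
  ortho <- dr - model$V %*% crossprod(model$V, dr)
  expect_lt(max(abs(ortho)), 1e-10)
})

test_that("relaxation under zero and constant forces hits the known fixed points", {
  model <- random_model(10, 4, seed = 7)
  res0 <- relax_to_equilibrium(model, function(x) numeric(30))
  expect_equal(res0$coordinates, model$r_o)
  expect_equal(res0$iterations, 1L)
  expect_true(res0$converged)

  set.seed(8); fstar <- rnorm(30)
  res <- relax_to_equilibrium(model, function(x) fstar)
  expect_true(res$converged)
  expect_lt(max(abs(res$deformation - displacement(model, fstar))), 1e-3)
  # alpha = 1 lands on a constant-map fixed point in two iterations
  res1 <- relax_to_equilibrium(model, function(x) fstar,
                               relaxation_settings(alpha = 1))
  expect_equal(res1$iterations, 2L)
  expect_lt(max(abs(res1$deformation - displacement(model, fstar))), 1e-12)
})

test_that("relaxation with a linear force field matches the direct linear solve", {
  model <- random_model(8, 3, seed = 11)
  n3 <- 24
  set.seed(12)
  f0 <- rnorm(n3)
  K <- 0.05 * crossprod(matrix(rnorm(n3 * n3), n3)) / n3  # small SPD coupling
  force_fun <- function(r) f0 - K %*% (r - model$r_o)
  res <- relax_to_equilibrium(model, force_fun,
                              relaxation_settings(tolerance = 1e-9,
                                                  max_iterations = 2000))
  expect_true(res$converged)
  R <- model$beta * model$V %*% diag(model$lambda) %*% t(model$V)
  dr_exact <- solve(diag(n3) + R %*% K, R %*% f0)
  expect_lt(max(abs(res$deformation - as.numeric(dr_exact))), 1e-6)
})

test_that("the max-change trace is non-increasing after the first step for constant forces", {
  model <- random_model(12, 4, seed = 13)
  set.seed(14); fstar <- rnorm(36)
  res <- relax_to_equilibrium(model, function(x) fstar,
                              relaxation_settings(alpha = 0.3, tolerance = 1e-8))
  if (length(res$trace) > 2)
    expect_true(all(diff(res$trace[-1]) <= 1e-12))
})

test_that("non-convergence is flagged, not thrown", {
  model <- random_model(6, 2, seed = 15)
  set.seed(16); fstar <- rnorm(18) * 10
  res <- relax_to_equilibrium(model, function(x) fstar,
                              relaxation_settings(alpha = 0.5,
                                                  tolerance = 1e-12,
                                                  max_iterations = 3))
  expect_false(res$converged)
  expect_length(res$trace, 3L)
  expect_error(relax_to_equilibrium(model, function(x) rep(NaN, 18)),
               "non-finite")
})

test_that("closest_to_average matches the explicit RMSD argmin", {
  expect_equal(closest_to_average(matrix(rnorm(30), 1)), 1L)
  # frame 2 constructed as the mean of frames 1 and 3
  f1 <- rnorm(30); f3 <- rnorm(30)
  ens <- rbind(f1, (f1 + f3) / 2, f3)
  expect_equal(closest_to_average(ens, superpose = FALSE), 2L)
  set.seed(18)
  ens <- matrix(rnorm(100 * 30), 100, 30)
  mu <- colMeans(ens)
  want <- which.min(sqrt(rowMeans(sweep(ens, 2, mu)^2)))
  expect_equal(closest_to_average(ens, superpose = FALSE), want)
})

test_that("identical frames give a zero-variance model with captured fraction 0", {
  ens <- matrix(rep(rnorm(30), each = 4), 4, 30)
  expect_warning(model <- build_response_model(ens, M = 2, superpose = FALSE),
                 "zero-variance")
  expect_equal(model$lambda, c(0, 0))
  expect_equal(model$captured_fraction, 0)
})

test_that("planted covariance modes are recovered from a Gaussian ensemble", {
  set.seed(20)
  dirs <- qr.Q(qr(matrix(rnorm(45 * 3), 45, 3)))
  planted <- c(4, 1, 0.25)
  ens <- make_harmonic_ensemble(
    15, modes = list(list(direction = dirs[, 1], lambda = 4),
                     list(direction = dirs[, 2], lambda = 1),
                     list(direction = dirs[, 3], lambda = 0.25)),
    noise_sd = 0.05, n_frames = 5000, seed = 21)
  model <- build_response_model(ens$ensemble, M = 3, superpose = FALSE)
  expect_true(all(abs(model$lambda - planted) / planted < 0.10))
  cosines <- abs(colSums(model$V * ens$modes))
  expect_true(all(cosines > 0.95))
  # retained share exceeds the planted signal share at M = M*
  signal_share <- sum(planted) / (sum(planted) + 0.05^2 * 45)
  expect_gt(model$captured_fraction, signal_share)
})

test_that("full-rank decomposition reconstructs the sample covariance", {
  set.seed(22)
  ens <- matrix(rnorm(200 * 12), 200, 12)  # F > 3N: dense eigen path
  model <- build_response_model(ens, M = 12, superpose = FALSE)
  X <- sweep(ens, 2, colMeans(ens))
  C <- crossprod(X) / nrow(ens)
  recon <- model$V %*% diag(model$lambda) %*% t(model$V)
  expect_lt(max(abs(recon - C)), 1e-8)
  expect_equal(model$captured_fraction, 1, tolerance = 1e-10)
})

test_that("Gram-trick and dense eigen paths agree on the same data", {
  set.seed(23)
  base <- rnorm(60)
  ens_small <- matrix(rep(base, each = 30), 30, 60) +
    matrix(rnorm(30 * 60, sd = 0.3), 30, 60)  # F < 3N: Gram path
  mg <- build_response_model(ens_small, M = 5, superpose = FALSE)
  X <- sweep(ens_small, 2, colMeans(ens_small))
  eg <- eigen(crossprod(X) / nrow(ens_small), symmetric = TRUE)
  expect_lt(max(abs(mg$lambda - eg$values[1:5])), 1e-8)
  # compare subspace projectors, not raw vectors (sign/degeneracy freedom)
  P1 <- tcrossprod(mg$V)
  P2 <- tcrossprod(eg$vectors[, 1:5])
  expect_lt(max(abs(P1 - P2)), 1e-6)
})

test_that("superposition removes a planted rigid-body rotation from the spectrum", {
  set.seed(24)
  base <- matrix(runif(30, 0, 10), 10, 3)
  frames <- t(vapply(1:60, function(k) {
    tr <- axis_angle_transform(c(0, 0, 1), runif(1, -0.4, 0.4))
    flatten_xyz(apply_transform(tr, base)) + rnorm(30, sd = 0.02)
  }, numeric(30)))
  m_sup <- build_response_model(frames, M = 3, superpose = TRUE)
  m_raw <- build_response_model(frames, M = 3, superpose = FALSE)
  expect_lt(m_sup$lambda[1], 0.1 * m_raw$lambda[1])
})
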