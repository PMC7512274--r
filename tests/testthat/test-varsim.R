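test_that("simulation matches the model: white noise, determinism", {
  m <- var_model(list(matrix(0, 3, 3)), diag(3))
  tt <- 20000
  x <- simulate_var(m, tt, seed = 1)
  r1 <- sample_covariances(x, 1)$lags[[2]]
  expect_lt(max(abs(r1)), 5 / sqrt(tt))
  y <- simulate_var(m, tt, seed = 1)
  expect_identical(x, y)
  z <- simulate_var(m, tt, seed = 2)
  expect_false(identical(x, z))
})

test_that("unstable models are rejected with a diagnostic", {
  expect_error(var_model(list(matrix(1.2)), matrix(1)), "not stable")
  m <- var_model(list(matrix(1.2)), matrix(1), validate = FALSE)
  expect_error(simulate_var(m, 10, seed = 1), "unstable")
  expect_error(theoretical_covariances(m, 1), "stable")
})

test_that("sample covariances use divisor T and match hand evaluation", {
  x <- rbind(c(1, 0), c(0, 1))
  cv <- sample_covariances(x, 1)
  expect_equal(cv$lags[[1]], diag(2) / 2)
  expect_equal(cv$lags[[2]], rbind(c(0, 0), c(0.5, 0)))
  expect_equal(sample_covariances(matrix(0, 10, 2), 2)$lags[[3]],
               matrix(0, 2, 2))
  set.seed(3)
  z <- matrix(rnorm(20000 * 3), ncol = 3)
  expect_lt(max(abs(sample_covariances(z, 0)$lags[[1]] - diag(3))),
            5 / sqrt(20000))
  expect_error(sample_covariances(x, 2), "more rows")
})

test_that("block Toeplitz embedding is correct and PSD on exact covariances", {
  c0 <- matrix(2)
  expect_equal(block_toeplitz(cov_seq(list(c0))), matrix(2))
  expect_equal(block_toeplitz(cov_seq(list(matrix(2), matrix(1)))),
               rbind(c(2, 1), c(1, 2)))
  m <- random_stable_var(3, 2, seed = 11)
  tc <- theoretical_covariances(m, 2)
  ev <- eigen(block_toeplitz(tc), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("block trace sums super-diagonal blocks", {
  l00 <- matrix(1:4, 2); l01 <- matrix(5:8, 2); l11 <- matrix(9:12, 2)
  m <- rbind(cbind(l00, l01), cbind(t(l01), l11))
  expect_equal(block_trace(m, 0, 2), l00 + l11)
  expect_equal(block_trace(m, 1, 2), l01)
  expect_equal(block_trace(diag(6), 1, 2), matrix(0, 2, 2))
  expect_error(block_trace(m, 2, 2), "out of range")
  # negative offsets via the transpose: for symmetric M the sub-diagonal
  # block sum D_{-i}(M) equals D_i(M)^T -- checked by brute-force loops
  set.seed(4)
  mm <- matrix(rnorm(36), 6)
  mm <- mm + t(mm)
  brute_super <- function(m, i, b) {
    nb <- nrow(m) / b
    out <- matrix(0, b, b)
    for (h in 0:(nb - 1 - i))
      out <- out + m[h * b + 1:b, (h + i) * b + 1:b]
    out
  }
  brute_sub <- function(m, i, b) {
    nb <- nrow(m) / b
    out <- matrix(0, b, b)
    for (h in 0:(nb - 1 - i))
      out <- out + m[(h + i) * b + 1:b, h * b + 1:b]
    out
  }
  for (i in 0:2) {
    expect_equal(block_trace(mm, i, 2), brute_super(mm, i, 2))
    expect_equal(t(block_trace(mm, i, 2)), brute_sub(mm, i, 2))
  }
})

test_that("ISDM coefficients match the defining sum and the transfer function", {
  # white noise: Q0 = Sigma^{-1}
  sig <- rbind(c(2, 0.5), c(0.5, 1))
  m0 <- var_model(list(), sig)
  expect_equal(isdm_from_var(m0)$coeffs[[1]], solve(sig))
  # scalar AR(1)
  m1 <- var_model(list(matrix(0.5)), matrix(2))
  q <- isdm_from_var(m1)
  expect_equal(q$coeffs[[1]][1, 1], (1 + 0.25) / 2)
  expect_equal(q$coeffs[[2]][1, 1], -0.5 / 2)
  # grid evaluation equals A(w)^H Sigma^{-1} A(w) computed directly
  m <- random_stable_var(3, 2, seed = 21)
  poly <- isdm_from_var(m)
  om <- freq_grid(64)
  vals <- eval_trig_poly(poly, om)
  sinv <- solve(m$sigma)
  for (w in c(1, 17, 40)) {
    aw <- -(-diag(3))   # A_0 = -I enters with e^0
    aw <- diag(3) + 0i
    for (i in seq_len(m$p)) aw <- aw - m$coeffs[[i]] * exp(-1i * om[w] * i)
    direct <- Conj(t(aw)) %*% sinv %*% aw
    expect_lt(max(abs(vals[, , w] - direct)), 1e-10)
  }
  expect_gt(min_eig_on_grid(poly), 0)
})

test_that("exact covariances solve the Lyapunov equation and match long runs", {
  m0 <- var_model(list(matrix(0, 2, 2)), diag(2))
  tc0 <- theoretical_covariances(m0, 1)
  expect_equal(tc0$lags[[1]], diag(2))
  expect_equal(tc0$lags[[2]], matrix(0, 2, 2))
  m1 <- var_model(list(matrix(0.5)), matrix(1))
  tc1 <- theoretical_covariances(m1, 1)
  expect_equal(tc1$lags[[1]][1, 1], 4 / 3)
  expect_equal(tc1$lags[[2]][1, 1], 0.5 * 4 / 3)
  m <- random_stable_var(2, 1, seed = 31)
  tc <- theoretical_covariances(m, 1)
  x <- simulate_var(m, 100000, seed = 5)
  sc <- sample_covariances(x, 1)
  expect_lt(max(abs(sc$lags[[1]] - tc$lags[[1]])), 0.1)
  expect_lt(max(abs(sc$lags[[2]] - tc$lags[[2]])), 0.1)
})

test_that("simulated covariances converge to the exact ones as T grows", {
  m <- random_stable_var(2, 1, seed = 41)
  tc <- theoretical_covariances(m, 1)
  errs <- vapply(c(1e3, 1e4, 1e5), function(tt) {
    sc <- sample_covariances(simulate_var(m, tt, seed = 9), 1)
    max(abs(sc$lags[[1]] - tc$lags[[1]]),
        abs(sc$lags[[2]] - tc$lags[[2]]))
  }, 0)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("synthetic generator prescribes the stated coefficients", {
  cells <- rbind(c(4, 2), c(7, 3))
  g <- generate_synthetic_model(2, k = 8, positions = cells, seed = 1)
  q0 <- g$isdm$coeffs[[1]]
  q1 <- g$isdm$coeffs[[2]]
  expect_equal(q0[4, 2], 0.5)
  expect_equal(q1[4, 2], 0.25)
  expect_equal(q0[7, 3], 0.5)
  expect_equal(unname(q0[9, 1]), 0.3)
  expect_equal(unname(q1[9, 5]), 0.15)
  expect_true(all(diag(q1) == 1))
  # zero cells of the true pattern are exactly zero in every manifest block
  man <- 1:8
  zero <- !g$pattern$adjacency
  expect_true(all(q0[man, man][zero] == 0))
  expect_true(all(q1[man, man][zero] == 0))
  # scale-50 variant used by the short-sample study
  g50 <- generate_synthetic_model(2, k = 8, positions = cells, seed = 1,
                                  scale = 50)
  expect_equal(g50$isdm$coeffs[[1]][4, 2], 25)
  expect_equal(g50$isdm$coeffs[[2]][4, 2], 12.5)
  expect_equal(unname(g50$isdm$coeffs[[1]][9, 1]), 15)
  expect_equal(unname(g50$isdm$coeffs[[2]][9, 1]), 7.5)
})

test_that("generator round-trips through spectral factorization", {
  g <- generate_synthetic_model(3, k = 6, seed = 7)
  expect_true(is_stable(g$model))
  rt <- isdm_from_var(g$model)
  for (i in 1:2)
    expect_lt(max(abs(rt$coeffs[[i]] - g$isdm$coeffs[[i]])), 1e-6)
  expect_error(generate_synthetic_model(20, k = 5), "0..10")
})

test_that("pattern distance is a metric with the documented values", {
  a <- pattern_from_cells(15, rbind(c(3, 1), c(9, 4)))
  full <- sparsity_pattern(matrix(TRUE, 15, 15))
  expect_equal(pattern_distance(a, a), 0)
  expect_equal(pattern_distance(a, full), 103)
  b <- pattern_from_cells(15, rbind(c(3, 1), c(9, 4), c(5, 2)))
  expect_equal(pattern_distance(a, b), 1)
  set.seed(8)
  pats <- lapply(1:6, function(i) {
    adj <- matrix(runif(25) < 0.4, 5, 5)
    sparsity_pattern(adj | t(adj))
  })
  for (i in 1:4) {
    x <- pats[[i]]; y <- pats[[i + 1]]; z <- pats[[i + 2]]
    expect_equal(pattern_distance(x, y), pattern_distance(y, x))
    expect_lte(pattern_distance(x, z),
               pattern_distance(x, y) + pattern_distance(y, z))
  }
  expect_error(pattern_distance(a, pats[[1]]), "different sizes")
})

test_that("time-series and model files round-trip", {
  m <- random_stable_var(3, 2, seed = 51)
  x <- simulate_var(m, 50, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_ts(round(x, 6), f)
  expect_equal(read_ts(f), round(x, 6))
  f2 <- tempfile(fileext = ".tsv")
  write_ts(round(x, 6), f2, sep = "\t")
  expect_equal(read_ts(f2), round(x, 6))
  fm <- tempfile(fileext = ".json")
  write_var_model(m, fm, seed = 51)
  m2 <- read_var_model(fm)
  expect_equal(m2$coeffs, m$coeffs, tolerance = 1e-12)
  expect_equal(m2$sigma, m$sigma, tolerance = 1e-12)
  unlink(c(f, f2, fm))
})
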