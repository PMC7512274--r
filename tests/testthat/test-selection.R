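test_that("effective parameter count follows the closed formula", {
  expect_equal(effective_params(15, p = 1, n0 = 0), 345)
  expect_equal(effective_params(15, p = 1, n0 = 103), 36)
  # diagonal pattern: K(p+1)
  kbar <- 15 * 14 / 2
  expect_equal(effective_params(15, p = 1, n0 = kbar), 30)
  expect_equal(effective_params(15, p = 3, n0 = kbar), 60)
  sp <- sparsity_pattern(diag(15) > 0)
  expect_equal(effective_params(sp, p = 1), 30)
})

test_that("criteria obey their defining identities", {
  set.seed(23)
  a <- crossprod(matrix(rnorm(25), 5)) / 5 + diag(5)
  r0 <- a + diag(5)
  tt <- 5000; k <- 5
  # Sigma = I makes SBC the pure penalty
  expect_equal(compute_itc("SBC", diag(k), r0, n_ef = 17, T = tt, K = k),
               17 * log(tt))
  # EBIC at gamma = 0 is SBC
  for (n0 in c(0, 3, 7)) {
    nef <- effective_params(k, p = 1, n0 = n0)
    expect_equal(
      compute_itc("EBIC", a, r0, nef, tt, k, gamma = 0, n0 = n0),
      compute_itc("SBC", a, r0, nef, tt, k, n0 = n0))
  }
  # RNMLFD - RNML = 2 Nef log K for random valid inputs
  for (nef in c(10, 25, 40)) {
    d <- compute_itc("RNMLFD", a, r0, nef, tt, k) -
      compute_itc("RNML", a, r0, nef, tt, k)
    expect_equal(d, 2 * nef * log(k))
  }
  expect_error(compute_itc("AICc", a, r0, n_ef = tt, T = tt, K = k),
               "AICc")
  expect_error(compute_itc("RNML", a + diag(5), a, 10, tt, k),
               "tr\\(R0")
  vals <- itc_all(a, r0, 20, tt, k)
  expect_named(vals, c("SBC", "AICc", "logFPE", "RNML", "EBIC", "EBICFD",
                       "RNMLFD"))
})

test_that("criteria increase with residual log-determinant and complexity", {
  tt <- 2000; k <- 5
  r0 <- 3 * diag(k)
  sig1 <- diag(k); sig2 <- 1.2 * diag(k)
  for (nm in c("SBC", "AICc", "logFPE", "RNML", "EBIC", "EBICFD",
               "RNMLFD")) {
    expect_lt(compute_itc(nm, sig1, r0, 20, tt, k),
              compute_itc(nm, sig2, r0, 20, tt, k))
  }
  for (nm in c("SBC", "EBICFD", "RNMLFD")) {
    v <- vapply(c(10, 20, 30, 40), function(nef)
      compute_itc(nm, sig1, r0, nef, tt, k), 0)
    expect_true(all(diff(v) > 0))
  }
})

test_that("family-size penalties differ as documented over the zero count", {
  k <- 15; kbar <- k * (k - 1) / 2
  tt <- 1000
  sig <- diag(k); r0 <- 2 * diag(k)
  n0s <- 0:kbar
  ebic_extra <- vapply(n0s, function(n0)
    compute_itc("EBIC", sig, r0, effective_params(k, 1, n0), tt, k,
                n0 = n0) -
      compute_itc("SBC", sig, r0, effective_params(k, 1, n0), tt, k), 0)
  fd_extra <- vapply(n0s, function(n0)
    compute_itc("EBICFD", sig, r0, effective_params(k, 1, n0), tt, k,
                n0 = n0) -
      compute_itc("SBC", sig, r0, effective_params(k, 1, n0), tt, k), 0)
  # the finite-dimensional penalty grows as N0 decreases ...
  expect_true(all(diff(fd_extra) < 0))
  # ... while the binomial term peaks at N0 = Kbar/2 and is symmetric
  expect_equal(which.max(ebic_extra), which.min(abs(n0s - kbar / 2)))
  expect_false(all(diff(ebic_extra) < 0))
})

test_that("Bartlett correlogram has the stated structure", {
  set.seed(24)
  x <- matrix(rnorm(4000 * 2), ncol = 2)
  # M = 0: constant spectrum R0
  c0 <- correlogram_bartlett(x, window_len = 0)
  expect_equal(c0$degree, 0)
  expect_equal(c0$coeffs[[1]], sample_covariances(x, 0)$lags[[1]])
  cg <- correlogram_bartlett(x)
  expect_equal(cg$degree, floor(sqrt(4000)))
  om <- c(0.4, 1.3)
  vals <- eval_trig_poly(cg, c(om, -om))
  # every evaluation is Hermitian, and the value at -w is its conjugate
  expect_equal(vals[, , 1], Conj(t(vals[, , 1])), tolerance = 1e-12)
  expect_equal(vals[, , 3], Conj(vals[, , 1]), tolerance = 1e-12)
  expect_equal(vals[, , 4], Conj(vals[, , 2]), tolerance = 1e-12)
  # white noise: spectrum stays near R0 at every frequency
  valsg <- eval_trig_poly(cg, freq_grid(64))
  expect_lt(max(abs(valsg[1, 1, ] - cg$coeffs[[1]][1, 1])),
            4 * sqrt(cg$degree / 4000))
})

test_that("relative entropy rate matches closed forms and is nonnegative", {
  id <- array(rep(diag(2), 8), c(2, 2, 8)) + 0i
  expect_equal(relative_entropy_rate(id, id), 0)
  # scalar constant spectra with ratio 2: -(log 2 + 1 - 2)/2
  n <- 256
  num <- array(2 + 0i, c(1, 1, n))
  den <- array(1 + 0i, c(1, 1, n))
  expect_equal(relative_entropy_rate(num, den),
               -(log(2) + 1 - 2) / 2, tolerance = 1e-6)
  # always >= 0 over random PD spectrum pairs (per-eigenvalue inequality)
  set.seed(25)
  for (i in 1:4) {
    m1 <- random_stable_var(2, 1, seed = 300 + i)
    m2 <- random_stable_var(2, 1, seed = 400 + i)
    p1 <- eval_trig_poly(isdm_from_var(m1), freq_grid(128))
    p2 <- eval_trig_poly(isdm_from_var(m2), freq_grid(128))
    expect_gte(relative_entropy_rate(p1, p2), -1e-9)
  }
})

test_that("score functions combine divergence and edge count", {
  sf <- score_functions(0.1, 10, T = 1000)
  expect_equal(unname(sf["SF1"]), 0)
  expect_equal(unname(sf["SF3"] - sf["SF2"]), 10 * (log(1000) - 1) / 1000)
  # one latent variable: Ne = K(K+1)/2 - N0
  expect_equal(megvar:::.edge_count(15, 103, 1), 17)
  expect_equal(15 * 16 / 2 - 103, 17)
  expect_error(score_functions(-1, 10, 100), "d > 0")
  expect_error(score_functions(0.1, 0, 100), "at least 1")
})
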