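test_that("sparsity promoter sums per-pair maxima of entry coefficients", {
  # zero off-diagonal manifest entries in every block trace
  expect_equal(sparsity_promoter(diag(6), k = 3, block = 3), 0)
  # p = 0, single pair, single coefficient
  z <- rbind(c(1, 0.3), c(0.3, 2))
  expect_equal(sparsity_promoter(z, k = 2, block = 2), 0.3)
  # p = 1: max over the coefficients of the (2,1) entry polynomial
  z2 <- matrix(0, 4, 4)
  z2[2, 1] <- z2[1, 2] <- 0.2          # D_0(2,1) = 0.2
  z2[2, 3] <- z2[3, 2] <- -0.5         # D_1(2,1) = -0.5
  expect_equal(sparsity_promoter(z2, k = 2, block = 2), 0.5)
})

test_that("MEI solves the scalar problem and white-noise case exactly", {
  s <- solve_me1(cov_seq(list(matrix(2))))
  expect_equal(s$X[1, 1], 0.5, tolerance = 1e-12)
  expect_lt(abs(s$gap), 1e-10)
  s2 <- solve_me1(cov_seq(list(diag(3), matrix(0, 3, 3))))
  expect_equal(s2$D[[1]], diag(3), tolerance = 1e-10)
  expect_equal(s2$D[[2]], matrix(0, 3, 3), tolerance = 1e-10)
  expect_error(solve_me1(cov_seq(list(matrix(c(1, 2, 2, 1), 2)))),
               "positive definite")
})

test_that("MEI on exact covariances equals the Yule-Walker fit", {
  for (seed in c(101, 102)) {
    m <- random_stable_var(4, 2, seed = seed)
    tc <- theoretical_covariances(m, 2)
    sol <- solve_me1(tc)
    oracle <- yule_walker_isdm_oracle(tc)
    for (i in 1:3)
      expect_lt(max(abs(sol$D[[i]] - oracle[[i]])), 1e-4)
    # and both agree with the generating model's inverse spectrum
    truth <- isdm_from_var(m)
    for (i in 1:3)
      expect_lt(max(abs(sol$D[[i]] - truth$coeffs[[i]])), 1e-6)
  }
})

test_that("MEII honors the latent constraints and the identity special case", {
  cc <- cov_seq(list(diag(6), matrix(0, 6, 6)))
  s <- solve_me2(cc, lam = 0.05, K = 5, r = 1)
  expect_equal(s$objective, 6, tolerance = 1e-6)
  expect_lt(max(abs(s$X[1:6, 1:6] - diag(6))), 1e-6)
  expect_lt(max(abs(s$X[7:12, ])), 1e-6)
  expect_error(solve_me2(cc, lam = -1, K = 5, r = 1), "nonnegative")

  poly <- normalized_latent_isdm(5, rbind(c(3, 1), c(5, 2)))
  tc <- theoretical_covariances(spectral_factorize(poly), 1)
  for (lam in c(0.01, 0.2)) {
    s <- solve_me2(tc, lam, K = 5, r = 1)
    d0 <- s$D[[1]]; d1 <- s$D[[2]]
    expect_lt(abs(d0[6, 6] - 1), 1e-6)   # lag-0 latent block = I
    expect_lt(abs(d1[6, 6]), 1e-6)       # higher-lag latent block = 0
    ev <- eigen(s$X, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-6)
  }
})

test_that("MEII penalty value is non-increasing along the lambda grid", {
  poly <- normalized_latent_isdm(4, rbind(c(3, 1)))
  m <- spectral_factorize(poly)
  x <- simulate_var(m, 5000, seed = 3)[, 1:4]
  cc <- expectation_step(sample_covariances(x, 1),
                         megvar:::.qlm_zero_init(matrix(0.2, 1, 4), 1))
  fs <- vapply(c(0.005, 0.02, 0.08, 0.3), function(lam) {
    sol <- solve_me2(cc, lam, K = 4, r = 1)
    sparsity_promoter(sol, 4, block = 5)
  }, 0)
  expect_true(all(diff(fs) <= 1e-6))
})

test_that("MEIII enforces hard zeros and recovers a pattern-true system", {
  cells <- rbind(c(3, 1), c(5, 2))
  poly <- normalized_latent_isdm(5, cells)
  sp <- pattern_from_cells(5, cells)
  tc <- theoretical_covariances(spectral_factorize(poly), 1)
  s3 <- solve_me3(tc, sp, K = 5, r = 1)
  # maximum-entropy covariance extension: exact recovery of the truth
  expect_lt(max(abs(s3$D[[1]] - poly$coeffs[[1]])), 1e-3)
  expect_lt(max(abs(s3$D[[2]] - poly$coeffs[[2]])), 1e-3)
  # constrained cells vanish
  zero <- which(lower.tri(sp$adjacency) & !sp$adjacency, arr.ind = TRUE)
  for (e in seq_len(nrow(zero))) {
    a <- zero[e, 1]; b <- zero[e, 2]
    expect_lt(abs(s3$D[[1]][a, b]), 1e-8)
    expect_lt(abs(s3$D[[2]][a, b]), 1e-8)
    expect_lt(abs(s3$D[[2]][b, a]), 1e-8)
  }
  # all-true pattern reduces MEIII to MEII at lambda = 0
  full <- sparsity_pattern(matrix(TRUE, 5, 5))
  sfull <- solve_me3(tc, full, K = 5, r = 1)
  s20 <- solve_me2(tc, 1e-9, K = 5, r = 1)
  expect_lt(abs(sfull$objective - s20$objective), 1e-6)
})

test_that("ME objectives are invariant under variable permutation", {
  poly <- normalized_latent_isdm(4, rbind(c(2, 1), c(4, 3)))
  tc <- theoretical_covariances(spectral_factorize(poly), 1)
  perm <- c(3, 1, 4, 2)
  lags_p <- lapply(tc$lags, function(cl) cl[c(perm, 5), c(perm, 5)])
  tcp <- cov_seq(lags_p)
  s <- solve_me2(tc, 0.05, K = 4, r = 1)
  sp_ <- solve_me2(tcp, 0.05, K = 4, r = 1)
  expect_lt(abs(s$objective - sp_$objective), 1e-6)
  man <- cov_seq(lapply(tc$lags, function(cl) cl[1:4, 1:4]))
  manp <- cov_seq(lapply(lags_p, function(cl) cl[1:4, 1:4]))
  expect_lt(abs(solve_me1(man)$objective - solve_me1(manp)$objective),
            1e-8)
})
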