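test_that("eigenvalue initialization extracts the leading latent direction", {
  expect_equal(init_latent_from_eig(diag(c(4, 1)), 1), rbind(c(2, 0)))
  g <- init_latent_from_eig(diag(3), 1)
  expect_equal(sum(g^2), 1)
  set.seed(12)
  a <- crossprod(matrix(rnorm(16), 4))
  g1 <- init_latent_from_eig(a, 1)
  # rank-1 truncation sits below Q0 in the PSD order
  ev <- eigen(a - crossprod(g1), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_error(init_latent_from_eig(diag(2), 3), "latent")
})

test_that("expectation step reduces to the identity extension at zero coupling", {
  m <- random_stable_var(3, 1, seed = 13)
  rh <- theoretical_covariances(m, 1)
  qlm <- megvar:::.qlm_zero_init(matrix(0, 1, 3), 1)
  cc <- expectation_step(rh, qlm)
  expect_equal(cc$dim, 4)
  # manifest block equals the input covariances exactly
  expect_equal(cc$lags[[1]][1:3, 1:3], rh$lags[[1]])
  expect_equal(cc$lags[[2]][1:3, 1:3], rh$lags[[2]])
  # latent block is the identity at lag 0 and zero elsewhere
  expect_equal(cc$lags[[1]][4, 4], 1)
  expect_equal(cc$lags[[2]][4, 4], 0)
  expect_equal(cc$lags[[1]][4, 1:3], c(0, 0, 0))
})

test_that("expectation step matches a hand-computed scalar convolution", {
  r0 <- 2; r1 <- 0.7
  rh <- cov_seq(list(matrix(r0), matrix(r1)))
  qm <- c(-0.3, 0.4, 0.2)   # lags -1, 0, 1
  qlm <- list(matrix(qm[1]), matrix(qm[2]), matrix(qm[3]))
  cc <- expectation_step(rh, qlm)
  clm0 <- -(qm[1] * r1 + qm[2] * r0 + qm[3] * r1)
  expect_equal(cc$lags[[1]][2, 1], clm0)
  # manifest block copied verbatim
  expect_equal(cc$lags[[1]][1, 1], r0)
  expect_equal(cc$lags[[2]][1, 1], r1)
  expect_error(expectation_step(rh, qlm[1:2]), "lags")
})

test_that("maximum PSC is a normalized, scale-free edge statistic", {
  d <- trig_poly(list(diag(c(1, 2, 3)), matrix(0, 3, 3)))
  expect_equal(max_psc(d, 1, 2), 0)
  two <- trig_poly(list(rbind(c(1, 0.5), c(0.5, 1))))
  expect_equal(max_psc(two, 2, 1), 0.5)
  m <- random_stable_var(3, 1, seed = 14)
  poly <- isdm_from_var(m)
  v1 <- max_psc(poly, 2, 1)
  poly5 <- trig_poly(lapply(poly$coeffs, function(q) 5 * q))
  expect_equal(max_psc(poly5, 2, 1), v1, tolerance = 1e-12)
  expect_error(max_psc(poly, 2, 2), "differ")
})

test_that("pattern extraction thresholds the PSC and is monotone", {
  d <- trig_poly(list(diag(4), matrix(0, 4, 4)))
  sp <- extract_pattern(d, 1e-3, 4)
  expect_equal(sp$n0, 6)
  # a pair whose max PSC is 5e-4 is declared a non-edge at Th = 1e-3
  q0 <- diag(4); q0[2, 1] <- q0[1, 2] <- 5e-4
  spx <- extract_pattern(trig_poly(list(q0, matrix(0, 4, 4))), 1e-3, 4)
  expect_false(spx$adjacency[2, 1])
  expect_true(extract_pattern(trig_poly(list(q0, matrix(0, 4, 4))),
                              1e-4, 4)$adjacency[2, 1])
  # raising the threshold never decreases the zero count
  m <- random_stable_var(4, 1, seed = 15)
  poly <- isdm_from_var(m)
  n0s <- vapply(c(1e-4, 1e-2, 0.1, 0.5), function(th)
    extract_pattern(poly, th, 4)$n0, 0)
  expect_true(all(diff(n0s) >= 0))
  expect_error(extract_pattern(poly, 0, 4), "positive")
})

test_that("the EM sweep returns one candidate per lambda and is reproducible", {
  gen <- generate_synthetic_model(2, k = 5, seed = 16)
  x <- simulate_var(gen$model, 4000, seed = 17)[, 1:5]
  lam <- c(0.02, 0.05, 0.1)
  fit <- megvar(x, lambda = lam, nit = 1, score_loops = character(0),
                constrained = FALSE)
  expect_length(fit$candidates, 3)
  expect_true(all(vapply(fit$candidates, function(cd) isTRUE(cd$ok), TRUE)))
  # weak penalties leave the pattern dense
  expect_lte(fit$candidates[[1]]$n0, 2)
  fit_na <- megvar(x, lambda = lam, nit = 1, adaptive = FALSE,
                   score_loops = character(0), constrained = FALSE)
  expect_length(fit_na$candidates, 3)
  # adaptive and non-adaptive runs share the first grid point exactly
  expect_equal(fit$candidates[[1]]$isdm_pen$coeffs,
               fit_na$candidates[[1]]$isdm_pen$coeffs)
  # and the sweep is deterministic
  fit2 <- megvar(x, lambda = lam, nit = 1, score_loops = character(0),
                 constrained = FALSE)
  expect_equal(fit$candidates[[3]]$isdm_pen$coeffs,
               fit2$candidates[[3]]$isdm_pen$coeffs)
})

test_that("assembled inverse spectra carry an exact identity latent block", {
  gen <- generate_synthetic_model(1, k = 4, seed = 18)
  x <- simulate_var(gen$model, 4000, seed = 19)[, 1:4]
  fit <- megvar(x, lambda = c(0.03, 0.08), nit = 2,
                score_loops = "constrained")
  for (cd in fit$candidates) {
    for (isdm in list(cd$isdm_pen, cd$isdm_con)) {
      expect_equal(isdm$coeffs[[1]][5, 5], 1)
      expect_equal(isdm$coeffs[[2]][5, 5], 0)
    }
    ev <- eigen(cd$sigma_con, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("EM fixed point: zero coupling plus unpenalized solve gives MEI", {
  m <- random_stable_var(4, 1, seed = 20)
  tc <- theoretical_covariances(m, 1)
  me1 <- solve_me1(tc)
  cc <- expectation_step(tc, megvar:::.qlm_zero_init(matrix(0, 1, 4), 1))
  s2 <- solve_me2(cc, 1e-10, K = 4, r = 1)
  for (i in 1:2)
    expect_lt(max(abs(s2$D[[i]][1:4, 1:4] - me1$D[[i]])), 1e-4)
})
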