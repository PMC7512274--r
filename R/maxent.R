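#' Group-sparsity promoter for block-trace coefficients
#'
#' Evaluates \eqn{f(Z) = \sum_{a>b} \max_i |D_i(Z)(a,b)|} over the
#' below-diagonal manifest pairs, where the maximum runs over all
#' coefficients of the `(a, b)` entry polynomial of
#' \eqn{\Delta Z \Delta^H}: the lag coefficients `D_i(Z)(a,b)` for
#' `i = 0..p` together with the mirrored cells `D_i(Z)(b,a)`, `i >= 1`,
#' which carry the negative lags. Tying the whole group together drives an
#' entire inverse-spectrum entry function to zero at once.
#'
#' @param z a symmetric block parameter matrix (or an `"me_solution"`).
#' @param k number of manifest variables (pairs with `a, b <= k` count).
#' @param block block size of `z` (defaults to `k`, or the solution's block).
#' @return Nonnegative scalar; zero iff all penalized entries vanish.
#' @export
sparsity_promoter <- function(z, k, block = NULL) {
  if (inherits(z, "me_solution")) {
    if (is.null(block)) block <- z$block
    z <- z$X
  }
  if (is.null(block)) block <- k
  d <- block_traces(z, block)
  tot <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(max(a - 1, 0))) {
      vals <- abs(d[[1]][a, b])
      for (i in seq_along(d)[-1])
        vals <- c(vals, abs(d[[i]][a, b]), abs(d[[i]][b, a]))
      tot <- tot + max(vals)
    }
  }
  tot
}

# ---- internal: dual machinery -------------------------------------------
#
# All three maximum-entropy programs share the form
#   min_{X >= 0} tr(M X) - logdet X00 + lambda f(X),  A(X) = b,
# with M = T(C).  Dualizing penalty and equality constraints gives
#   max g(theta) = m + logdet N - logdet N11 - b' theta,
#   N = M + sum_q theta_q S_q,
# over per-pair l1 balls (penalty duals) and free multipliers, where N11 is
# the trailing m*p block of N.  The inner minimizer -- the primal solution --
# is available in closed form: X* = N^{-1} - blkdiag(0, N11^{-1}), and the
# dual gradient is exactly the vector of primal functional values A(X*) - b,
# D_i(X*)(a,b).  MEI has no dual variables (closed form), MEII is solved by
# spectral projected gradient over the balls, MEIII by Newton.

# entry-list basis for the functional X -> D_i(X)(a, b) on symmetric X
.basis_entry <- function(a, b, i, m, p) {
  hs <- 0:(p - i)
  if (i == 0 && a == b) {
    list(r = hs * m + a, c = hs * m + a, v = rep(1, length(hs)))
  } else {
    r <- c(hs * m + a, (hs + i) * m + b)
    c <- c((hs + i) * m + b, hs * m + a)
    list(r = r, c = c, v = rep(0.5, length(r)))
  }
}

# flatten a list of basis entries into parallel vectors
.basis_flatten <- function(basis, n) {
  grp <- rep(seq_along(basis), vapply(basis, function(e) length(e$r), 0L))
  re <- unlist(lapply(basis, `[[`, "r"))
  ce <- unlist(lapply(basis, `[[`, "c"))
  ve <- unlist(lapply(basis, `[[`, "v"))
  list(grp = grp, re = re, ce = ce, ve = ve, n = n,
       lin_rc = (ce - 1L) * n + re,   # index of N[r, c] add positions
       lin_cr = (re - 1L) * n + ce,   # index of X[c, r] for tr(S X)
       nvar = length(basis))
}

# latent-block equality constraints of MEII/MEIII: D_0 latent = I,
# D_i latent = 0 for i = 1..p
.latent_basis <- function(K, r, p, m) {
  basis <- list(); b <- numeric(0)
  for (al in seq_len(r)) {
    for (be in al:r) {
      basis <- c(basis, list(.basis_entry(K + be, K + al, 0, m, p)))
      b <- c(b, as.numeric(al == be))
    }
  }
  if (p >= 1) {
    for (i in seq_len(p)) {
      for (al in seq_len(r)) {
        for (be in seq_len(r)) {
          basis <- c(basis, list(.basis_entry(K + al, K + be, i, m, p)))
          b <- c(b, 0)
        }
      }
    }
  }
  list(basis = basis, b = b)
}

# sum an entry-by-entry matrix into a group-by-group matrix
.aggregate_by_group <- function(term, grp, nvar) {
  tmp <- rowsum(term, grp, reorder = TRUE)
  tmp <- t(rowsum(t(tmp), grp, reorder = TRUE))
  out <- matrix(0, nvar, nvar)
  pres <- sort(unique(grp))
  out[pres, pres] <- tmp
  out
}

# N and its value pieces; returns NULL when N leaves the PD domain
.dual_eval <- function(M, fl, theta, m) {
  n <- nrow(M)
  N <- M
  if (length(theta))
    N[fl$lin_rc] <- N[fl$lin_rc] + fl$ve * theta[fl$grp]
  ch <- tryCatch(chol(N), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  ld <- 2 * sum(log(diag(ch)))
  if (n > m) {
    n11 <- N[(m + 1):n, (m + 1):n, drop = FALSE]
    ch11 <- tryCatch(chol(n11), error = function(e) NULL)
    if (is.null(ch11)) return(NULL)
    ld11 <- 2 * sum(log(diag(ch11)))
  } else {
    ch11 <- NULL
    ld11 <- 0
  }
  list(N = N, chol = ch, chol11 = ch11, logdet = ld, logdet11 = ld11)
}

# primal minimizer X* = N^{-1} - blkdiag(0, N11^{-1}) from a .dual_eval
.dual_primal <- function(ev, m) {
  n <- nrow(ev$N)
  xs <- chol2inv(ev$chol)
  if (n > m) {
    idx <- (m + 1):n
    xs[idx, idx] <- xs[idx, idx] - chol2inv(ev$chol11)
  }
  xs
}

.dual_grad <- function(ev, fl, b, m) {
  xs <- .dual_primal(ev, m)
  g <- as.vector(rowsum(fl$ve * xs[fl$lin_cr], fl$grp,
                        reorder = TRUE)) - b
  list(grad = g, xstar = xs)
}

# Newton maximization of g over the free variables listed in `free`
# (all others held at theta); used for MEIII and for polishing the
# equality multipliers of MEII.
.dual_newton <- function(M, fl, b, m, theta, free = seq_len(fl$nvar),
                         gtol = 1e-9, maxit = 60, loose_tol = 1e-6) {
  n <- nrow(M)
  sel <- fl$grp %in% free
  sgrp <- match(fl$grp[sel], free)
  sre <- fl$re[sel]; sce <- fl$ce[sel]; sve <- fl$ve[sel]
  in11 <- sre > m & sce > m
  ev <- .dual_eval(M, fl, theta, m)
  if (is.null(ev)) stop("infeasible start for dual Newton")
  gval <- m + ev$logdet - ev$logdet11 - sum(b * theta)
  status <- "max_iterations"
  for (it in seq_len(maxit)) {
    gr <- .dual_grad(ev, fl, b, m)$grad[free]
    if (max(abs(gr)) < gtol) { status <- "converged"; break }
    ninv <- chol2inv(ev$chol)
    a1 <- ninv[sce, sre, drop = FALSE]
    term <- -(outer(sve, sve) * a1 * t(a1))
    hfull <- .aggregate_by_group(term, sgrp, length(free))
    if (any(in11) && n > m) {
      n11inv <- chol2inv(ev$chol11)
      r11 <- sre[in11] - m; c11 <- sce[in11] - m; v11 <- sve[in11]
      a2 <- n11inv[c11, r11, drop = FALSE]
      h11 <- outer(v11, v11) * a2 * t(a2)
      hfull <- hfull + .aggregate_by_group(h11, sgrp[in11], length(free))
    }
    # solve (-H) d = grad; -H is PSD, add tiny ridge for safety
    d <- tryCatch(solve(-hfull + diag(1e-12, length(free)), gr),
                  error = function(e) gr)
    step <- 1
    improved <- FALSE
    for (ls in 1:40) {
      thn <- theta
      thn[free] <- theta[free] + step * d
      evn <- .dual_eval(M, fl, thn, m)
      if (!is.null(evn)) {
        gn <- m + evn$logdet - evn$logdet11 - sum(b * thn)
        if (gn > gval + 1e-4 * step * sum(gr * d)) {
          theta <- thn; ev <- evn; gval <- gn; improved <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!improved) {
      # line search exhausted: accept if the gradient is already small
      status <- if (max(abs(gr)) < loose_tol) "converged" else "stalled"
      break
    }
  }
  if (status == "max_iterations" &&
      max(abs(.dual_grad(ev, fl, b, m)$grad[free])) < loose_tol)
    status <- "converged"
  list(theta = theta, ev = ev, value = gval, status = status,
       iterations = it)
}

# project each row of w (pairs x (p+1)) onto the l1 ball of radius lam
.project_l1_rows <- function(w, lam) {
  aw <- abs(w)
  s <- rowSums(aw)
  over <- s > lam
  if (!any(over)) return(w)
  wo <- aw[over, , drop = FALSE]
  k <- ncol(wo)
  us <- t(apply(wo, 1, sort, decreasing = TRUE))
  if (k == 1) us <- matrix(us, ncol = 1)
  css <- t(apply(us, 1, cumsum))
  if (k == 1) css <- matrix(css, ncol = 1)
  js <- matrix(rep(seq_len(k), each = nrow(wo)), nrow(wo), k)
  cond <- us - (css - lam) / js > 0
  rho <- apply(cond, 1, function(z) max(which(z)))
  tau <- (css[cbind(seq_len(nrow(wo)), rho)] - lam) / rho
  shrunk <- pmax(wo - tau, 0) * sign(w[over, , drop = FALSE])
  w[over, ] <- shrunk
  w
}

.me_solution <- function(xstar, m, p, K, r, M, lam = 0, dual = NA_real_,
                         iterations = 0L, status = "closed_form",
                         theta = NULL) {
  x00 <- xstar[seq_len(m), seq_len(m), drop = FALSE]
  ld <- 2 * sum(log(diag(chol(x00))))
  fval <- if (K > 1) sparsity_promoter(xstar, K, block = m) else 0
  primal <- sum(M * xstar) - ld + lam * fval
  structure(
    list(X = xstar, block = m, order = p, K = K, r = r,
         D = block_traces(xstar, m), lambda = lam, f = fval,
         objective = primal, dual = dual, gap = primal - dual,
         iterations = iterations, status = status, theta = theta),
    class = "me_solution")
}

#' @export
print.me_solution <- function(x, ...) {
  cat("maximum-entropy solution: block ", x$block, ", order ", x$order,
      "\n  objective ", format(x$objective, digits = 8), sep = "")
  if (is.finite(x$gap))
    cat(", duality gap ", format(x$gap, digits = 3), sep = "")
  cat("\n  status: ", x$status, " (", x$iterations, " iterations)\n",
      sep = "")
  invisible(x)
}

#' First maximum-entropy problem: unpenalized covariance extension
#'
#' Solves \eqn{\min_{X \succeq 0} tr(T(\hat R) X) - \log\det X_{00}} for the
#' manifest variables. The optimum is available in closed form from the
#' Schur complement of the block-Toeplitz matrix and coincides with the
#' Yule-Walker fit of a VAR(p) to the covariances: the inverse-spectrum
#' coefficients are the block traces \eqn{D_i(X)}.
#'
#' @param cov a [cov_seq()] with lags `0..p`; its block-Toeplitz embedding
#'   must be positive definite.
#' @return An `"me_solution"` with the optimal `X`, block traces `D`,
#'   objective and status.
#' @export
solve_me1 <- function(cov) {
  m <- cov$dim
  p <- cov$q
  M <- block_toeplitz(cov)
  ev <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ev))
    stop("solver failure: block-Toeplitz covariance matrix is not ",
         "positive definite (problem unbounded)")
  n <- nrow(M)
  xs <- chol2inv(ev)
  if (n > m) {
    idx <- (m + 1):n
    ch11 <- chol(M[idx, idx, drop = FALSE])
    xs[idx, idx] <- xs[idx, idx] - chol2inv(ch11)
    ld11 <- 2 * sum(log(diag(ch11)))
  } else ld11 <- 0
  # dual value g = m + logdet M - logdet M11 (no dual variables)
  gval <- m + 2 * sum(log(diag(ev))) - ld11
  .me_solution(xs, m, p, K = m, r = 0, M = M, dual = gval)
}

#' Second maximum-entropy problem: penalized latent-variable extension
#'
#' Solves the full-model program
#' \eqn{\min tr(T(C) X) - \log\det X_{00} + \lambda f(X)} over
#' \eqn{X \succeq 0} with the latent identity constraints (lag-0 latent
#' block of \eqn{D(X)} equal to `I`, higher lags zero) and the promoter `f`
#' applied to the manifest block only. The smooth dual is maximized by a
#' Barzilai-Borwein spectral projected gradient over per-pair l1 balls of
#' radius `lambda`, followed by a Newton polish of the equality multipliers;
#' the primal solution is recovered in closed form from the dual matrix.
#'
#' @param cov a (K+r)-dimensional [cov_seq()] with lags `0..p`.
#' @param lam nonnegative penalty weight.
#' @param K,r manifest and latent block sizes (`K + r` must equal the
#'   covariance dimension).
#' @param control list of solver knobs: `maxit` (default 3000), `tol`
#'   (projected-gradient tolerance, default 1e-8), `memory` (nonmonotone
#'   window, default 10), `polish` (default `TRUE`).
#' @return An `"me_solution"`; `status` records convergence and `gap` the
#'   (approximate) duality gap.
#' @export
solve_me2 <- function(cov, lam, K, r, control = list()) {
  if (lam < 0) stop("'lam' must be nonnegative")
  m <- cov$dim
  if (K + r != m) stop("K + r must equal the covariance dimension")
  p <- cov$q
  ctl <- utils::modifyList(
    list(maxit = 3000, tol = 1e-8, memory = 10, polish = TRUE), control)
  M <- block_toeplitz(cov)
  if (is.null(tryCatch(chol(M), error = function(e) NULL)))
    stop("solver failure: block-Toeplitz covariance matrix is not ",
         "positive definite")
  # dual variables: one (2p+1)-vector per below-diagonal manifest pair
  # (entry-polynomial coefficients at (a,b) for i = 0..p and (b,a) for
  # i = 1..p), then the latent equality multipliers
  pairs <- which(lower.tri(matrix(0, K, K)), arr.ind = TRUE)
  npair <- nrow(pairs)
  ngrp <- 2 * p + 1
  basis <- vector("list", npair * ngrp)
  q <- 0
  for (e in seq_len(npair)) {
    a <- pairs[e, 1]; bb <- pairs[e, 2]
    q <- q + 1
    basis[[q]] <- .basis_entry(a, bb, 0, m, p)
    for (i in seq_len(p)) {
      basis[[q + 1]] <- .basis_entry(a, bb, i, m, p)
      basis[[q + 2]] <- .basis_entry(bb, a, i, m, p)
      q <- q + 2
    }
  }
  lat <- .latent_basis(K, r, p, m)
  basis <- c(basis, lat$basis)
  b <- c(rep(0, npair * ngrp), lat$b)
  fl <- .basis_flatten(basis, nrow(M))
  nw <- npair * ngrp
  widx <- seq_len(nw)
  lidx <- (nw + 1):fl$nvar

  proj <- function(theta) {
    w <- matrix(theta[widx], npair, ngrp, byrow = TRUE)
    w <- .project_l1_rows(w, lam)
    theta[widx] <- as.vector(t(w))
    theta
  }
  gfun <- function(theta) {
    ev <- .dual_eval(M, fl, theta, m)
    if (is.null(ev)) return(NULL)
    list(ev = ev, val = m + ev$logdet - ev$logdet11 - sum(b * theta))
  }

  theta <- rep(0, fl$nvar)
  cur <- gfun(theta)
  gr <- .dual_grad(cur$ev, fl, b, m)$grad
  alpha <- 1 / max(1e-8, max(abs(gr)))
  hist_vals <- rep(-Inf, ctl$memory)
  hist_vals[1] <- cur$val
  status <- "max_iterations"
  it <- 0
  for (it in seq_len(ctl$maxit)) {
    pg <- proj(theta + gr) - theta
    if (max(abs(pg)) < ctl$tol) { status <- "converged"; break }
    d <- proj(theta + alpha * gr) - theta
    gtd <- sum(gr * d)
    ref <- max(hist_vals)
    step <- 1
    ok <- FALSE
    for (ls in 1:30) {
      thn <- theta + step * d
      nxt <- gfun(thn)
      if (!is.null(nxt) && nxt$val >= ref + 1e-4 * step * gtd) {
        ok <- TRUE; break
      }
      step <- step / 2
    }
    if (!ok) { status <- "stalled"; break }
    grn <- .dual_grad(nxt$ev, fl, b, m)$grad
    sdiff <- thn - theta
    ydiff <- grn - gr          # gradient of concave g: y = g'(new)-g'(old)
    sy <- -sum(sdiff * ydiff)  # positive for strictly concave g
    ss <- sum(sdiff * sdiff)
    alpha <- if (sy > 1e-14) min(max(ss / sy, 1e-6), 1e6) else 1
    theta <- thn; cur <- nxt; gr <- grn
    hist_vals[(it %% ctl$memory) + 1] <- cur$val
  }
  if (ctl$polish && length(lidx)) {
    pol <- .dual_newton(M, fl, b, m, theta, free = lidx,
                        gtol = 1e-10, maxit = 25)
    theta <- pol$theta
    cur <- list(ev = pol$ev, val = pol$value)
  }
  xs <- .dual_primal(cur$ev, m)
  sol <- .me_solution(xs, m, p, K, r, M, lam = lam, dual = cur$val,
                      iterations = it, status = status, theta = theta)
  sol
}

#' Third maximum-entropy problem: pattern-constrained extension
#'
#' As [solve_me2()] with `lam = 0` plus hard zeros: for every below-diagonal
#' manifest pair with `SP(a,b) = 0`, all lag coefficients
#' \eqn{D_i(X)(a,b)} and \eqn{D_i(X)(b,a)} are constrained to zero, so the
#' corresponding inverse-spectrum entry function vanishes identically. The
#' smooth unconstrained dual is maximized by Newton's method.
#'
#' @param cov a (K+r)-dimensional [cov_seq()] with lags `0..p`.
#' @param sp a [sparsity_pattern()] on the `K` manifest variables.
#' @param K,r manifest and latent block sizes.
#' @param control list with `gtol` (default 1e-10) and `maxit` (default 60).
#' @return An `"me_solution"`.
#' @export
solve_me3 <- function(cov, sp, K, r, control = list()) {
  m <- cov$dim
  if (K + r != m) stop("K + r must equal the covariance dimension")
  if (sp$k != K) stop("pattern size does not match K")
  p <- cov$q
  ctl <- utils::modifyList(list(gtol = 1e-10, maxit = 60), control)
  M <- block_toeplitz(cov)
  if (is.null(tryCatch(chol(M), error = function(e) NULL)))
    stop("solver failure: block-Toeplitz covariance matrix is not ",
         "positive definite")
  lat <- .latent_basis(K, r, p, m)
  basis <- lat$basis
  b <- lat$b
  zero_cells <- which(lower.tri(sp$adjacency) & !sp$adjacency,
                      arr.ind = TRUE)
  for (e in seq_len(nrow(zero_cells))) {
    a <- zero_cells[e, 1]; bb <- zero_cells[e, 2]
    basis <- c(basis, list(.basis_entry(a, bb, 0, m, p)))
    b <- c(b, 0)
    if (p >= 1) {
      for (i in seq_len(p)) {
        basis <- c(basis, list(.basis_entry(a, bb, i, m, p),
                               .basis_entry(bb, a, i, m, p)))
        b <- c(b, 0, 0)
      }
    }
  }
  fl <- .basis_flatten(basis, nrow(M))
  res <- tryCatch(
    .dual_newton(M, fl, b, m, rep(0, fl$nvar), gtol = ctl$gtol,
                 maxit = ctl$maxit),
    error = function(e) stop("solver failure: ", conditionMessage(e)))
  xs <- .dual_primal(res$ev, m)
  .me_solution(xs, m, p, K, r, M, lam = 0, dual = res$value,
               iterations = res$iterations, status = res$status,
               theta = res$theta)
}

# repair a covariance sequence whose block-Toeplitz embedding lost positive
# definiteness to EM truncation: push the lag-0 block up by the violated
# amount (smallest eigenvalue plus a margin); returns cov with attribute
# "pd_shift" recording the shift applied (0 when untouched)
.ensure_pd_toeplitz <- function(cov, margin = 1e-8) {
  M <- block_toeplitz(cov)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  shift <- 0
  if (min(ev) < margin * max(abs(ev))) {
    shift <- abs(min(ev)) + margin * max(abs(ev))
    cov$lags[[1]] <- cov$lags[[1]] + shift * diag(cov$dim)
  }
  attr(cov, "pd_shift") <- shift
  cov
}
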