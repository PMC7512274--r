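#' Autocovariance sequences
#'
#' A light container for matrix covariance lags \eqn{C_0, ..., C_q}.
#' Negative lags are implied through \eqn{C_{-i} = C_i^\top} and available
#' via [cov_lag()].
#'
#' @param lags list of square matrices, lag 0 first.
#' @return An object of class `"cov_seq"`.
#' @export
cov_seq <- function(lags) {
  stopifnot(is.list(lags), length(lags) >= 1)
  lags <- lapply(lags, as.matrix)
  m <- nrow(lags[[1]])
  for (l in lags) if (!all(dim(l) == c(m, m))) stop("ragged lag matrices")
  structure(list(lags = lags, dim = m, q = length(lags) - 1L),
            class = "cov_seq")
}

#' @export
print.cov_seq <- function(x, ...) {
  cat("covariance sequence: dimension ", x$dim, ", lags 0..", x$q, "\n",
      sep = "")
  invisible(x)
}

#' @rdname cov_seq
#' @param cov a `"cov_seq"`.
#' @param i lag index, possibly negative.
#' @export
cov_lag <- function(cov, i) {
  if (abs(i) > cov$q) stop("lag ", i, " not available")
  if (i >= 0) cov$lags[[i + 1]] else t(cov$lags[[-i + 1]])
}

#' Biased sample autocovariances of a time series
#'
#' Computes \eqn{\hat C_i = T^{-1} \sum_{t=1}^{T-i} x_{t+i} x_t^\top} for
#' `i = 0..p`. The divisor is `T` for every lag (the biased estimator), which
#' keeps the block-Toeplitz embedding of the sequence positive semidefinite.
#'
#' @param x numeric matrix, `T` rows by `K` columns.
#' @param p largest lag.
#' @return A [cov_seq()] with lags `0..p`.
#' @examples
#' x <- rbind(c(1, 0), c(0, 1))
#' sample_covariances(x, 1)$lags[[2]]
#' @export
sample_covariances <- function(x, p) {
  x <- as.matrix(x)
  tt <- nrow(x)
  if (p >= tt) stop("need more rows than lags (T = ", tt, ", p = ", p, ")")
  lags <- vector("list", p + 1)
  lags[[1]] <- crossprod(x) / tt
  lags[[1]] <- (lags[[1]] + t(lags[[1]])) / 2
  if (p >= 1) {
    for (i in seq_len(p)) {
      lags[[i + 1]] <-
        crossprod(x[(1 + i):tt, , drop = FALSE],
                  x[seq_len(tt - i), , drop = FALSE]) / tt
    }
  }
  cov_seq(lags)
}

#' Block-Toeplitz embedding of a covariance sequence
#'
#' Builds the symmetric `(q+1)m` by `(q+1)m` matrix whose block `(h, k)` is
#' `C_{k-h}` for `k >= h` and `C_{h-k}^T` otherwise. For the exact
#' covariances of a stationary process this matrix is positive semidefinite.
#'
#' @param cov a [cov_seq()].
#' @return A symmetric matrix.
#' @export
block_toeplitz <- function(cov) {
  m <- cov$dim
  q <- cov$q
  out <- matrix(0, m * (q + 1), m * (q + 1))
  for (h in 0:q) {
    for (k in 0:q) {
      out[h * m + seq_len(m), k * m + seq_len(m)] <- cov_lag(cov, k - h)
    }
  }
  (out + t(out)) / 2
}

#' Block trace of a block matrix
#'
#' For a square matrix partitioned in `block` by `block` blocks, returns
#' \eqn{D_i(M) = \sum_{h=0}^{q-i} M_{h, h+i}}, the sum of the blocks along
#' the `i`-th block super-diagonal. Negative offsets obey
#' \eqn{D_{-i}(M) = D_i(M)^\top} for symmetric `M`; callers take the
#' transpose.
#'
#' @param m square matrix with side divisible by `block`.
#' @param i block offset, `0 <= i <=` number of block rows minus one.
#' @param block block size.
#' @return A `block` by `block` matrix.
#' @export
block_trace <- function(m, i, block) {
  n <- nrow(m)
  if (n %% block != 0) stop("matrix side not divisible by block size")
  nb <- n %/% block
  if (i < 0 || i > nb - 1) stop("offset ", i, " out of range 0..", nb - 1)
  out <- matrix(0, block, block)
  for (h in 0:(nb - 1 - i)) {
    out <- out + m[h * block + seq_len(block),
                   (h + i) * block + seq_len(block)]
  }
  out
}

# all block traces 0..nb-1 at once (hot path helper)
block_traces <- function(m, block) {
  nb <- nrow(m) %/% block
  lapply(0:(nb - 1), function(i) block_trace(m, i, block))
}
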