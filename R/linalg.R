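# Numerical kernels: complex matrix exponential, adaptive quadrature of
# complex vector/matrix-valued integrands, and the (confluent)
# Vandermonde solve behind the Cayley-Hamilton representation of a
# matrix exponential with polynomial entries.

# Matrix exponential by scaling-and-squaring with a [6/6] Pade
# approximant; works for real and complex square matrices.  Base R has
# no expm and the dependency tier used here keeps the kernel local.
cexpm <- function(A) {
  stopifnot(nrow(A) == ncol(A))
  n <- nrow(A)
  if (n == 1L) return(matrix(exp(A[1L, 1L]), 1L, 1L))
  nrmA <- max(rowSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin)) + 1))
  As <- A / 2^j
  # Pade [6/6]
  c6 <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(1 + 0i * As[1L], n)
  A2 <- As %*% As
  U <- As %*% (c6[2] * I + c6[4] * A2 + c6[6] * A2 %*% A2)
  V <- c6[1] * I + c6[3] * A2 + c6[5] * A2 %*% A2 + c6[7] * A2 %*% A2 %*% A2
  E <- solve(V - U, V + U)
  for (k in seq_len(j)) E <- E %*% E
  if (is.numeric(A)) E <- Re(E)
  E
}

# Adaptive Simpson quadrature for an integrand f(t) returning a numeric
# or complex vector (or matrix flattened by the caller).  Tolerances
# follow the tight settings used for all PGF work.
quad_vec <- function(f, a, b, atol = 1e-12, rtol = 1e-10, max_depth = 30L) {
  simpson <- function(fa, fm, fb, h) h / 6 * (fa + 4 * fm + fb)
  rec <- function(a, b, fa, fm, fb, whole, depth) {
    m <- (a + b) / 2
    fl <- f((a + m) / 2); fr <- f((m + b) / 2)
    left <- simpson(fa, fl, fm, m - a)
    right <- simpson(fm, fr, fb, b - m)
    err <- max(abs(left + right - whole))
    if (depth <= 0L ||
        err < 15 * max(atol, rtol * max(abs(left + right))))
      return(left + right + (left + right - whole) / 15)
    rec(a, m, fa, fl, fm, left, depth - 1L) +
      rec(m, b, fm, fr, fb, right, depth - 1L)
  }
  if (a == b) return(f(a) * 0)
  fa <- f(a); fm <- f((a + b) / 2); fb <- f(b)
  rec(a, b, fa, fm, fb, simpson(fa, fm, fb, b - a), max_depth)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch); used where the
# integrand is a polynomial-coefficient array and adaptivity is
# unnecessary because the coefficients are smooth exponentials in time.
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# Solve for the Cayley-Hamilton coefficients alpha_k in
#   exp(mu_i) = sum_k alpha_k mu_i^k ,
# clustering repeated eigenvalues and replacing duplicate rows by
# derivative equations (d^r/dmu^r of both sides), which keeps the solve
# well-posed for defective spectra.
ch_alpha <- function(mu, tol = 1e-8) {
  n <- length(mu)
  used <- rep(FALSE, n)
  rows <- matrix(0 + 0i, n, n)
  rhs <- complex(n)
  r <- 0L
  for (i in seq_len(n)) {
    if (used[i]) next
    cl <- which(!used & abs(mu - mu[i]) < tol * max(1, abs(mu[i])))
    used[cl] <- TRUE
    m <- mean(mu[cl])
    for (d in seq_along(cl) - 1L) {        # derivative order d
      r <- r + 1L
      for (k in seq_len(n) - 1L) {
        rows[r, k + 1L] <- if (k >= d)
          prod(seq.int(k, by = -1, length.out = d)) * m^(k - d) else 0
      }
      rhs[r] <- exp(m)
    }
  }
  as.vector(solve(rows, rhs))
}
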