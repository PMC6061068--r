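# Light polynomial arithmetic used by the symbolic layer.
#
# A univariate polynomial is a plain coefficient vector c(p0, p1, ...)
# (possibly complex).  A bivariate polynomial in (lambda, s) is a matrix
# B with B[i + 1, j + 1] = coefficient of lambda^i s^j.  These carry the
# structural bookkeeping for the characteristic Jacobian: whether a
# coefficient depends on the probing variable s_X is a degree question,
# so all that is required is exact-as-entered add/multiply on small
# coefficient arrays.

p_trim <- function(p, tol = 0) {
  n <- length(p)
  while (n > 1L && abs(p[n]) <= tol) n <- n - 1L
  p[seq_len(n)]
}

p_add <- function(a, b) {
  n <- max(length(a), length(b))
  r <- numeric(n) * (0 + 0i)
  if (is.numeric(a) && is.numeric(b)) r <- numeric(n)
  r[seq_along(a)] <- r[seq_along(a)] + a
  r[seq_along(b)] <- r[seq_along(b)] + b
  r
}

p_mul <- function(a, b) {
  r <- rep(if (is.complex(a) || is.complex(b)) 0 + 0i else 0,
           length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    r[idx] <- r[idx] + a[i] * b
  }
  r
}

p_pow <- function(a, n) {
  stopifnot(n >= 0L)
  r <- if (is.complex(a)) 1 + 0i else 1
  while (n > 0L) {
    r <- p_mul(r, a)
    n <- n - 1L
  }
  r
}

p_eval <- function(p, x) {
  r <- p[length(p)]
  if (length(p) > 1L)
    for (i in (length(p) - 1L):1L) r <- r * x + p[i]
  r + x * 0  # promote to complex if x is
}

# degree with a relative tolerance: coefficients that are numerically
# zero relative to the largest one do not count
p_deg <- function(p, rtol = 1e-9) {
  m <- max(abs(p))
  if (m == 0) return(0L)
  idx <- which(abs(p) > rtol * m)
  max(idx) - 1L
}

## ---- bivariate (lambda, s) ----

bp_const <- function(x) matrix(x, 1L, 1L)

bp_pad <- function(B, nr, nc) {
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(B)), seq_len(ncol(B))] <- B
  out
}

bp_add <- function(A, B) {
  nr <- max(nrow(A), nrow(B)); nc <- max(ncol(A), ncol(B))
  bp_pad(A, nr, nc) + bp_pad(B, nr, nc)
}

bp_mul <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B) - 1L, ncol(A) + ncol(B) - 1L)
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (A[i, j] == 0) next
    ri <- i:(i + nrow(B) - 1L); rj <- j:(j + ncol(B) - 1L)
    out[ri, rj] <- out[ri, rj] + A[i, j] * B
  }
  out
}

bp_neg <- function(A) -A

bp_trim <- function(A, tol = 0) {
  nr <- nrow(A); nc <- ncol(A)
  while (nr > 1L && all(abs(A[nr, ]) <= tol)) nr <- nr - 1L
  while (nc > 1L && all(abs(A[seq_len(nr), nc]) <= tol)) nc <- nc - 1L
  A[seq_len(nr), seq_len(nc), drop = FALSE]
}

# determinant of a square matrix whose entries are bivariate polynomials,
# stored as a list-matrix; cofactor expansion (independent parts are tiny)
bp_det <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M[[1L, 1L]])
  acc <- bp_const(0)
  for (j in seq_len(n)) {
    piv <- M[[1L, j]]
    if (all(piv == 0)) next
    minor <- M[-1L, -j, drop = FALSE]
    term <- bp_mul(piv, bp_det(minor))
    if (j %% 2L == 0L) term <- bp_neg(term)
    acc <- bp_add(acc, term)
  }
  acc
}
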