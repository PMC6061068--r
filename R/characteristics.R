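#' Characteristic ODE system of the generating-function PDE
#'
#' The first-order PDE for the joint PGF of a hierarchic network is
#' solved along characteristic curves.  The dependent (system II)
#' coordinates obey the autonomous linear system
#' \code{ds_dep/dt = -A' (s_dep - 1)} with the exact solution
#' \code{s_dep(t') = 1 + exp(-A'(t' - t)) (s_dep(t) - 1)}.  The
#' independent coordinates obey \code{ds_ind/dt = J s_ind + f}, where
#' the Jacobian \code{J} and inhomogeneity \code{f} are built from the
#' factors \code{c_i(s_dep, t', t)}, the dependent-product monomials
#' propagated along the dependent characteristics:
#' \deqn{J_{pq} = \sum_i Q_{pi} k_i (\delta_{pq} - c_i R_{qi}), \quad
#'       f_j = -\sum_{i: \mathrm{no\ ind.\ product}} Q_{ji} k_i c_i.}
#' The influx reactions contribute the factor
#' \code{exp(int_0^t b.(s(tau)-1) dtau)} to the PGF.
#'
#' @param decomp a \code{\link{decompose_hierarchic}} result.
#' @return an object of class \code{characteristic_system} with
#'   callable \code{J(s_dep, tp, t)}, \code{f(s_dep, tp, t)},
#'   \code{c_factors(s_dep, tp, t)}, \code{rhs_ind(s_ind, s_dep)},
#'   \code{sdep_at(s_dep, tau, t)} and the flag \code{commuting_J}.
#' @export
build_characteristics <- function(decomp) {
  net <- decomp$net
  ind <- decomp$ind_idx; dep <- decomp$dep_idx
  A <- decomp$A
  At <- t(A)
  n_ind <- decomp$n_ind; n_dep <- decomp$n_dep
  Rdep <- net$R[dep, , drop = FALSE]
  Rind <- net$R[ind, , drop = FALSE]
  Qind <- net$Q[ind, , drop = FALSE]
  has_ind_prod <- if (n_ind) colSums(Rind) > 0 else rep(FALSE, net$m)

  # dependent characteristic at time tau, given terminal value at time t
  sdep_at <- function(s_dep, tau, t) {
    if (!n_dep) return(s_dep)
    as.vector(1 + cexpm(-At * (tau - t)) %*% (s_dep - 1))
  }

  c_factors <- function(s_dep, tp, t) {
    sd <- sdep_at(s_dep, tp, t)
    vapply(seq_len(net$m), function(i) {
      r <- Rdep[, i]
      if (!n_dep || !any(r > 0)) return(1 + 0i)
      prod(sd^r)
    }, complex(1))
  }

  Jfun <- function(s_dep, tp, t) {
    ci <- c_factors(s_dep, tp, t)
    J <- matrix(0 + 0i, n_ind, n_ind)
    for (i in seq_len(net$m)) {
      p <- which(Qind[, i] > 0)
      if (!length(p)) next
      for (q in seq_len(n_ind))
        J[p, q] <- J[p, q] + net$k[i] * ((p == q) - ci[i] * Rind[q, i])
    }
    J
  }

  ffun <- function(s_dep, tp, t) {
    ci <- c_factors(s_dep, tp, t)
    f <- complex(n_ind)
    for (i in seq_len(net$m)) {
      p <- which(Qind[, i] > 0)
      if (!length(p) || has_ind_prod[i]) next
      f[p] <- f[p] - net$k[i] * ci[i]
    }
    f
  }

  # direct right-hand side of the independent characteristics at the
  # current point (s_ind, s_dep); equals J s_ind + f by construction
  rhs_ind <- function(s_ind, s_dep) {
    ds <- complex(n_ind)
    for (i in seq_len(net$m)) {
      p <- which(Qind[, i] > 0)
      if (!length(p)) next
      ci <- if (n_dep && any(Rdep[, i] > 0)) prod(s_dep^Rdep[, i]) else 1
      lin <- sum(Rind[, i] * s_ind) + as.numeric(!has_ind_prod[i])
      ds[p] <- ds[p] - net$k[i] * (ci * lin - s_ind[p])
    }
    ds
  }

  commuting <- TRUE
  if (n_ind > 1L && n_dep > 0L) {
    # deterministic numeric probe: J at two times must commute for the
    # closed-form path; fixed probe points, no RNG involved
    probes <- list(c(0.31, 1.07), c(0.11, 0.73), c(0.57, 1.91),
                   c(0.23, 1.41), c(0.91, 1.63))
    sd_pts <- lapply(seq_len(3), function(r)
      0.3 + 0.5 * cos(r + seq_len(n_dep)) +
        0.35i * sin(2 * r + seq_len(n_dep)))
    for (pr in probes) for (sd in sd_pts) {
      J1 <- Jfun(sd, pr[1], 2); J2 <- Jfun(sd, pr[2], 2)
      comm <- J1 %*% J2 - J2 %*% J1
      scale <- max(1, max(abs(J1)) * max(abs(J2)))
      if (max(abs(comm)) > 1e-10 * scale) { commuting <- FALSE; break }
      if (!commuting) break
    }
  }

  structure(list(decomp = decomp, net = net,
                 J = Jfun, f = ffun, c_factors = c_factors,
                 rhs_ind = rhs_ind, sdep_at = sdep_at,
                 commuting_J = commuting),
            class = "characteristic_system")
}

#' @export
print.characteristic_system <- function(x, ...) {
  cat("Characteristic system:", x$decomp$n_ind, "independent,",
      x$decomp$n_dep, "dependent coordinates;",
      if (x$commuting_J) "commuting" else "non-commuting", "Jacobian\n")
  invisible(x)
}

# J as a matrix of polynomials in s_X (other dependent coordinates 1),
# with the dependent characteristic evaluated at time offset dt_off
# before t (dt_off = 0 gives the instantaneous Jacobian of Example-type
# calculations).  Entries are coefficient vectors.
jacobian_poly_matrix <- function(cs, X, dt_off = 0) {
  decomp <- cs$decomp; net <- cs$net
  dep <- decomp$dep_idx; ind <- decomp$ind_idx
  xj <- match(X, net$species[dep])
  if (is.na(xj)) stop("'", X, "' is not a dependent species")
  n_ind <- decomp$n_ind; n_dep <- decomp$n_dep
  # (s_dep(t'))_l = 1 + w_l (s_X - 1) with w = exp(-A'(t'-t)) e_X
  w <- as.vector(cexpm(-t(decomp$A) * (-dt_off))[, xj])
  Rdep <- net$R[dep, , drop = FALSE]
  Rind <- net$R[ind, , drop = FALSE]
  Qind <- net$Q[ind, , drop = FALSE]
  cpoly <- lapply(seq_len(net$m), function(i) {
    p <- 1
    for (l in seq_len(n_dep)) if (Rdep[l, i] > 0)
      p <- p_mul(p, p_pow(c(1 - w[l], w[l]), Rdep[l, i]))
    p
  })
  J <- vector("list", n_ind * n_ind)
  dim(J) <- c(n_ind, n_ind)
  for (p in seq_len(n_ind)) for (q in seq_len(n_ind)) J[[p, q]] <- 0
  for (i in seq_len(net$m)) {
    p <- which(Qind[, i] > 0)
    if (!length(p)) next
    for (q in seq_len(n_ind)) {
      term <- p_mul(cpoly[[i]], -net$k[i] * Rind[q, i])
      if (p == q) term <- p_add(term, net$k[i])
      J[[p, q]] <- p_add(J[[p, q]], term)
    }
  }
  J
}

#' Characteristic polynomial of the Jacobian as a bivariate polynomial
#'
#' Computes \code{det(lambda I - J(s_X))} exactly from the coefficient
#' arithmetic of the Jacobian entries, with all dependent coordinates
#' other than the probing species set to 1.  The result is the basis of
#' the eigenvalue-dependence test for conditional multimodality.
#'
#' @param cs a \code{\link{build_characteristics}} result.
#' @param X name of a dependent species.
#' @return an object of class \code{char_poly}: a coefficient matrix
#'   \code{B[i+1, j+1]} = coefficient of \code{lambda^i s_X^j}.
#' @examples
#' net <- parse_reactions(c("X -> Y + Z @ 7.0", "Y -> X @ 1.875"))
#' cp <- jacobian_charpoly(build_characteristics(decompose_hierarchic(net)), "Z")
#' cp$B
#' @export
jacobian_charpoly <- function(cs, X, dt_off = 0) {
  if (cs$decomp$n_ind == 0L)
    return(structure(list(B = matrix(1, 1, 1), species = X, n_ind = 0L),
                     class = "char_poly"))
  Jp <- jacobian_poly_matrix(cs, X, dt_off)
  n <- nrow(Jp)
  M <- vector("list", n * n); dim(M) <- c(n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    # lambda * delta_pq - J_pq as bivariate (rows lambda, cols s)
    B <- matrix(-Jp[[p, q]], nrow = 1)
    if (p == q) B <- bp_add(B, matrix(c(0, 1), nrow = 2, ncol = 1))
    M[[p, q]] <- B
  }
  B <- bp_trim(bp_det(M), tol = 0)
  structure(list(B = B, species = X, n_ind = n), class = "char_poly")
}

#' @export
print.char_poly <- function(x, ...) {
  terms <- character()
  for (i in seq_len(nrow(x$B))) for (j in seq_len(ncol(x$B))) {
    co <- x$B[i, j]
    if (co == 0) next
    t0 <- sprintf("%g", co)
    if (i > 1) t0 <- paste0(t0, "*lambda^", i - 1)
    if (j > 1) t0 <- paste0(t0, "*s^", j - 1)
    terms <- c(terms, t0)
  }
  cat("char poly in (lambda, s_", x$species, "): ",
      paste(terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Do the Jacobian eigenvalues depend on the probing variable?
#'
#' True iff some coefficient of the characteristic polynomial (viewed
#' as a polynomial in lambda) has positive degree in \code{s_X}.  This
#' is the structural criterion deciding between finite-order and
#' infinite-order generalized marginal distributions.
#'
#' @param cp a \code{\link{jacobian_charpoly}} result.
#' @return logical.
#' @export
eigen_depends <- function(cp) {
  B <- cp$B
  if (ncol(B) < 2L) return(FALSE)
  mx <- max(abs(B))
  any(abs(B[, -1L, drop = FALSE]) > 1e-12 * mx)
}
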