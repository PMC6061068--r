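#' Initial-distribution generating function
#'
#' Product over species of \code{s0^x0} (deterministic count) or
#' \code{exp(mean (s0 - 1))} (Poisson); mixed products are allowed.
#' Deterministic exponents are capped at 1e6 and powers of non-zero
#' bases are computed in log space to avoid overflow.
#'
#' @param ic a \code{\link{initial_condition}}.
#' @param s0 complex vector, ordered like \code{names(ic)}.
#' @return complex scalar.
#' @export
initial_pgf <- function(ic, s0) {
  if (length(s0) != length(ic)) stop("s0 has wrong length")
  g <- 1 + 0i
  for (i in seq_along(ic)) {
    e <- ic[[i]]
    if (e$type == "poisson") {
      g <- g * exp(e$mean * (s0[i] - 1))
    } else {
      x0 <- min(e$count, 1e6)
      if (x0 == 0) next
      if (s0[i] == 0) return(0 + 0i)
      g <- g * exp(x0 * log(s0[i]))
    }
  }
  g
}

# reorder an initial condition to a species ordering (names must match)
align_ic <- function(ic, species) {
  if (is.null(names(ic)) || !all(species %in% names(ic)))
    stop("initial condition must name every species: ",
         paste(species, collapse = ", "))
  structure(ic[match(species, names(ic))], class = "cme_ic")
}

pgf_handle <- function(evaluator, species, ic, method) {
  structure(list(eval = evaluator, species = species, ic = ic,
                 method = method), class = "pgf_handle")
}

#' @export
print.pgf_handle <- function(x, ...) {
  cat("PGF handle (", x$method, ") over species ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate the joint PGF by backward characteristic integration
#'
#' The general, always-valid path: the dependent coordinates follow
#' their exact linear solution, the independent coordinates are
#' integrated backward from the terminal value \code{s} at time
#' \code{t} with a complex-valued Adams solver (tolerances 1e-10 /
#' 1e-12), and the influx factor \code{exp(int_0^t b.(s(tau)-1) dtau)}
#' is accumulated alongside.  The result is the initial PGF evaluated
#' at the mapped-back point, times the influx factor.
#'
#' @param decomp a \code{\link{decompose_hierarchic}} result.
#' @param cs matching \code{\link{build_characteristics}} result.
#' @param ic a \code{\link{initial_condition}} ordered like the network
#'   species.
#' @param s complex vector (length n) in the closed unit polydisc.
#' @param t non-negative time.
#' @return complex scalar \code{g(s, t)}.
#' @export
evaluate_pgf <- function(decomp, cs, ic, s, t) {
  if (t < 0) stop("t must be >= 0")
  net <- decomp$net
  if (length(s) != net$n) stop("s has wrong length")
  ic <- align_ic(ic, net$species)
  s <- as.complex(s)
  if (t == 0) return(initial_pgf(ic, s))
  ind <- decomp$ind_idx; dep <- decomp$dep_idx
  s_dep <- s[dep]
  b_any <- any(decomp$b > 0)
  s0 <- complex(net$n)
  s0[dep] <- cs$sdep_at(s_dep, 0, t)
  influx <- 0 + 0i
  if (decomp$n_ind > 0L) {
    nI <- decomp$n_ind
    y0 <- c(s[ind], 0 + 0i)   # last slot: influx integral (from t down)
    deriv <- function(tau, y, parms) {
      sd <- cs$sdep_at(s_dep, tau, t)
      dy <- cs$rhs_ind(y[seq_len(nI)], sd)
      dinflux <- if (b_any) {
        full <- complex(net$n)
        full[ind] <- y[seq_len(nI)]; full[dep] <- sd
        sum(decomp$b * (full - 1))
      } else 0 + 0i
      list(c(dy, dinflux))
    }
    sol <- deSolve::zvode(y = y0, times = c(t, 0), func = deriv,
                          rtol = 1e-10, atol = 1e-12, mf = 10)
    if (attr(sol, "istate")[1] < 0)
      stop("characteristic ODE solver failed (rtol 1e-10, atol 1e-12)")
    yT <- unname(sol[nrow(sol), -1])
    s0[ind] <- yT[seq_len(nI)]
    influx <- -yT[nI + 1L]    # integrated from t to 0, so negate
  } else if (b_any) {
    influx <- quad_vec(function(tau) {
      full <- complex(net$n)
      full[dep] <- cs$sdep_at(s_dep, tau, t)
      sum(decomp$b * (full - 1))
    }, 0, t)
  }
  initial_pgf(ic, s0) * exp(influx)
}

#' Closed-form PGF via matrix exponentials (commuting Jacobian, b = 0)
#'
#' Implements the explicit solution
#' \code{s0_ind = exp(-M(t)) s_ind - v(t)} with
#' \code{M(t) = int_0^t J dt'} and
#' \code{v(t) = int_0^t exp(-M(t')) f(t') dt'}, all time integrals by
#' adaptive quadrature of matrix-valued integrands; an independently
#' coded second path used to cross-validate the numeric characteristic
#' integration.
#'
#' @inheritParams evaluate_pgf
#' @return a \code{pgf_handle} whose evaluator takes \code{(s, t)}.
#' @export
closed_form_pgf <- function(decomp, cs, ic) {
  if (any(decomp$b > 0))
    stop("closed form requires b = 0 (no influx reactions); ",
         "use evaluate_pgf")
  if (!cs$commuting_J)
    stop("closed form requires a commuting Jacobian; use evaluate_pgf")
  net <- decomp$net
  ic <- align_ic(ic, net$species)
  ind <- decomp$ind_idx; dep <- decomp$dep_idx
  nI <- decomp$n_ind
  # J and f are time-independent iff system II has no internal dynamics
  J_static <- decomp$n_dep == 0L || all(decomp$A == 0)
  evaluator <- function(s, t) {
    s <- as.complex(s)
    if (t < 0) stop("t must be >= 0")
    if (t == 0) return(initial_pgf(ic, s))
    s_dep <- s[dep]
    s0 <- complex(net$n)
    s0[dep] <- cs$sdep_at(s_dep, 0, t)
    if (nI > 0L) {
      if (J_static) {
        J0 <- cs$J(s_dep, t, t)
        f0 <- cs$f(s_dep, t, t)
        M <- J0 * t
        v <- if (any(f0 != 0))
          as.vector(quad_vec(function(u)
            as.vector(cexpm(-J0 * u) %*% f0), 0, t))
        else complex(nI)
      } else {
        Mof <- function(tp) {
          m <- quad_vec(function(u) as.vector(cs$J(s_dep, u, t)), 0, tp)
          matrix(m, nI, nI)
        }
        M <- Mof(t)
        v <- as.vector(quad_vec(function(tp)
          as.vector(cexpm(-Mof(tp)) %*% cs$f(s_dep, tp, t)), 0, t,
          atol = 1e-11, rtol = 1e-9))
      }
      s0[ind] <- as.vector(cexpm(-M) %*% s[ind]) - v
    }
    initial_pgf(ic, s0)
  }
  pgf_handle(evaluator, net$species, ic, "closed-form-commuting")
}

#' Marginal PGF of one species
#'
#' Fixes all coordinates except \code{X} at 1.
#'
#' @param h a \code{pgf_handle} (or any function of \code{(s, t)}).
#' @param X species name.
#' @param t time at which the marginal is taken.
#' @return univariate function \code{u -> g((1,...,u,...,1), t)}.
#' @export
marginal_pgf <- function(h, X, t) {
  ev <- if (inherits(h, "pgf_handle")) h$eval else h
  species <- if (inherits(h, "pgf_handle")) h$species else
    stop("need a pgf_handle to resolve species names")
  i <- match(X, species)
  if (is.na(i)) stop("unknown species '", X, "'")
  n <- length(species)
  batch <- if (inherits(h, "pgf_handle")) h$eval_batch else NULL
  function(u) {
    if (length(u) > 1L) {
      if (!is.null(batch)) {
        S <- matrix(1 + 0i, n, length(u))
        S[i, ] <- u
        return(batch(S, t))
      }
      return(vapply(u, function(ui) {
        s <- rep(1 + 0i, n); s[i] <- ui; ev(s, t)
      }, complex(1)))
    }
    s <- rep(1 + 0i, n)
    s[i] <- u
    ev(s, t)
  }
}

# convenience: pgf_handle for the general numeric path; carries a batch
# evaluator that integrates the characteristics of many terminal points
# in a single solver call (the curves are independent, so they stack)
numeric_pgf <- function(decomp, cs, ic) {
  h <- pgf_handle(function(s, t) evaluate_pgf(decomp, cs, ic, s, t),
                  decomp$net$species, ic, "numeric-characteristics")
  h$eval_batch <- function(S, t) evaluate_pgf_batch(decomp, cs, ic, S, t)
  h
}

# S: n x M matrix of terminal points, one column per PGF evaluation
evaluate_pgf_batch <- function(decomp, cs, ic, S, t) {
  net <- decomp$net
  ic <- align_ic(ic, net$species)
  if (t < 0) stop("t must be >= 0")
  M <- ncol(S)
  ind <- decomp$ind_idx; dep <- decomp$dep_idx
  nI <- decomp$n_ind; nD <- decomp$n_dep
  At <- t(decomp$A)
  Sdep <- matrix(S[dep, , drop = FALSE] - 1, nD, M)
  sdep_batch <- function(tau) {
    if (!nD) return(matrix(0 + 0i, 0, M))
    1 + cexpm(-At * (tau - t)) %*% Sdep
  }
  Rdep <- net$R[dep, , drop = FALSE]
  Rind <- net$R[ind, , drop = FALSE]
  Qind <- net$Q[ind, , drop = FALSE]
  has_ind_prod <- if (nI) colSums(Rind) > 0 else rep(FALSE, net$m)
  b_any <- any(decomp$b > 0)
  s0 <- S
  influx <- complex(M)
  if (t > 0 && nI > 0L) {
    y0 <- c(as.vector(S[ind, , drop = FALSE]), complex(M))
    deriv <- function(tau, y, parms) {
      Sind <- matrix(y[seq_len(nI * M)], nI, M)
      sd <- sdep_batch(tau)
      dS <- matrix(0 + 0i, nI, M)
      for (i in seq_len(net$m)) {
        p <- which(Qind[, i] > 0)
        if (!length(p)) next
        ci <- rep(1 + 0i, M)
        for (l in which(Rdep[, i] > 0)) ci <- ci * sd[l, ]^Rdep[l, i]
        lin <- if (has_ind_prod[i])
          as.vector(Rind[, i] %*% Sind) else rep(1 + 0i, M)
        dS[p, ] <- dS[p, ] - net$k[i] * (ci * lin - Sind[p, ])
      }
      dinf <- if (b_any) {
        acc <- complex(M)
        for (j in seq_len(net$n)) {
          if (decomp$b[j] == 0) next
          row <- if (j %in% ind) Sind[match(j, ind), ] else
            sd[match(j, dep), ]
          acc <- acc + decomp$b[j] * (row - 1)
        }
        acc
      } else complex(M)
      list(c(as.vector(dS), dinf))
    }
    sol <- deSolve::zvode(y = y0, times = c(t, 0), func = deriv,
                          rtol = 1e-10, atol = 1e-12, mf = 10)
    if (attr(sol, "istate")[1] < 0)
      stop("characteristic ODE solver failed (rtol 1e-10, atol 1e-12)")
    yT <- unname(sol[nrow(sol), -1])
    s0[ind, ] <- matrix(yT[seq_len(nI * M)], nI, M)
    influx <- -yT[nI * M + seq_len(M)]
  } else if (t > 0 && b_any) {
    influx <- quad_vec(function(tau) {
      sd <- sdep_batch(tau)
      acc <- complex(M)
      for (j in which(decomp$b > 0))
        acc <- acc + decomp$b[j] * (sd[match(j, dep), ] - 1)
      acc
    }, 0, t)
  }
  if (t > 0 && nD) s0[dep, ] <- sdep_batch(0)
  g <- rep(1 + 0i, M)
  for (i in seq_len(net$n)) {
    e <- ic[[i]]
    if (e$type == "poisson") {
      g <- g * exp(e$mean * (s0[i, ] - 1))
    } else if (e$count > 0) {
      g <- g * s0[i, ]^min(e$count, 1e6)
    }
  }
  g * exp(influx)
}

#' Decay-chain network with emitted particles
#'
#' Builds the reaction network \code{X_i -> X_{i+1} + sum_p R[i,p] P_p}
#' for a linear decay chain of \code{n} isotopes emitting particle
#' species \code{P_p} (the columns of \code{particles}).
#'
#' @param k decay rates \code{k_1..k_{n-1}} of the first \code{n-1}
#'   isotopes.
#' @param particles (n-1) x p matrix of non-negative integer particle
#'   stoichiometries; column names give the particle species names.
#' @return a \code{reaction_network} with species
#'   \code{X1..Xn, <particles>}.
#' @export
bateman_chain <- function(k, particles) {
  particles <- as.matrix(particles)
  nsteps <- length(k)
  if (nrow(particles) != nsteps)
    stop("particles must have one row per decay step")
  pn <- colnames(particles)
  if (is.null(pn)) pn <- paste0("P", seq_len(ncol(particles)))
  iso <- paste0("X", seq_len(nsteps + 1L))
  lines <- vapply(seq_len(nsteps), function(i) {
    rhs <- iso[i + 1L]
    for (p in seq_along(pn)) if (particles[i, p] > 0)
      rhs <- paste(rhs, "+", if (particles[i, p] == 1) pn[p] else
        paste(particles[i, p], pn[p]))
    sprintf("%s -> %s @ %.17g", iso[i], rhs, k[i])
  }, character(1))
  parse_reactions(lines)
}

#' Explicit PGF for a decay chain with emitted particles
#'
#' The chain solution in partial-fraction form: with distinct rates the
#' backward-mapped isotope coordinate is
#' \deqn{s^0_i = <x_i>_0-free form; see Details.}
#' For Poisson initial means \code{<x>_0} the PGF is
#' \code{exp(<x_part>_0.(s_part - 1) + sum_i E_i(s_part, t) s_i -
#' sum_i <x_i>_0)} where \code{E_i} carries the factors
#' \code{prod_l k_l s^R} and the sums \code{sum_l exp(-k_l t) /
#' prod_{j != l}(k_j - k_l)}.
#'
#' @param k decay rates \code{k_1..k_{n-1}} (must be distinct; repeated
#'   rates fall back to \code{\link{evaluate_pgf}} with a warning).
#' @param particles stoichiometry matrix as in
#'   \code{\link{bateman_chain}}.
#' @param ic a \code{\link{initial_condition}} ordered like the
#'   \code{bateman_chain} species (isotopes first, Poisson means).
#' @return a \code{pgf_handle}.
#' @export
bateman_pgf <- function(k, particles, ic) {
  net <- bateman_chain(k, particles)
  nsteps <- length(k)
  n_iso <- nsteps + 1L
  particles <- as.matrix(particles)
  if (is.null(colnames(particles)))
    colnames(particles) <- paste0("P", seq_len(ncol(particles)))
  # particles that are never emitted do not enter the network
  particles <- particles[, colSums(particles) > 0, drop = FALSE]
  pn <- ncol(particles)
  kfull <- c(k, 0)          # terminal isotope does not decay
  if (anyDuplicated(signif(kfull, 12))) {
    warning("repeated decay rates: partial-fraction form invalid, ",
            "falling back to numeric characteristics")
    decomp <- decompose_hierarchic(net)
    return(numeric_pgf(decomp, build_characteristics(decomp), ic))
  }
  ic <- align_ic(ic, net$species)
  iso_idx <- match(paste0("X", seq_len(n_iso)), net$species)
  part_idx <- match(colnames(particles), net$species)
  get_mean <- function(i) {
    e <- ic[[i]]
    if (e$type != "poisson")
      stop("bateman_pgf assumes Poisson initial means")
    e$mean
  }
  means <- vapply(iso_idx, get_mean, numeric(1))
  evaluator <- function(s, t) {
    s <- as.complex(s)
    s_iso <- s[iso_idx]
    s_part <- s[part_idx]
    g <- 0 + 0i
    # particle initial means
    for (p in seq_len(pn)) g <- g + get_mean(part_idx[p]) * (s_part[p] - 1)
    for (i in seq_len(n_iso)) {
      Ei <- means[i] * exp(-kfull[i] * t)
      if (i > 1) for (m in seq_len(i - 1L)) {
        fac <- means[m]
        for (l in m:(i - 1L))
          fac <- fac * k[l] * prod(s_part^particles[l, ])
        ssum <- 0 + 0i
        for (l in m:i) {
          den <- prod(kfull[setdiff(m:i, l)] - kfull[l])
          ssum <- ssum + exp(-kfull[l] * t) / den
        }
        Ei <- Ei + fac * ssum
      }
      g <- g + Ei * s_iso[i] - means[i]
    }
    exp(g)
  }
  pgf_handle(evaluator, net$species, ic, "named-closed-form")
}
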