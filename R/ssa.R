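#' Exact stochastic simulation (Gillespie direct method)
#'
#' Samples one exact realization of the Markov jump process underlying
#' the CME: exponential waiting times with the total propensity,
#' reaction chosen proportionally to its propensity.  Poisson initial
#' conditions are sampled per species before simulation.
#'
#' @param net a \code{reaction_network}.
#' @param x0 integer state vector, or a \code{\link{initial_condition}}.
#' @param t_end simulation horizon (>= 0).
#' @param seed RNG seed (integer).
#' @return object of class \code{ssa_trajectory}: \code{times}
#'   (event times, starting at 0), \code{states} (matrix, one row per
#'   event), \code{seed}.
#' @export
simulate_ssa <- function(net, x0, t_end, seed = 1L) {
  if (t_end < 0) stop("t_end must be >= 0")
  if (!is.finite(seed) || seed != round(seed)) stop("invalid seed")
  set.seed(as.integer(seed))
  if (inherits(x0, "cme_ic")) x0 <- sample_ic(x0, net$species)
  if (length(x0) != net$n || any(x0 < 0) || any(x0 != round(x0)))
    stop("x0 must be a non-negative integer state of length ", net$n)
  Qi <- net$Q; Ri <- net$R
  storage.mode(Qi) <- "integer"; storage.mode(Ri) <- "integer"
  tr <- ssa_trajectory_cpp(Qi, Ri, net$k, as.integer(x0), t_end)
  colnames(tr$states) <- net$species
  structure(list(times = tr$times, states = tr$states, seed = seed,
                 species = net$species), class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("SSA trajectory:", length(x$times) - 1L, "events, final state (",
      paste(x$states[nrow(x$states), ], collapse = ", "), ")\n")
  invisible(x)
}

#' Write a trajectory as TSV (time, one column per species)
#' @param tr an \code{ssa_trajectory}.
#' @param path output path.
#' @export
write_trajectory <- function(tr, path) {
  df <- data.frame(time = tr$times, tr$states, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sample_ic <- function(ic, species) {
  ic <- align_ic(ic, species)
  vapply(seq_along(ic), function(i) {
    e <- ic[[i]]
    if (e$type == "det") as.integer(e$count) else
      stats::rpois(1L, e$mean)
  }, integer(1))
}

#' End states of an SSA ensemble
#'
#' Runs \code{runs} independent trajectories to \code{t_end} and
#' returns only the final states (single sampling time per run, keeping
#' the samples i.i.d.).
#'
#' @inheritParams simulate_ssa
#' @param runs ensemble size.
#' @return integer matrix \code{runs x n}, columns named by species.
#' @export
ssa_endstates <- function(net, x0, t_end, runs, seed = 1L) {
  if (!is.finite(seed) || seed != round(seed)) stop("invalid seed")
  set.seed(as.integer(seed))
  x0m <- if (inherits(x0, "cme_ic")) {
    ic <- align_ic(x0, net$species)
    m <- matrix(0L, runs, net$n)
    for (i in seq_along(ic)) {
      e <- ic[[i]]
      m[, i] <- if (e$type == "det") as.integer(e$count) else
        stats::rpois(runs, e$mean)
    }
    m
  } else {
    if (length(x0) != net$n) stop("x0 has wrong length")
    matrix(as.integer(x0), runs, net$n, byrow = TRUE)
  }
  Qi <- net$Q; Ri <- net$R
  storage.mode(Qi) <- "integer"; storage.mode(Ri) <- "integer"
  out <- ssa_endstates_cpp(Qi, Ri, net$k, x0m, t_end)
  colnames(out) <- net$species
  out
}

#' Empirical pmf of one species from ensemble end states
#'
#' Normalized histogram with per-bin Monte-Carlo standard errors
#' \code{sqrt(p (1 - p) / n)}; the pmf noise floor is set to the
#' largest standard error so that mode detection tolerances account
#' for sampling noise.
#'
#' @param endstates matrix from \code{\link{ssa_endstates}}.
#' @param X species name or column index.
#' @return a \code{\link{cme_pmf}} with the \code{se} field set.
#' @export
empirical_pmf <- function(endstates, X) {
  if (!nrow(endstates)) stop("empty ensemble")
  x <- endstates[, X]
  n <- length(x)
  N <- max(x)
  p <- tabulate(x + 1L, nbins = N + 1L) / n
  se <- sqrt(p * (1 - p) / n)
  cme_pmf(p, deficit = 0, noise = max(se) / max(p), se = se)
}

#' Total variation distance between two pmfs
#'
#' \code{0.5 * sum |p_n - q_n|} over the union support.
#'
#' @param p,q \code{\link{cme_pmf}} objects (or bare probability
#'   vectors).
#' @return number in [0, 1] (up to truncation deficits).
#' @export
total_variation <- function(p, q) {
  pv <- if (inherits(p, "cme_pmf")) p$p else p
  qv <- if (inherits(q, "cme_pmf")) q$p else q
  n <- max(length(pv), length(qv))
  pv <- c(pv, numeric(n - length(pv)))
  qv <- c(qv, numeric(n - length(qv)))
  0.5 * sum(abs(pv - qv))
}
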