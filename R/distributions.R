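#' Discrete compound Poisson pmf (DCP^N)
#'
#' Distribution with PGF \code{exp(sum_i lambda alpha_i (s^i - 1))};
#' the order N is the highest index with positive weight.  Computed by
#' the standard compound-Poisson recursion
#' \code{p_0 = exp(-lambda)},
#' \code{p_n = (1/n) sum_i i lambda alpha_i p_{n-i}}.
#'
#' @param lambda positive rate of the generalized Poisson.
#' @param alpha weights \code{alpha_1..alpha_N}, in [0,1], summing to 1.
#' @param N_trunc truncation of the returned pmf.
#' @return a \code{\link{cme_pmf}}.
#' @examples
#' dcp_pmf(2, 1, 20)$p[1:3]   # Poisson(2)
#' @export
dcp_pmf <- function(lambda, alpha, N_trunc) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (any(alpha < 0) || abs(sum(alpha) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  N <- max(which(alpha > 0))
  p <- numeric(N_trunc + 1L)
  p[1] <- exp(-lambda)
  for (n in seq_len(N_trunc)) {
    i <- seq_len(min(n, N))
    p[n + 1L] <- sum(i * lambda * alpha[i] * p[n - i + 1L]) / n
  }
  cme_pmf(p, deficit = 1 - sum(p), noise = 0)
}

# helper for the stuttering parameterization g(s) = exp(sum a_i (s^i - 1))
dcp_pmf_a <- function(a, N_trunc) dcp_pmf(sum(a), a / sum(a), N_trunc)

#' Khatri Type B pmf (KTB^N)
#'
#' Distribution with PGF \code{(sum_i alpha_i s^i)^nu}: the nu-fold
#' convolution of the weight vector, support \code{0..nu*N}.  When the
#' weights are rational (within 1e-9 of p/q with q <= 1e6) the
#' convolution is carried out on integer numerators, so the result is
#' exact and sums to exactly 1.
#'
#' @param nu number of trials (integer >= 0).
#' @param alpha weights \code{alpha_0..alpha_N} summing to 1.
#' @return a \code{\link{cme_pmf}}.
#' @examples
#' ktb_pmf(4, c(0.52, 0.16, 0.32))$p[3]   # 0.22151168
#' @export
ktb_pmf <- function(nu, alpha) {
  if (nu < 0 || nu != round(nu)) stop("nu must be an integer >= 0")
  if (any(alpha < 0) || abs(sum(alpha) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  if (nu == 0) return(cme_pmf(1, deficit = 0))
  conv <- function(a, b) {
    r <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a))
      r[i:(i + length(b) - 1L)] <- r[i:(i + length(b) - 1L)] + a[i] * b
    r
  }
  # exact integer path for rational weights
  den <- NA
  for (q in c(2, 4, 5, 8, 10, 16, 20, 25, 50, 100, 1000, 1e4, 1e6)) {
    if (all(abs(alpha * q - round(alpha * q)) < 1e-9)) { den <- q; break }
  }
  if (!is.na(den) && den^nu < 2^53) {
    num <- round(alpha * den)
    r <- Reduce(conv, rep(list(num), nu))
    p <- r / den^nu
    return(cme_pmf(p, deficit = 1 - sum(p), noise = 0))
  }
  p <- Reduce(conv, rep(list(alpha), nu))
  cme_pmf(p, deficit = 1 - sum(p), noise = 0)
}

#' Neyman Type A pmf
#'
#' Poisson(lambda) generalized by Poisson(phi): PGF
#' \code{exp(lambda (exp(phi (s - 1)) - 1))}, the canonical multimodal
#' bursting distribution.  Computed as the mixture over the number of
#' bursts m ~ Poisson(lambda) of Poisson(m phi), truncating the burst
#' count when its Poisson tail drops below 1e-14.
#'
#' @param lambda burst-count rate (> 0).
#' @param phi burst size (> 0).
#' @param N_trunc truncation of the returned pmf.
#' @return a \code{\link{cme_pmf}}.
#' @export
neyman_a_pmf <- function(lambda, phi, N_trunc) {
  if (lambda <= 0 || phi <= 0) stop("lambda and phi must be > 0")
  M <- max(10, ceiling(lambda + 10 * sqrt(lambda) + 10))
  while (stats::ppois(M, lambda, lower.tail = FALSE) > 1e-14) M <- M + 10
  w <- stats::dpois(0:M, lambda)
  counts <- 0:N_trunc
  p <- numeric(N_trunc + 1L)
  for (m in 0:M) {
    p <- p + w[m + 1L] * if (m == 0) as.numeric(counts == 0) else
      stats::dpois(counts, m * phi)
  }
  cme_pmf(p, deficit = 1 - sum(p), noise = 0)
}

#' Kernel smoothing of a pmf
#'
#' Moving-average blur used before mode counting on Monte-Carlo
#' estimates, where bin noise would otherwise create spurious local
#' maxima.
#'
#' @param pmf a \code{\link{cme_pmf}}.
#' @param window odd window width (1 = no smoothing).
#' @return a \code{\link{cme_pmf}} with the same support.
#' @export
smooth_pmf <- function(pmf, window = 3L) {
  if (window <= 1L) return(pmf)
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  p <- pmf$p; n <- length(p)
  sm <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    mean(p[idx])
  }, numeric(1))
  cme_pmf(sm / sum(sm) * sum(p), deficit = pmf$deficit, noise = pmf$noise)
}

#' Local maxima of a pmf
#'
#' A count n is a local maximum iff \code{p_n >= p_{n-1}} and
#' \code{p_n >= p_{n+1}} with strict inequality on at least one
#' existing side; comparisons use the tolerance
#' \code{max(noise floor, 1e-12) * max(p)}.  Runs of ties (plateaus)
#' collapse to their leftmost point and are flagged.  \code{n = 0} only
#' uses the right comparison.
#'
#' @param pmf a \code{\link{cme_pmf}}.
#' @param smooth optional moving-average window applied first (for
#'   Monte-Carlo pmfs).
#' @return object of class \code{mode_set}: \code{modes} (locations),
#'   \code{plateau} (flags), \code{is_unimodal}.
#' @examples
#' find_local_maxima(ktb_pmf(4, c(0.52, 0.16, 0.32)))$modes  # 2 4
#' @export
find_local_maxima <- function(pmf, smooth = 1L) {
  if (!length(pmf$p)) stop("empty pmf")
  if (smooth > 1L) pmf <- smooth_pmf(pmf, smooth)
  p <- pmf$p
  tol <- max(pmf$noise, 1e-12) * max(p)
  n <- length(p)
  modes <- integer(); plateau <- logical()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && abs(p[j + 1L] - p[i]) <= tol) j <- j + 1L
    left_ok <- i == 1L || p[i - 1L] < p[i] - tol
    right_ok <- j == n || p[j + 1L] < p[j] - tol
    if (left_ok && right_ok && !(i == 1L && j == n && all(p <= tol))) {
      modes <- c(modes, i - 1L)
      plateau <- c(plateau, j > i)
    }
    i <- j + 1L
  }
  structure(list(modes = modes, plateau = plateau,
                 is_unimodal = length(modes) <= 1L),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("modes at {", paste(x$modes, collapse = ", "), "}",
      if (any(x$plateau)) " (plateaus flagged)" else "",
      "; ", if (x$is_unimodal) "unimodal" else "multimodal", "\n", sep = "")
  invisible(x)
}
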