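#' Two-level hierarchic decomposition of a first-order network
#'
#' Partitions the species into an independent part (system I, may
#' contain splitting and catalytic reactions, at most one independent
#' product molecule per reaction) and a dependent part (system II,
#' strictly monomolecular, fed by system I).  Influx reactions
#' \code{0 -> S} are collected in the rate vector \code{b}; the
#' conversion/degradation rates of system II populate the matrix
#' \code{A} used by the rate equation \code{dC/dt = A C + influx}.
#'
#' When several partitions are valid (a splitting product that never
#' acts as an educt can sit in either part) the partition is made
#' deterministic by two rules: species never appearing as educts are
#' assigned to the dependent part, and among the remaining valid
#' partitions the one maximizing the number of independent species is
#' chosen, ties broken by species order.
#'
#' @param net a \code{reaction_network} that is first-order or
#'   monomolecular (see \code{\link{classify_network}}).
#' @return an object of class \code{hierarchic_decomposition} with
#'   fields \code{ind_idx}, \code{dep_idx} (integer indices into
#'   \code{net$species}), \code{A} (n_dep x n_dep), \code{b} (length n)
#'   and \code{roles} (per-reaction tags).
#' @examples
#' decompose_hierarchic(parse_reactions("X -> X + Y @ 20.0"))
#' @export
decompose_hierarchic <- function(net) {
  cls <- classify_network(net)
  if (cls == "not-first-order")
    stop("network is not first-order: a reaction has more than one educt")
  n <- net$n; m <- net$m
  educt_of <- apply(net$Q, 2, function(q) {
    i <- which(q > 0)
    if (length(i)) i else NA_integer_
  })
  influx <- is.na(educt_of)
  # autocatalysis makes the characteristic system non-linear in s_educt,
  # so such networks fall outside the hierarchically linear class
  for (i in seq_len(m)) {
    if (influx[i]) next
    if (net$R[educt_of[i], i] > 1)
      stop("not hierarchic: autocatalytic reaction '",
           serialize_reactions(net)[i],
           "' (such systems are not hierarchically linear)")
  }
  for (i in which(influx)) {
    if (sum(net$R[, i]) != 1)
      stop("not two-level hierarchic: influx reaction '",
           serialize_reactions(net)[i],
           "' must produce exactly one molecule")
  }
  is_educt <- seq_len(n) %in% educt_of[!is.na(educt_of)]
  forced_dep <- which(!is_educt)      # never an educt -> dependent part
  free <- which(is_educt)

  valid_partition <- function(ind) {
    dep <- setdiff(seq_len(n), ind)
    for (i in seq_len(m)) {
      if (influx[i]) next
      e <- educt_of[i]
      if (e %in% ind) {
        if (sum(net$R[ind, i]) > 1) return(FALSE)
      } else {
        # dependent educt: monomolecular, products dependent only
        if (sum(net$R[ind, i]) > 0) return(FALSE)
        if (sum(net$R[dep, i]) > 1) return(FALSE)
      }
    }
    TRUE
  }

  best <- NULL
  nf <- length(free)
  if (nf > 20L) stop("partition search not supported beyond 20 educt species")
  # subsets of the educt species, largest first; within a size, prefer
  # including earlier species (lexicographic by species order)
  for (size in rev(0:nf)) {
    combs <- if (size == 0L) list(integer()) else
      lapply(utils::combn(seq_len(nf), size, simplify = FALSE),
             function(ii) free[ii])   # never let combn() expand a scalar
    for (ind in combs) {
      if (valid_partition(ind)) { best <- ind; break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    stop("not two-level hierarchic: no valid independent/dependent ",
         "partition exists")
  ind_idx <- sort(best)
  dep_idx <- setdiff(seq_len(n), ind_idx)

  roles <- character(m)
  b <- numeric(n)
  A <- matrix(0, length(dep_idx), length(dep_idx),
              dimnames = list(net$species[dep_idx], net$species[dep_idx]))
  for (i in seq_len(m)) {
    if (influx[i]) {
      roles[i] <- "influx"
      b[which(net$R[, i] > 0)] <- b[which(net$R[, i] > 0)] + net$k[i]
      next
    }
    e <- educt_of[i]
    if (e %in% ind_idx) { roles[i] <- "system-I"; next }
    ej <- match(e, dep_idx)
    prod <- which(net$R[, i] > 0)
    if (length(prod)) {
      pj <- match(prod, dep_idx)
      roles[i] <- "system-II-conversion"
      A[pj, ej] <- A[pj, ej] + net$k[i]
      A[ej, ej] <- A[ej, ej] - net$k[i]
    } else {
      roles[i] <- "system-II-degradation"
      A[ej, ej] <- A[ej, ej] - net$k[i]
    }
  }
  structure(list(net = net, ind_idx = ind_idx, dep_idx = dep_idx,
                 n_ind = length(ind_idx), n_dep = length(dep_idx),
                 A = A, b = b, roles = roles),
            class = "hierarchic_decomposition")
}

#' @export
print.hierarchic_decomposition <- function(x, ...) {
  cat("Hierarchic decomposition\n")
  cat("  independent (system I):",
      if (x$n_ind) paste(x$net$species[x$ind_idx], collapse = ", ")
      else "(none)", "\n")
  cat("  dependent (system II): ",
      if (x$n_dep) paste(x$net$species[x$dep_idx], collapse = ", ")
      else "(none)", "\n")
  if (any(x$b > 0))
    cat("  influx b:", paste(sprintf("%s=%g", x$net$species[x$b > 0],
                                     x$b[x$b > 0]), collapse = ", "), "\n")
  invisible(x)
}

# would moving dependent species X to the independent part still give a
# valid two-level partition?  (Splitting products that never act as
# educts are assignable to either part; unimodality then follows from
# the independent-part theorem.)
assignable_independent <- function(decomp, X) {
  net <- decomp$net
  xi <- match(X, net$species)
  if (xi %in% decomp$ind_idx) return(TRUE)
  ind <- sort(c(decomp$ind_idx, xi))
  dep <- setdiff(seq_len(net$n), ind)
  for (i in seq_len(net$m)) {
    e <- which(net$Q[, i] > 0)
    if (!length(e)) next
    if (e %in% ind) {
      if (sum(net$R[ind, i]) > 1) return(FALSE)
    } else {
      if (sum(net$R[ind, i]) > 0) return(FALSE)
      if (sum(net$R[dep, i]) > 1) return(FALSE)
    }
  }
  TRUE
}

# re-check the defining constraints of an existing decomposition;
# used by property tests
validate_decomposition <- function(decomp) {
  net <- decomp$net
  ind <- decomp$ind_idx; dep <- decomp$dep_idx
  stopifnot(sort(c(ind, dep)) == seq_len(net$n))
  for (i in seq_len(net$m)) {
    e <- which(net$Q[, i] > 0)
    if (!length(e)) next
    if (e %in% ind) {
      if (sum(net$R[ind, i]) > 1) return(FALSE)
    } else {
      if (sum(net$R[ind, i]) > 0) return(FALSE)
      if (sum(net$R[dep, i]) > 1) return(FALSE)
    }
  }
  TRUE
}
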