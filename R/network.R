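#' Reaction networks of first-order kinetics
#'
#' A reaction network holds an ordered species list, the educt and
#' product stoichiometric matrices \code{Q} and \code{R} (species x
#' reactions, non-negative integers) and the vector \code{k} of positive
#' rate constants (units 1/time).  Reaction \code{i} is
#' \code{Q[, i]' S -> R[, i]' S} with propensity
#' \code{k[i] * prod_j x_j! / (x_j - Q[j, i])!}.
#'
#' @param species character vector of unique species identifiers.
#' @param Q,R species-by-reaction matrices of non-negative integers.
#' @param k positive rate constants, one per reaction.
#' @return An object of class \code{reaction_network}.
#' @examples
#' net <- parse_reactions("X -> X + Y @ 20.0")
#' net$Q
#' @export
reaction_network <- function(species, Q, R, k) {
  species <- as.character(species)
  Q <- as.matrix(Q); R <- as.matrix(R)
  storage.mode(Q) <- "double"; storage.mode(R) <- "double"
  n <- length(species); m <- length(k)
  if (n < 1L || m < 1L) stop("need at least one species and one reaction")
  if (anyDuplicated(species)) stop("species identifiers must be unique")
  if (!all(dim(Q) == c(n, m)) || !all(dim(R) == c(n, m)))
    stop("Q and R must be ", n, " x ", m)
  if (any(Q < 0) || any(R < 0) || any(Q != round(Q)) || any(R != round(R)))
    stop("stoichiometric coefficients must be non-negative integers")
  if (any(!is.finite(k)) || any(k <= 0))
    stop("rate constants must be positive and finite")
  rownames(Q) <- rownames(R) <- species
  structure(list(species = species, Q = Q, R = R, k = as.numeric(k),
                 n = n, m = m),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", x$n, "species,", x$m, "reactions\n")
  cat(serialize_reactions(x), sep = "\n")
  invisible(x)
}

side_to_string <- function(coef, species) {
  idx <- which(coef > 0)
  if (!length(idx)) return("0")
  paste(ifelse(coef[idx] == 1, species[idx],
               paste(coef[idx], species[idx])), collapse = " + ")
}

#' Serialize a network back to the reaction-file grammar
#'
#' @param net a \code{reaction_network}.
#' @return character vector, one reaction per line.
#' @export
serialize_reactions <- function(net) {
  vapply(seq_len(net$m), function(i) {
    sprintf("%s -> %s @ %.17g",
            side_to_string(net$Q[, i], net$species),
            side_to_string(net$R[, i], net$species), net$k[i])
  }, character(1))
}

parse_side <- function(txt, line_no) {
  txt <- trimws(txt)
  if (txt == "0") return(list())
  terms <- strsplit(txt, "+", fixed = TRUE)[[1]]
  out <- list()
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9]+(?:\\.[0-9]+)?\\s+)?([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1]]
    if (!length(m))
      stop("syntax error in reaction term '", tm, "' on line ", line_no)
    coef <- if (nzchar(trimws(m[2]))) as.numeric(m[2]) else 1
    if (coef != round(coef))
      stop("non-integer stoichiometric coefficient on line ", line_no)
    out[[length(out) + 1L]] <- list(species = m[3], coef = as.integer(coef))
  }
  out
}

#' Parse a reaction file
#'
#' Grammar: one reaction per line, \code{<lhs> "->" <rhs> "@" <rate>},
#' each side either \code{0} (no species) or a \code{+}-separated list of
#' \code{[coefficient] species}; \code{#} starts a comment.  Lines
#' \code{init <species> det <count>} or \code{init <species> poisson
#' <mean>} declare the initial condition and are returned in the
#' \code{ic} attribute.
#'
#' @param text character scalar or vector with the file content, or a
#'   file path to read.
#' @return a \code{reaction_network}; if \code{init} lines are present,
#'   attribute \code{"ic"} holds the corresponding initial condition.
#' @examples
#' parse_reactions(c("X -> X + Y @ 20.0", "init X poisson 2"))
#' @export
parse_reactions <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  species <- character(); lhs <- list(); rhs <- list(); k <- numeric()
  ic_lines <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (grepl("^init\\s", line)) {
      m <- regmatches(line, regexec(
        "^init\\s+([A-Za-z_][A-Za-z0-9_]*)\\s+(det|poisson)\\s+([0-9eE+.-]+)$",
        line))[[1]]
      if (!length(m)) stop("syntax error in init line ", ln)
      ic_lines[[length(ic_lines) + 1L]] <-
        list(species = m[2], type = m[3], value = as.numeric(m[4]))
      next
    }
    m <- regmatches(line, regexec("^(.*)->(.*)@(.*)$", line))[[1]]
    if (!length(m)) stop("syntax error on line ", ln)
    rate <- suppressWarnings(as.numeric(trimws(m[4])))
    if (is.na(rate)) stop("unreadable rate on line ", ln)
    if (rate <= 0) stop("rate must be positive on line ", ln)
    l <- parse_side(m[2], ln); r <- parse_side(m[3], ln)
    for (tm in c(l, r))
      if (!tm$species %in% species) species <- c(species, tm$species)
    lhs[[length(lhs) + 1L]] <- l
    rhs[[length(rhs) + 1L]] <- r
    k <- c(k, rate)
  }
  if (!length(k)) stop("no reactions found")
  n <- length(species); m_ <- length(k)
  Q <- matrix(0, n, m_); R <- matrix(0, n, m_)
  for (i in seq_len(m_)) {
    for (tm in lhs[[i]]) Q[match(tm$species, species), i] <-
        Q[match(tm$species, species), i] + tm$coef
    for (tm in rhs[[i]]) R[match(tm$species, species), i] <-
        R[match(tm$species, species), i] + tm$coef
  }
  net <- reaction_network(species, Q, R, k)
  if (length(ic_lines)) {
    spec <- stats::setNames(vector("list", n), species)
    for (e in ic_lines) {
      if (!e$species %in% species) stop("init for unknown species ", e$species)
      spec[[e$species]] <- if (e$type == "det")
        list(type = "det", count = as.integer(e$value))
      else list(type = "poisson", mean = e$value)
    }
    attr(net, "ic") <- do.call(initial_condition, spec)
  }
  net
}

#' Classify a network by the order of its generating-function PDE
#'
#' \code{first-order} means every reaction has at most one educt
#' molecule (column sums of \code{Q} at most 1); \code{monomolecular}
#' additionally requires at most one product molecule.  Networks with a
#' bimolecular educt side are \code{not-first-order}.
#'
#' @param net a \code{reaction_network}.
#' @return one of \code{"monomolecular"}, \code{"first-order"},
#'   \code{"not-first-order"}.
#' @export
classify_network <- function(net) {
  qs <- colSums(net$Q); rs <- colSums(net$R)
  if (any(qs > 1)) return("not-first-order")
  if (all(rs <= 1)) "monomolecular" else "first-order"
}

#' Reaction propensities
#'
#' Mass-action propensities \code{k_i * prod_j x_j!/(x_j - Q_ji)!}, with
#' the falling factorial taken as 0 when \code{x_j < Q_ji}.
#'
#' @param net a \code{reaction_network}.
#' @param x non-negative integer state vector (length \code{net$n}).
#' @return numeric vector of length \code{net$m}.
#' @export
propensities <- function(net, x) {
  if (length(x) != net$n) stop("state has wrong length")
  if (any(x < 0) || any(x != round(x))) stop("state must be integer >= 0")
  a <- net$k
  for (i in seq_len(net$m)) {
    for (j in which(net$Q[, i] > 0)) {
      q <- net$Q[j, i]
      a[i] <- a[i] * if (x[j] < q) 0 else
        prod(seq.int(x[j], by = -1, length.out = q))
    }
  }
  a
}

#' State-change vectors
#'
#' @param net a \code{reaction_network}.
#' @return the species-by-reaction matrix \code{R - Q}.
#' @export
state_changes <- function(net) net$R - net$Q

#' Initial conditions for the CME
#'
#' Each species gets either a deterministic molecule count or a Poisson
#' mean; the joint initial distribution is the corresponding product.
#'
#' @param ... one named argument per species, each either
#'   \code{list(type = "det", count = <int>)} or
#'   \code{list(type = "poisson", mean = <num>)}.
#' @return an object of class \code{cme_ic}.
#' @examples
#' initial_condition(X = list(type = "poisson", mean = 2),
#'                   Y = list(type = "det", count = 0))
#' @export
initial_condition <- function(...) {
  spec <- list(...)
  if (is.null(names(spec)) || any(!nzchar(names(spec))))
    stop("every initial-condition entry must be named by its species")
  for (nm in names(spec)) {
    e <- spec[[nm]]
    if (is.null(e)) {
      spec[[nm]] <- list(type = "det", count = 0L)  # default: absent
      next
    }
    if (!is.list(e) || is.null(e$type)) stop("bad initial condition for ", nm)
    if (e$type == "det") {
      if (is.null(e$count) || e$count < 0 || e$count != round(e$count))
        stop("deterministic count for ", nm, " must be an integer >= 0")
    } else if (e$type == "poisson") {
      if (is.null(e$mean) || !is.finite(e$mean) || e$mean < 0)
        stop("poisson mean for ", nm, " must be finite and >= 0")
    } else stop("unknown initial-condition type '", e$type, "'")
  }
  structure(spec, class = "cme_ic")
}

# convenience builders used throughout tests and the model zoo
ic_all_poisson <- function(species, means) {
  do.call(initial_condition, stats::setNames(
    lapply(means, function(m) list(type = "poisson", mean = m)), species))
}

ic_all_det <- function(species, counts) {
  do.call(initial_condition, stats::setNames(
    lapply(counts, function(x) list(type = "det", count = as.integer(x))),
    species))
}
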