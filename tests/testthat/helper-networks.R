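# Fixture builders shared across test files.  Everything is constructed
# in code; parameter sets follow the worked examples of the model zoo.

catalysis_fixture <- function(mean_x = 2, y = list(type = "det", count = 0)) {
  net <- parse_reactions("X -> X + Y @ 20.0")
  ic <- initial_condition(X = list(type = "poisson", mean = mean_x), Y = y)
  d <- decompose_hierarchic(net)
  list(net = net, ic = ic, decomp = d, cs = build_characteristics(d))
}

splitting_fixture <- function(mean_x = 2) {
  net <- parse_reactions("X -> Y + Z @ 1.0")
  ic <- initial_condition(X = list(type = "poisson", mean = mean_x),
                          Y = list(type = "poisson", mean = 0),
                          Z = list(type = "poisson", mean = 0))
  d <- decompose_hierarchic(net)
  list(net = net, ic = ic, decomp = d, cs = build_characteristics(d))
}

conv_split_fixture <- function() {
  net <- parse_reactions(c("X -> Y + Z @ 7.0", "Y -> X @ 1.875"))
  ic <- initial_condition(X = list(type = "poisson", mean = 1.875),
                          Y = list(type = "poisson", mean = 1.875),
                          Z = list(type = "det", count = 0))
  d <- decompose_hierarchic(net)
  list(net = net, ic = ic, decomp = d, cs = build_characteristics(d))
}

chain3_fixture <- function() {
  net <- parse_reactions(c("X1 -> X2 @ 1.3", "X2 -> X3 @ 0.7"))
  ic <- initial_condition(X1 = list(type = "poisson", mean = 3),
                          X2 = list(type = "poisson", mean = 0.5),
                          X3 = list(type = "poisson", mean = 0.2))
  d <- decompose_hierarchic(net)
  list(net = net, ic = ic, decomp = d, cs = build_characteristics(d))
}

# random point in the open unit polydisc (complex), reproducible
runit <- function(n, rmax = 0.95) {
  r <- runif(n, 0, rmax); th <- runif(n, 0, 2 * pi)
  complex(modulus = r, argument = th)
}

# deterministic rate-equation Jacobian of the full network (dC/dt = F C + b)
rate_jacobian <- function(net) {
  F <- matrix(0, net$n, net$n)
  for (i in seq_len(net$m)) {
    e <- which(net$Q[, i] > 0)
    if (!length(e)) next
    F[, e] <- F[, e] + net$k[i] * (net$R[, i] - net$Q[, i])
  }
  F
}
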