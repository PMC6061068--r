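test_that("initial PGFs cover deterministic, Poisson and mixed products", {
  ic <- initial_condition(A = list(type = "det", count = 2),
                          B = list(type = "det", count = 0))
  expect_equal(initial_pgf(ic, c(0.5, 0.3) + 0i), 0.25 + 0i)
  icp <- initial_condition(A = list(type = "poisson", mean = 2))
  expect_equal(initial_pgf(icp, 1 + 0i), 1 + 0i)
  expect_equal(initial_pgf(icp, 0 + 0i), exp(-2) + 0i)
  mixed <- initial_condition(A = list(type = "poisson", mean = 2),
                             B = list(type = "det", count = 3))
  expect_equal(mixed_val <- initial_pgf(mixed, c(0.5, 0.5) + 0i),
               exp(-1) * 0.125 + 0i)
})

test_that("the numeric characteristics reproduce the catalysis solution", {
  f <- catalysis_fixture(mean_x = 2, y = list(type = "poisson", mean = 0))
  eq37 <- function(s, t) exp(2 * (exp(20 * t * (s[2] - 1)) * s[1] - 1))
  set.seed(101)
  for (r in 1:20) {
    s <- runit(2); t <- runif(1, 0.05, 1)
    expect_lt(abs(evaluate_pgf(f$decomp, f$cs, f$ic, s, t) - eq37(s, t)),
              1e-8)
  }
  # s = 1 is a fixed point of the characteristics
  expect_equal(evaluate_pgf(f$decomp, f$cs, f$ic, c(1, 1), 0.7), 1 + 0i,
               tolerance = 1e-9)
})

test_that("normalization g(1, t) = 1 holds across the zoo", {
  for (nm in c("catalysis", "catalysis_degradation", "splitting",
               "conversion_splitting", "two_stage", "two_stage_slow",
               "bateman")) {
    e <- zoo_model(nm)
    d <- decompose_hierarchic(e$net)
    cs <- build_characteristics(d)
    for (t in c(0.1, 1, 10)) {
      g1 <- evaluate_pgf(d, cs, e$ic, rep(1, e$net$n), t)
      expect_lt(abs(g1 - 1), 1e-9, label = paste(nm, "t =", t))
    }
  }
})

test_that("closed-form and numeric paths agree on no-influx models", {
  set.seed(7)
  for (fx in list(catalysis_fixture(y = list(type = "poisson", mean = 0)),
                  splitting_fixture(), conv_split_fixture())) {
    h <- closed_form_pgf(fx$decomp, fx$cs, fx$ic)
    for (r in 1:20) {
      s <- runit(fx$net$n); t <- runif(1, 0.05, 1.5)
      a <- evaluate_pgf(fx$decomp, fx$cs, fx$ic, s, t)
      expect_lt(abs(a - h$eval(s, t)), 1e-8)
    }
  }
})

test_that("closed form refuses influx and hands off to the numeric path", {
  net <- parse_reactions(c("0 -> X @ 1.2", "X -> 0 @ 1.2",
                           "X -> X + Y @ 10.0", "Y -> 0 @ 0.3"))
  d <- decompose_hierarchic(net)
  cs <- build_characteristics(d)
  ic <- initial_condition(X = list(type = "det", count = 0),
                          Y = list(type = "det", count = 0))
  expect_error(closed_form_pgf(d, cs, ic), "evaluate_pgf")
})

test_that("monomolecular networks stay product Poisson (rate-equation means)", {
  f <- chain3_fixture()
  h <- closed_form_pgf(f$decomp, f$cs, f$ic)
  F <- rate_jacobian(f$net)
  for (t in c(0.5, 2)) {
    means <- as.vector(hiercme:::cexpm(F * t) %*% c(3, 0.5, 0.2))
    for (i in 1:3) {
      pm <- pmf_from_pgf(marginal_pgf(h, paste0("X", i), t), 40)
      ref <- cme_pmf(stats::dpois(0:40, means[i]), deficit = 0)
      expect_lt(total_variation(pm, ref), 1e-8)
    }
  }
})

test_that("marginals at u = 1 are 1 and unknown species are rejected", {
  f <- catalysis_fixture()
  h <- closed_form_pgf(f$decomp, f$cs, f$ic)
  gu <- marginal_pgf(h, "Y", 0.4)
  expect_equal(gu(1 + 0i), 1 + 0i, tolerance = 1e-10)
  expect_error(marginal_pgf(h, "W", 0.4), "unknown species")
})

test_that("deterministic-IC catalysis marginal of Y is exactly Poisson", {
  f <- catalysis_fixture(y = list(type = "det", count = 0))
  ic <- initial_condition(X = list(type = "det", count = 2),
                          Y = list(type = "det", count = 0))
  h <- closed_form_pgf(f$decomp, f$cs, ic)
  t <- 0.15
  pm <- pmf_from_pgf(marginal_pgf(h, "Y", t), 64)
  ref <- cme_pmf(stats::dpois(0:64, 2 * 20 * t), deficit = 0)
  expect_lt(total_variation(pm, ref), 1e-10)
})

test_that("splitting marginals are Poisson with the printed covariance", {
  f <- splitting_fixture(mean_x = 2)
  h <- closed_form_pgf(f$decomp, f$cs, f$ic)
  t <- 0.8
  lam <- 2 * (1 - exp(-t))          # rate-equation mean of Y and Z
  for (X in c("Y", "Z")) {
    pm <- pmf_from_pgf(marginal_pgf(h, X, t), 32)
    expect_lt(total_variation(pm, cme_pmf(stats::dpois(0:32, lam),
                                          deficit = 0)), 1e-8)
  }
  # mixed second cumulant Cov(Y, Z) = <x>_0 (1 - exp(-k t))
  hh <- 1e-4
  lg <- function(sy, sz) log(Re(h$eval(c(1, sy, sz), t)))
  cov_yz <- (lg(1 + hh, 1 + hh) - lg(1 + hh, 1 - hh) -
             lg(1 - hh, 1 + hh) + lg(1 - hh, 1 - hh)) / (4 * hh^2)
  expect_equal(cov_yz, 2 * (1 - exp(-t)), tolerance = 1e-6)
})

test_that("first cumulants from the PGF solve the rate equations", {
  for (nm in c("catalysis_degradation", "conversion_splitting",
               "two_stage")) {
    e <- zoo_model(nm)
    d <- decompose_hierarchic(e$net)
    cs <- build_characteristics(d)
    h <- hiercme:::numeric_pgf(d, cs, e$ic)
    t <- e$times[1]
    m0 <- vapply(hiercme:::align_ic(e$ic, e$net$species), function(x)
      if (x$type == "poisson") x$mean else as.numeric(x$count), numeric(1))
    rhs <- function(tt, C, p) {
      dC <- numeric(e$net$n)
      for (i in seq_len(e$net$m)) {
        ed <- which(e$net$Q[, i] > 0)
        rate <- e$net$k[i] * if (length(ed)) C[ed] else 1
        dC <- dC + rate * (e$net$R[, i] - e$net$Q[, i])
      }
      list(dC)
    }
    ode_means <- deSolve::ode(m0, c(0, t), rhs, NULL,
                              rtol = 1e-10, atol = 1e-12)[2, -1]
    for (j in seq_len(e$net$n)) {
      mu <- cumulants_from_pgf(marginal_pgf(h, e$net$species[j], t), 1)
      expect_equal(unname(mu), unname(ode_means[j]), tolerance = 1e-5,
                   label = paste(nm, e$net$species[j]))
    }
  }
})

test_that("the decay-chain closed form matches the characteristic solver", {
  k <- c(3.1, 1); part <- matrix(c(1L, 1L), 2, 1,
                                 dimnames = list(NULL, "Y"))
  ic <- initial_condition(X1 = list(type = "poisson", mean = 2),
                          X2 = list(type = "poisson", mean = 0.1),
                          X3 = list(type = "poisson", mean = 0.001),
                          Y = list(type = "poisson", mean = 0))
  h <- bateman_pgf(k, part, ic)
  net <- bateman_chain(k, part)
  d <- decompose_hierarchic(net)
  cs <- build_characteristics(d)
  set.seed(12)
  for (r in 1:20) {
    s <- runit(4); t <- runif(1, 0.1, 2)
    expect_lt(abs(h$eval(s, t) - evaluate_pgf(d, cs, ic, s, t)), 1e-8)
  }
})

test_that("a chain without particles reduces to monomolecular Bateman means", {
  ic <- initial_condition(X1 = list(type = "poisson", mean = 1.7),
                          X2 = list(type = "poisson", mean = 0))
  h <- bateman_pgf(0.9, matrix(0L, 1, 1, dimnames = list(NULL, "Y")), ic)
  t <- 1.1
  gu <- marginal_pgf(h, "X2", t)
  expect_equal(cumulants_from_pgf(gu, 1), 1.7 * (1 - exp(-0.9 * t)),
               tolerance = 1e-7)
  pm <- pmf_from_pgf(gu, 32)
  expect_lt(total_variation(
    pm, cme_pmf(stats::dpois(0:32, 1.7 * (1 - exp(-0.9 * t))),
                deficit = 0)), 1e-10)
})

test_that("repeated decay rates fall back to the numeric path with a warning", {
  ic <- initial_condition(X1 = list(type = "poisson", mean = 1),
                          X2 = list(type = "poisson", mean = 0),
                          X3 = list(type = "poisson", mean = 0),
                          Y = list(type = "poisson", mean = 0))
  expect_warning(
    h <- bateman_pgf(c(1, 1), matrix(c(1L, 1L), 2, 1,
                                     dimnames = list(NULL, "Y")), ic),
    "repeated")
  expect_equal(h$method, "numeric-characteristics")
  expect_equal(abs(h$eval(rep(1, 4), 0.5)), 1, tolerance = 1e-9)
})
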