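random_params <- function(model, oral = FALSE) {
  rl <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  ka <- if (oral) rl(0.2, 5) else NULL
  Fb <- if (oral) runif(1, 0.3, 1) else NULL
  if (model == "one_compartment")
    one_comp_params(rl(0.1, 10), rl(0.05, 2), ka, Fb)
  else
    two_comp_params(rl(0.1, 10), rl(0.05, 2), rl(0.05, 3), rl(0.05, 3),
                    ka, Fb)
}

# Slowest rate governing the tail (absorption-limited "flip-flop" kinetics
# when ka is the slowest process).
terminal_rate <- function(model, params, route = "intravenous") {
  r <- if (model == "one_compartment") params$kelim
  else macro_rates(params)$beta
  if (route == "oral") r <- min(r, params$kabsorb)
  r
}

test_that("one-compartment IV solution has the right anchor points", {
  p <- one_comp_params(Vd = 1, kelim = log(2))
  expect_equal(concentration("one_compartment", "intravenous", p, 1, 0), 1)
  p <- one_comp_params(Vd = 4, kelim = log(2))
  expect_equal(concentration("one_compartment", "intravenous", p, 2, 1),
               0.25)   # one half-life from C0 = 0.5
})

test_that("oral dosing starts at zero and requires absorption parameters", {
  p <- one_comp_params(Vd = 1, kelim = 0.2, kabsorb = 1, Fbio = 0.9)
  expect_equal(concentration("one_compartment", "oral", p, 3, 0), 0)
  p2 <- two_comp_params(0.5, 0.2, 0.5, 0.3, kabsorb = 1, Fbio = 0.8)
  expect_equal(concentration("two_compartment", "oral", p2, 1, 0), 0)
  bare <- one_comp_params(Vd = 1, kelim = 0.2)
  expect_error(concentration("one_compartment", "oral", bare, 1, 1),
               class = "cvt_parameter_error")
})

test_that("the two-compartment model nests the one-compartment model as k12 -> 0", {
  tgrid <- c(0.1, 0.5, 1, 2, 5, 10, 24)
  p1 <- one_comp_params(Vd = 0.8, kelim = 0.3)
  p2 <- two_comp_params(V1 = 0.8, kelim = 0.3, k12 = 1e-12, k21 = 0.5)
  c1 <- concentration("one_compartment", "intravenous", p1, 2, tgrid)
  c2 <- concentration("two_compartment", "intravenous", p2, 2, tgrid)
  expect_equal(c2, c1, tolerance = 1e-9)
})

test_that("the coincident-rate oral limit is continuous", {
  pa <- one_comp_params(Vd = 1, kelim = 0.5, kabsorb = 0.5, Fbio = 1)
  pb <- one_comp_params(Vd = 1, kelim = 0.5, kabsorb = 0.5 * (1 + 1e-7),
                        Fbio = 1)
  tgrid <- c(0.5, 1, 2, 4)
  expect_equal(concentration("one_compartment", "oral", pa, 1, tgrid),
               concentration("one_compartment", "oral", pb, 1, tgrid),
               tolerance = 1e-6)
})

test_that("macro rates are the roots of the disposition polynomial", {
  # k12 ~ 0 factorizes into {k21, kelim}
  mr <- macro_rates(two_comp_params(1, 0.3, 1e-12, 0.7))
  expect_equal(sort(c(mr$alpha, mr$beta)), c(0.3, 0.7), tolerance = 1e-9)
  # Vieta for the symmetric case
  mr <- macro_rates(two_comp_params(1, 1, 1, 1))
  expect_equal(mr$alpha + mr$beta, 3)
  expect_equal(mr$alpha * mr$beta, 1)
  # defining property on random draws
  set.seed(5)
  for (i in 1:25) {
    p <- random_params("two_compartment")
    s <- p$k12 + p$k21 + p$kelim; q <- p$k21 * p$kelim
    mr <- macro_rates(p)
    expect_true(mr$alpha > mr$beta, info = "alpha > beta")
    expect_gt(mr$beta, 0)
    for (root in c(mr$alpha, mr$beta))
      expect_lt(abs(root^2 - s * root + q), 1e-12 * max(1, s^2))
  }
})

test_that("derived quantities match their closed forms", {
  p <- one_comp_params(Vd = 1, kelim = log(2))
  expect_equal(derived_tk_parameters("one_compartment", p, 1,
                                     "intravenous")$halflife_h, 1)
  p <- one_comp_params(Vd = 2, kelim = 0.5)
  d <- derived_tk_parameters("one_compartment", p, 10, "intravenous")
  expect_equal(d$AUCinf, 10)         # D / (Vd kelim)
  expect_equal(d$CLtot, 1)
  # oral tmax: ln(ka/kelim)/(ka - kelim), checked against direct maximization
  p <- one_comp_params(Vd = 1, kelim = 0.25, kabsorb = 1, Fbio = 1)
  d <- derived_tk_parameters("one_compartment", p, 1, "oral")
  expect_equal(d$tmax, log(4) / 0.75, tolerance = 1e-12)
  num <- optimize(function(tt) concentration("one_compartment", "oral", p,
                                             1, tt),
                  c(0, 40), maximum = TRUE, tol = 1e-9)
  expect_equal(d$tmax, num$maximum, tolerance = 1e-4)
  expect_equal(d$Cmax, num$objective, tolerance = 1e-9)
})

test_that("closed forms agree with ODE integration on 100 random draws", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    model <- sample(c("one_compartment", "two_compartment"), 1)
    route <- sample(c("intravenous", "oral"), 1)
    p <- random_params(model, oral = route == "oral")
    beta <- terminal_rate(model, p, route)
    tgrid <- seq(0.05, 10 / beta, length.out = 12)
    dose <- exp(runif(1, log(0.1), log(50)))
    cf <- concentration(model, route, p, dose, tgrid)
    od <- ode_concentration(model, route, p, dose, tgrid)
    denom <- pmax(abs(od), max(abs(od)) * 1e-9)
    worst <- max(worst, max(abs(cf - od) / denom))
  }
  expect_lt(worst, 1e-6)
})

test_that("concentrations are non-negative and decay to zero", {
  set.seed(7)
  for (i in 1:20) {
    model <- sample(c("one_compartment", "two_compartment"), 1)
    route <- sample(c("intravenous", "oral"), 1)
    p <- random_params(model, oral = route == "oral")
    beta <- terminal_rate(model, p, route)
    tgrid <- seq(0, 50 * log(2) / beta, length.out = 200)
    conc <- concentration(model, route, p, 1, tgrid)
    expect_true(all(conc >= 0))
    expect_lt(conc[length(conc)], 1e-10 * max(conc))
  }
})

test_that("trapezoid AUC over 10 terminal half-lives recovers AUCinf (mass balance)", {
  set.seed(9)
  for (i in 1:10) {
    model <- sample(c("one_compartment", "two_compartment"), 1)
    route <- sample(c("intravenous", "oral"), 1)
    p <- random_params(model, oral = route == "oral")
    beta <- terminal_rate(model, p, route)
    tgrid <- seq(0, 10 * log(2) / beta, length.out = 4000)
    conc <- concentration(model, route, p, 1, tgrid)
    auc <- trapezoid_auc(tgrid, conc)
    d <- derived_tk_parameters(model, p, 1, route)
    expect_equal(auc, d$AUCinf, tolerance = 0.005)
    # AUCinf * CLtot = Fbio * dose (mass balance)
    Fb <- if (route == "oral") p$Fbio else 1
    expect_equal(d$AUCinf * d$CLtot, Fb * 1, tolerance = 1e-9)
  }
})
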