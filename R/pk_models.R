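# Closed-form concentration functions for 1- and 2-compartment models under
# IV-bolus and first-order oral absorption, and derived TK quantities.
# Units close under mg/kg doses and L/kg volumes: mg/kg / (L/kg) = mg/L =
# ug/mL.

#' One-compartment parameter set
#'
#' @param Vd volume of distribution, L per kg bodyweight.
#' @param kelim first-order elimination rate constant, 1/h.
#' @param kabsorb first-order gut absorption rate, 1/h (oral dosing only).
#' @param Fbio fraction of the oral dose bioavailable, in \[0, 1\].
#' @return Object of class `one_comp_params`.
#' @export
one_comp_params <- function(Vd, kelim, kabsorb = NULL, Fbio = NULL) {
  if (!is.numeric(Vd) || Vd <= 0 || !is.numeric(kelim) || kelim <= 0)
    cvt_error("cvt_domain_error", "Vd and kelim must be strictly positive")
  if (!is.null(kabsorb) && (!is.numeric(kabsorb) || kabsorb <= 0))
    cvt_error("cvt_domain_error", "kabsorb must be strictly positive")
  if (!is.null(Fbio) && (Fbio < 0 || Fbio > 1))
    cvt_error("cvt_domain_error", "Fbio must lie in [0, 1]")
  structure(list(Vd = Vd, kelim = kelim, kabsorb = kabsorb, Fbio = Fbio),
            class = c("one_comp_params", "compartmental_params"))
}

#' Two-compartment parameter set
#'
#' Central-compartment elimination with first-order exchange to a peripheral
#' compartment (micro-constants k12, k21).
#'
#' @param V1 central compartment volume, L per kg bodyweight.
#' @param kelim elimination rate constant from the central compartment, 1/h.
#' @param k12,k21 inter-compartment exchange rate constants, 1/h.
#' @param kabsorb first-order gut absorption rate, 1/h (oral dosing only).
#' @param Fbio fraction of the oral dose bioavailable, in \[0, 1\].
#' @return Object of class `two_comp_params`.
#' @export
two_comp_params <- function(V1, kelim, k12, k21, kabsorb = NULL,
                            Fbio = NULL) {
  if (any(c(V1, kelim, k12, k21) <= 0))
    cvt_error("cvt_domain_error",
              "V1, kelim, k12 and k21 must be strictly positive")
  if (!is.null(kabsorb) && kabsorb <= 0)
    cvt_error("cvt_domain_error", "kabsorb must be strictly positive")
  if (!is.null(Fbio) && (Fbio < 0 || Fbio > 1))
    cvt_error("cvt_domain_error", "Fbio must lie in [0, 1]")
  structure(list(V1 = V1, kelim = kelim, k12 = k12, k21 = k21,
                 kabsorb = kabsorb, Fbio = Fbio),
            class = c("two_comp_params", "compartmental_params"))
}

#' Macro disposition rates of the two-compartment model
#'
#' The hybrid rate constants alpha > beta > 0 are the roots of
#' s^2 - (k12 + k21 + kelim) s + k21 kelim = 0; the bi-exponential IV
#' solution is C(t) = A exp(-alpha t) + B exp(-beta t) with
#' A = D (alpha - k21) / (V1 (alpha - beta)) and
#' B = D (k21 - beta) / (V1 (alpha - beta)).
#'
#' @param params a [two_comp_params()].
#' @return List with `alpha`, `beta` and unit-dose IV coefficients
#'   `A_unit`, `B_unit` (for D/V1 = 1).
#' @export
macro_rates <- function(params) {
  stopifnot(inherits(params, "two_comp_params"))
  s <- params$k12 + params$k21 + params$kelim
  p <- params$k21 * params$kelim
  disc <- sqrt(max(s^2 - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(alpha = alpha, beta = beta,
       A_unit = (alpha - params$k21) / (alpha - beta),
       B_unit = (params$k21 - beta) / (alpha - beta))
}

#' Predicted concentration under a compartmental model
#'
#' Analytical solutions of the 1- and 2-compartment disposition models with
#' IV-bolus or first-order oral absorption input:
#' \itemize{
#' \item 1c IV: `(D/Vd) exp(-kelim t)`
#' \item 1c oral: `Fbio D ka / (Vd (ka - kelim)) (exp(-kelim t) - exp(-ka t))`
#'   with the coincident-rate limit `Fbio D ka t exp(-ka t) / Vd` when
#'   `|ka - kelim| < 1e-8 kelim`
#' \item 2c IV: bi-exponential in the macro rates alpha, beta
#' \item 2c oral: tri-exponential in alpha, beta and ka
#' }
#'
#' @param model `"one_compartment"` or `"two_compartment"`.
#' @param route `"intravenous"` or `"oral"`.
#' @param params matching parameter object.
#' @param dose dose in mg per kg bodyweight.
#' @param t time(s) in hours, >= 0.
#' @return Predicted concentration(s) in ug/mL.
#' @export
concentration <- function(model = c("one_compartment", "two_compartment"),
                          route = c("intravenous", "oral"), params, dose, t) {
  model <- match.arg(model)
  route <- match.arg(route)
  if (any(t < 0)) cvt_error("cvt_domain_error", "t must be >= 0")
  if (dose <= 0) cvt_error("cvt_domain_error", "dose must be > 0")
  if (route == "oral" &&
      (is.null(params$kabsorb) || is.null(params$Fbio)))
    cvt_error("cvt_parameter_error",
              "oral route requires kabsorb and Fbio")

  if (model == "one_compartment") {
    stopifnot(inherits(params, "one_comp_params"))
    if (route == "intravenous")
      return(dose / params$Vd * exp(-params$kelim * t))
    ka <- params$kabsorb; ke <- params$kelim
    FD <- params$Fbio * dose
    if (abs(ka - ke) < 1e-8 * ke)
      return(FD * ka * t * exp(-ka * t) / params$Vd)
    return(FD * ka / (params$Vd * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)))
  }

  stopifnot(inherits(params, "two_comp_params"))
  mr <- macro_rates(params)
  a <- mr$alpha; b <- mr$beta; V1 <- params$V1; k21 <- params$k21
  if (route == "intravenous")
    return(dose / V1 * (mr$A_unit * exp(-a * t) + mr$B_unit * exp(-b * t)))
  ka <- params$kabsorb
  # A macro rate coincident with ka makes the partial fractions singular;
  # nudge ka (realistic parameters never hit the degeneracy exactly).
  if (min(abs(ka - a), abs(ka - b)) < 1e-8 * ka) ka <- ka * (1 + 1e-7)
  FDka <- params$Fbio * dose * ka
  c1 <- (k21 - a) / ((ka - a) * (b - a))
  c2 <- (k21 - b) / ((ka - b) * (a - b))
  c3 <- (k21 - ka) / ((a - ka) * (b - ka))
  pmax(FDka / V1 * (c1 * exp(-a * t) + c2 * exp(-b * t) + c3 * exp(-ka * t)),
       0)
}

#' Derived toxicokinetic quantities
#'
#' Terminal half-life, total clearance, extrapolated AUC, and the maximum
#' concentration and its time. For the one-compartment model these are closed
#' forms (`halflife = ln 2 / kelim`, `CLtot = Vd kelim`,
#' `AUCinf = Fbio D / CLtot`, oral `tmax = ln(ka/kelim)/(ka - kelim)`); the
#' two-compartment terminal half-life is `ln 2 / beta`, `CLtot = V1 kelim`,
#' and the oral Cmax/tmax are located numerically.
#'
#' @inheritParams concentration
#' @return List with `halflife_h`, `CLtot`, `AUCinf`, `Cmax`, `tmax`.
#' @export
derived_tk_parameters <- function(model = c("one_compartment",
                                            "two_compartment"),
                                  params, dose,
                                  route = c("intravenous", "oral")) {
  model <- match.arg(model)
  route <- match.arg(route)
  Fb <- if (route == "oral") params$Fbio else 1
  if (model == "one_compartment") {
    halflife <- log(2) / params$kelim
    CL <- params$Vd * params$kelim
    beta <- params$kelim
  } else {
    mr <- macro_rates(params)
    beta <- mr$beta
    halflife <- log(2) / beta
    CL <- params$V1 * params$kelim
  }
  AUCinf <- Fb * dose / CL
  if (route == "intravenous") {
    tmax <- 0
    Cmax <- concentration(model, route, params, dose, 0)
  } else if (model == "one_compartment") {
    ka <- params$kabsorb; ke <- params$kelim
    tmax <- if (abs(ka - ke) < 1e-8 * ke) 1 / ka else
      log(ka / ke) / (ka - ke)
    Cmax <- concentration(model, route, params, dose, tmax)
  } else {
    opt <- optimize(function(tt) concentration(model, route, params, dose,
                                               tt),
                    interval = c(0, 12 / beta), maximum = TRUE,
                    tol = 1e-10)
    tmax <- opt$maximum
    Cmax <- opt$objective
  }
  list(halflife_h = halflife, CLtot = CL, AUCinf = AUCinf, Cmax = Cmax,
       tmax = tmax)
}
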