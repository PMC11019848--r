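# Kinetic uptake regulation and the growth/concentration update rules.
#
# Uptake bounds are signed: negative flux = uptake. The effective
# pre-kinetic limit is the binding (less negative) of the availability
# bound -conc/(B*dt) -- classical dFBA: never drain more substrate than the
# broth holds in one step -- and the intrinsic transporter limit `lin`.
# Monod multiplies this by conc/(K + conc); Contois by
# conc/(K*B + conc), modelling biomass-dependent access to the substrate
# (polymer hydrolysis).

#' Kinetic regulation of an exchange reaction
#'
#' @param reaction target exchange reaction id.
#' @param kind `"monod"` or `"contois"`.
#' @param K half-saturation constant, > 0 (mM for Monod; mM per gDW/L for
#'   Contois, where it scales with biomass).
#' @param lin intrinsic uptake lower bound (mmol gDW^-1 h^-1, negative);
#'   `NULL` uses the model's static lower bound.
#' @return object of class `kinetic_regulation`.
#' @export
kinetic_regulation <- function(reaction, kind = c("monod", "contois"),
                               K, lin = NULL) {
  kind <- match.arg(kind)
  if (K <= 0) stop("K must be > 0")
  if (!is.null(lin) && !is.finite(lin)) stop("lin must be finite")
  structure(list(reaction = reaction, kind = kind, K = K, lin = lin),
            class = "kinetic_regulation")
}

availability_bound <- function(conc, biomass, dt, lin) {
  if (biomass <= 0) stop("biomass must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  max(-conc / (biomass * dt), lin)
}

#' Monod-regulated uptake lower bound
#'
#' `max(-conc/(B dt), lin) * conc / (K + conc)`: the binding pre-kinetic
#' limit times the Monod saturation factor.
#'
#' @param conc substrate concentration (mM), >= 0.
#' @param biomass biomass concentration (gDW/L), > 0.
#' @param dt time step (h), > 0.
#' @param reg a `kinetic_regulation` of kind `"monod"`.
#' @return signed lower bound (<= 0 for uptake).
#' @export
monod_bound <- function(conc, biomass, dt, reg) {
  availability_bound(conc, biomass, dt, reg$lin) * conc / (reg$K + conc)
}

#' Contois-regulated uptake lower bound
#'
#' `max(-conc/(B dt), lin) * conc / (K B + conc)`: the saturation constant
#' scales with biomass, so crowded cultures see proportionally less
#' accessible substrate.
#'
#' @inheritParams monod_bound
#' @param reg a `kinetic_regulation` of kind `"contois"`.
#' @export
contois_bound <- function(conc, biomass, dt, reg) {
  availability_bound(conc, biomass, dt, reg$lin) *
    conc / (reg$K * biomass + conc)
}

#' Carrying-capacity parameters
#'
#' The environmental biomass ceiling is the plateau biomass reached in the
#' baseline (GLM) medium plus a Hill-shaped increment in the initial
#' whey-protein concentration:
#' `cc = T_GLM + WP^H / (K + WP^H)` (increment saturating at 1, implemented
#' literally as the model defines it; units g/L implied).
#'
#' @param T_GLM plateau biomass in the baseline medium (gDW/L), > 0.
#' @param Hillcoef Hill exponent, > 0.
#' @param K Hill constant, > 0 (compared against `WP^Hillcoef`).
#' @param lambda logistic rate multiplier, >= 0 (dimensionless).
#' @param WP_initial initial whey-protein concentration (g/L), >= 0.
#' @return object of class `carrying_capacity_params`.
#' @export
carrying_capacity_params <- function(T_GLM, Hillcoef = 2, K = 1,
                                     lambda = 1, WP_initial = 0) {
  if (T_GLM <= 0) stop("T_GLM must be > 0")
  if (Hillcoef <= 0) stop("Hillcoef must be > 0")
  if (K <= 0) stop("K must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  if (WP_initial < 0) stop("WP_initial must be >= 0")
  structure(list(T_GLM = T_GLM, Hillcoef = Hillcoef, K = K,
                 lambda = lambda, WP_initial = WP_initial),
            class = "carrying_capacity_params")
}

#' Carrying capacity (gDW/L)
#' @param params a `carrying_capacity_params`.
#' @export
carrying_capacity <- function(params) {
  wph <- params$WP_initial^params$Hillcoef
  params$T_GLM + wph / (params$K + wph)
}

#' One biomass step (semi-explicit exact logistic integration)
#'
#' The logistic factor `lambda (1 - B/cc)` and the FBA growth rate are
#' frozen at the step's start; the resulting linear ODE
#' `dB/dt = r B` is integrated exactly: `B exp(r dt)`. Always positive.
#'
#' @param B biomass at the step start (gDW/L), > 0.
#' @param mu_fba FBA growth rate (1/h), >= 0.
#' @param params a `carrying_capacity_params`.
#' @param dt step (h), > 0.
#' @return biomass after `dt`.
#' @export
biomass_step <- function(B, mu_fba, params, dt) {
  if (B <= 0) stop("biomass must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  cc <- carrying_capacity(params)
  B * exp(params$lambda * (1 - B / cc) * mu_fba * dt)
}

#' One metabolite step (semi-implicit Euler)
#'
#' Production (v >= 0) is explicit: `m + v B dt`. Consumption (v < 0) is
#' implicit with the consumption rate linearised proportional to the
#' concentration, giving `m^2 / (m + |v| B dt)` -- strictly positive
#' whenever `m > 0`, which is the scheme's point.
#'
#' @param m concentration (mM), >= 0.
#' @param v exchange flux (mmol gDW^-1 h^-1; positive = production).
#' @param B biomass at the step start (gDW/L).
#' @param dt step (h).
#' @return concentration after `dt`.
#' @export
metabolite_step <- function(m, v, B, dt) {
  if (m < 0) stop("concentration must be >= 0")
  if (m == 0 && v < 0) return(0)
  if (v >= 0) m + v * B * dt
  else m^2 / (m + abs(v) * B * dt)
}
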