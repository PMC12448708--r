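#' @keywords internal
"_PACKAGE"

# universal gas constant, J mol-1 K-1
GAS_CONSTANT <- 8.314
# degrees C -> K offset
KELVIN0 <- 273.15
# default atmospheric O2 mole fraction, umol mol-1 (21 percent O2)
O2_DEFAULT <- 210000

#' Exponential Arrhenius temperature adjustment
#'
#' Scales a rate or constant known at 25 degrees C to another leaf
#' temperature with the standard exponential Arrhenius form
#' \deqn{k(T) = k_{25} \exp\!\left[\frac{E_a (T_k - 298.15)}{298.15\, R\, T_k}\right]}
#' where \eqn{T_k} is the leaf temperature in K and R = 8.314 J mol-1 K-1.
#'
#' @param k25 value at 25 degrees C (must be positive).
#' @param ea activation energy (J mol-1).
#' @param tleaf leaf temperature (degrees C).
#' @return The adjusted value at `tleaf`; equals `k25` at 25 degrees C and is
#'   strictly increasing in `tleaf` when `ea > 0`.
#' @export
arrheniusAdjust <- function(k25, ea, tleaf) {
  if (!all(is.finite(k25)) || !all(is.finite(ea)) || !all(is.finite(tleaf)))
    stop("arrheniusAdjust: inputs must be finite")
  if (any(k25 <= 0)) stop("arrheniusAdjust: k25 must be positive")
  tk <- tleaf + KELVIN0
  k25 * exp(ea * (tk - 298.15) / (298.15 * GAS_CONSTANT * tk))
}

#' Peaked Arrhenius temperature response
#'
#' Unimodal rate-versus-temperature function parameterised by the rate at the
#' optimum (`kopt`), the thermal optimum (`topt`, K), an activation energy
#' (`ea`) describing the rise below the optimum and a deactivation energy
#' (`hd`) describing the fall above it:
#' \deqn{f(T_l) = k_{opt} \frac{H_d \exp\!\left(\frac{E_a (T_l - T_{opt})}{T_l R T_{opt}}\right)}
#'   {H_d - E_a \left(1 - \exp\!\left(\frac{H_d (T_l - T_{opt})}{T_l R T_{opt}}\right)\right)}}
#' with \eqn{T_l} in K. `f(topt) = kopt` exactly and `f(tl) < kopt` for any
#' other temperature provided `0 < ea < hd`.
#'
#' @param kopt rate at the optimum (umol CO2 m-2 s-1).
#' @param topt thermal optimum (K).
#' @param ea activation energy (J mol-1); must satisfy `0 < ea < hd`.
#' @param hd deactivation energy (J mol-1), conventionally fixed at 200000.
#' @param tl evaluation temperature(s) (K).
#' @return Process rate(s) at `tl`.
#' @export
peakedArrhenius <- function(kopt, topt, ea, hd = 200000, tl) {
  if (!all(is.finite(c(kopt, topt, ea, hd))) || !all(is.finite(tl)))
    stop("peakedArrhenius: inputs must be finite")
  if (ea >= hd)
    stop("peakedArrhenius: requires ea < hd (deactivation must dominate)")
  if (ea <= 0) stop("peakedArrhenius: ea must be positive")
  if (any(tl <= 150) || topt <= 150)
    stop("peakedArrhenius: temperatures must be in Kelvin (looks like Celsius)")
  x <- (tl - topt) / (tl * GAS_CONSTANT * topt)
  kopt * hd * exp(ea * x) / (hd - ea * (1 - exp(hd * x)))
}

#' Rubisco-limited net assimilation
#'
#' \deqn{A_c = V_{cmax} \frac{C_i - \Gamma^*}{C_i + K_c (1 + O/K_o)} - R_L}
#'
#' @param vcmax maximum carboxylation rate at the curve temperature
#'   (umol CO2 m-2 s-1).
#' @param ci intercellular CO2 (umol mol-1).
#' @param o O2 mole fraction (umol mol-1), default 210000.
#' @param kc,ko,gammastar Rubisco constants evaluated at the same leaf
#'   temperature (umol mol-1), e.g. from [kineticsAt()].
#' @param rl respiration in the light (umol CO2 m-2 s-1).
#' @return Net Rubisco-limited assimilation rate; equals `-rl` at
#'   `ci = gammastar` and saturates at `vcmax - rl`.
#' @export
fvcbAc <- function(vcmax, ci, o = O2_DEFAULT, kc, ko, gammastar, rl) {
  if (!all(is.finite(c(vcmax, o, kc, ko, gammastar, rl))) ||
      !all(is.finite(ci)))
    stop("fvcbAc: inputs must be finite")
  if (vcmax < 0) stop("fvcbAc: vcmax must be non-negative")
  vcmax * (ci - gammastar) / (ci + kc * (1 + o / ko)) - rl
}

#' Electron transport rate from the non-rectangular hyperbola
#'
#' Solves \eqn{\theta J^2 - J(\alpha Q + J_{max}) + \alpha Q J_{max} = 0} for
#' its lower root, the operating electron transport rate at irradiance `q`.
#'
#' @param jmax maximum electron transport rate (umol m-2 s-1).
#' @param q photosynthetic photon flux density (umol photons m-2 s-1).
#' @param alpha quantum yield of electron transport (mol electrons mol-1
#'   photons), fixed default 0.24.
#' @param theta curvature of the light response, fixed default 0.85. With
#'   `theta = 0` the expression degenerates to the rectangular hyperbola
#'   `alpha*q*jmax/(alpha*q + jmax)`.
#' @return Electron transport rate J, with `0 <= J <= min(alpha*q, jmax)`.
#' @export
electronTransport <- function(jmax, q = 1800, alpha = 0.24, theta = 0.85) {
  if (!all(is.finite(c(jmax, alpha, theta))) || !all(is.finite(q)))
    stop("electronTransport: inputs must be finite")
  if (jmax <= 0) stop("electronTransport: jmax must be positive")
  if (q < 0 || any(q < 0)) stop("electronTransport: q must be non-negative")
  aq <- alpha * q
  if (theta < 1e-10) return(aq * jmax / (aq + jmax))
  disc <- (aq + jmax)^2 - 4 * theta * aq * jmax
  if (any(disc < 0)) stop("electronTransport: negative discriminant")
  ((aq + jmax) - sqrt(disc)) / (2 * theta)
}

#' RuBP-regeneration-limited net assimilation
#'
#' \deqn{A_j = \frac{J}{4} \frac{C_i - \Gamma^*}{C_i + 2\Gamma^*} - R_L}
#'
#' @param j electron transport rate (umol m-2 s-1), see [electronTransport()].
#' @param ci intercellular CO2 (umol mol-1).
#' @param gammastar photorespiratory compensation point at the curve
#'   temperature (umol mol-1).
#' @param rl respiration in the light (umol CO2 m-2 s-1).
#' @return Net RuBP-regeneration-limited rate; equals `-rl` at
#'   `ci = gammastar` and saturates at `j/4 - rl`.
#' @export
fvcbAj <- function(j, ci, gammastar, rl) {
  if (!all(is.finite(c(j, gammastar, rl))) || !all(is.finite(ci)))
    stop("fvcbAj: inputs must be finite")
  if (j < 0) stop("fvcbAj: j must be non-negative")
  j / 4 * (ci - gammastar) / (ci + 2 * gammastar) - rl
}

#' FvCB net assimilation (minimum of the two limitations)
#'
#' Forward model for one observation: evaluates the Rubisco-limited and
#' RuBP-regeneration-limited rates at `ci` and returns their strict minimum
#' together with the limiting process. Triose-phosphate limitation is not
#' modelled.
#'
#' @param vcmax,jmax capacities at the leaf temperature (umol CO2 m-2 s-1).
#' @param ci intercellular CO2 (umol mol-1), may be a vector.
#' @param o O2 mole fraction (umol mol-1).
#' @param kc,ko,gammastar Rubisco constants at the leaf temperature.
#' @param rl respiration in the light.
#' @param q,alpha,theta light parameters passed to [electronTransport()].
#' @return A data.frame with columns `anet`, `ac`, `aj`, `limiting`
#'   (`"Ac"` or `"Aj"`).
#' @export
fvcbAnet <- function(vcmax, jmax, ci, o = O2_DEFAULT, kc, ko, gammastar, rl,
                     q = 1800, alpha = 0.24, theta = 0.85) {
  j <- electronTransport(jmax, q = q, alpha = alpha, theta = theta)
  ac <- fvcbAc(vcmax, ci, o, kc, ko, gammastar, rl)
  aj <- fvcbAj(j, ci, gammastar, rl)
  data.frame(anet = pmin(ac, aj), ac = ac, aj = aj,
             limiting = ifelse(ac <= aj, "Ac", "Aj"))
}

#' Quadratic thermal response of net photosynthesis
#'
#' \eqn{A_{growth}(T_l) = a T_l^2 + b T_l + c} with `tl` in degrees C, and its
#' closed-form optimum \eqn{T_{optA} = -b / 2a},
#' \eqn{A_{opt} = A_{growth}(T_{optA})} (requires `a < 0`).
#'
#' @param a,b,c quadratic coefficients.
#' @param tl leaf temperature(s), degrees C.
#' @return `quadraticAgrowth()`: the rate(s) at `tl`. `toptFromQuadratic()`: a
#'   list with `topta` (degrees C) and `aopt`.
#' @export
quadraticAgrowth <- function(a, b, c, tl) {
  if (!all(is.finite(c(a, b, c))) || !all(is.finite(tl)))
    stop("quadraticAgrowth: inputs must be finite")
  a * tl^2 + b * tl + c
}

#' @rdname quadraticAgrowth
#' @export
toptFromQuadratic <- function(a, b, c) {
  if (!all(is.finite(c(a, b, c)))) stop("toptFromQuadratic: inputs must be finite")
  if (a >= 0)
    stop("toptFromQuadratic: no thermal optimum unless a < 0")
  topta <- -b / (2 * a)
  list(topta = topta, aopt = quadraticAgrowth(a, b, c, topta))
}
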