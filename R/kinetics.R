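#' Temperature-dependent Rubisco kinetic constants
#'
#' A `KineticsSet` bundles the Michaelis constants of Rubisco for CO2 (`kc25`)
#' and O2 (`ko25`), the photorespiratory CO2 compensation point (`gammastar25`),
#' a basal rate of respiration in the light (`rl25`), and the activation
#' energies that govern their exponential temperature responses. All
#' concentrations are mole fractions in umol mol-1 (so O2 at 21 percent is
#' 210000), rates in umol CO2 m-2 s-1, energies in J mol-1, reference
#' temperature 25 degrees C.
#'
#' @param name label for the set.
#' @param kc25,ko25,gammastar25 Michaelis constants and compensation point at
#'   25 degrees C (umol mol-1).
#' @param rl25 respiration in the light at 25 degrees C (umol CO2 m-2 s-1).
#' @param ea_kc,ea_ko,ea_gammastar,ea_rl activation energies (J mol-1).
#' @return An object of class `KineticsSet`.
#' @seealso [loadKinetics()] for the shipped presets, [kineticsAt()] to
#'   evaluate a set at a leaf temperature.
#' @export
kineticsSet <- function(name, kc25, ko25, gammastar25, rl25,
                        ea_kc, ea_ko, ea_gammastar, ea_rl) {
  vals <- c(kc25 = kc25, ko25 = ko25, gammastar25 = gammastar25, rl25 = rl25)
  eas <- c(ea_kc = ea_kc, ea_ko = ea_ko, ea_gammastar = ea_gammastar,
           ea_rl = ea_rl)
  if (!all(is.finite(vals)) || !all(is.finite(eas)))
    stop("kinetic constants must be finite")
  if (any(vals[c("kc25", "ko25", "gammastar25")] <= 0))
    stop("kc25, ko25 and gammastar25 must be positive")
  if (rl25 < 0) stop("rl25 must be non-negative")
  if (any(eas < 0)) stop("activation energies must be non-negative")
  structure(c(list(name = name), as.list(vals), as.list(eas)),
            class = "KineticsSet")
}

#' @export
print.KineticsSet <- function(x, ...) {
  cat("<KineticsSet>", x$name, "\n")
  cat(sprintf("  Kc(25)      = %8.1f umol mol-1  (Ea %6.0f J mol-1)\n",
              x$kc25, x$ea_kc))
  cat(sprintf("  Ko(25)      = %8.0f umol mol-1  (Ea %6.0f J mol-1)\n",
              x$ko25, x$ea_ko))
  cat(sprintf("  Gamma*(25)  = %8.2f umol mol-1  (Ea %6.0f J mol-1)\n",
              x$gammastar25, x$ea_gammastar))
  cat(sprintf("  RL(25)      = %8.2f umol m-2 s-1 (Ea %6.0f J mol-1)\n",
              x$rl25, x$ea_rl))
  invisible(x)
}

#' Load a named kinetics preset
#'
#' Presets are stored as a plain-text table under `inst/extdata`. The
#' `"tobacco"` set carries the standard in-vivo tobacco constants used
#' throughout C3 A/Ci fitting; `"rice"` and `"potato"` are representative
#' stand-in sets (see the `source` column of the table) intended for the
#' kinetics sensitivity analysis, not for parameter ground truth.
#'
#' @param name one of the names in [listKinetics()].
#' @return A [kineticsSet()] object.
#' @export
loadKinetics <- function(name = "tobacco") {
  tab <- kineticsTable()
  if (!name %in% unique(tab$name))
    stop("unknown kinetics preset '", name, "'; available: ",
         paste(unique(tab$name), collapse = ", "))
  rows <- tab[tab$name == name, ]
  vals <- stats::setNames(rows$value, rows$constant)
  kineticsSet(name,
              kc25 = vals[["kc25"]], ko25 = vals[["ko25"]],
              gammastar25 = vals[["gammastar25"]], rl25 = vals[["rl25"]],
              ea_kc = vals[["ea_kc"]], ea_ko = vals[["ea_ko"]],
              ea_gammastar = vals[["ea_gammastar"]], ea_rl = vals[["ea_rl"]])
}

#' @rdname loadKinetics
#' @export
listKinetics <- function() unique(kineticsTable()$name)

kineticsTable <- function() {
  path <- system.file("extdata", "kinetics_presets.tsv", package = "acitherm")
  if (path == "") path <- file.path("inst", "extdata", "kinetics_presets.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Evaluate kinetic constants at a leaf temperature
#'
#' Applies the exponential Arrhenius adjustment ([arrheniusAdjust()]) to each
#' constant of a [kineticsSet()], returning the constants at `tleaf`.
#'
#' @param kin a `KineticsSet`.
#' @param tleaf leaf temperature (degrees C).
#' @return A list with elements `kc`, `ko`, `gammastar`, `rl` at `tleaf`.
#' @export
kineticsAt <- function(kin, tleaf) {
  stopifnot(inherits(kin, "KineticsSet"))
  list(kc = arrheniusAdjust(kin$kc25, kin$ea_kc, tleaf),
       ko = arrheniusAdjust(kin$ko25, kin$ea_ko, tleaf),
       gammastar = arrheniusAdjust(kin$gammastar25, kin$ea_gammastar, tleaf),
       rl = arrheniusAdjust(kin$rl25, kin$ea_rl, tleaf))
}
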