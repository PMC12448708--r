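#' Refit a study under alternative Rubisco kinetics
#'
#' Robustness check for the choice of kinetic constants: refits every curve
#' with a different named preset and joins the original and alternative
#' estimates per curve, with relative differences. The question it answers is
#' whether treatment contrasts depend on the kinetics assumed, so rank
#' preservation across curves is the quantity of interest, not absolute
#' parity.
#'
#' @param study long-format gas-exchange table.
#' @param kinetics_name alternative preset name (see [listKinetics()]).
#' @param baseline baseline preset name (default `"tobacco"`).
#' @param fits optional precomputed [fitStudyACi()] table under the baseline,
#'   to avoid refitting it.
#' @param ... passed to [fitStudyACi()].
#' @return data.frame with per-curve baseline and alternative `vcmax`/`jmax`
#'   and their relative differences.
#' @export
refitWithKinetics <- function(study, kinetics_name, baseline = "tobacco",
                              fits = NULL, ...) {
  alt_kin <- loadKinetics(kinetics_name)  # errors listing presets if unknown
  if (nrow(study) == 0) {
    return(data.frame(tree_id = character(), year = integer(),
                      tleaf = numeric(), vcmax = numeric(), jmax = numeric(),
                      vcmax_alt = numeric(), jmax_alt = numeric(),
                      vcmax_rel_diff = numeric(), jmax_rel_diff = numeric()))
  }
  if (is.null(fits)) fits <- fitStudyACi(study, kin = loadKinetics(baseline), ...)
  alt <- fitStudyACi(study, kin = alt_kin, ...)
  key <- paste(fits$tree_id, fits$year, fits$tleaf)
  akey <- paste(alt$tree_id, alt$year, alt$tleaf)
  m <- match(key, akey)
  out <- fits[, c("tree_id", "species", "year", "tgrow", "cgrow", "tleaf",
                  "vcmax", "jmax", "accepted")]
  out$vcmax_alt <- alt$vcmax[m]
  out$jmax_alt <- alt$jmax[m]
  out$accepted_alt <- alt$accepted[m]
  out$vcmax_rel_diff <- (out$vcmax_alt - out$vcmax) / out$vcmax
  out$jmax_rel_diff <- (out$jmax_alt - out$jmax) / out$jmax
  out
}

#' Correct intercellular CO2 for cuticular conductance
#'
#' Gas-exchange systems attribute all water loss to stomata; if a cuticular
#' conductance `gcw` carries part of it, the stomatal (and hence CO2)
#' conductance is overestimated and Ci with it. The standard correction
#' removes the cuticular pathway from the water conductance before converting
#' to CO2 units. Writing the measured CO2 supply as
#' `A = (gsw/1.6) (Ca - Ci)`, the corrected intercellular CO2 is
#' \deqn{C_i' = C_a - (C_a - C_i)\,\frac{g_{sw}}{g_{sw} - g_{cw}}}
#' which returns the curve unchanged at `gcw = 0`, is continuous and
#' decreasing in `gcw`, and shifts low-conductance curves the most.
#'
#' @param curve data.frame with columns `ca`, `ci`, `gs` (mol H2O m-2 s-1).
#' @param gcw cuticular conductance to water (mmol H2O m-2 s-1; reported
#'   leaf values span roughly 5 to 20).
#' @return The curve with `ci` replaced by the corrected values.
#' @export
cuticularCorrect <- function(curve, gcw) {
  stopifnot(is.data.frame(curve), all(c("ca", "ci", "gs") %in% names(curve)))
  if (!is.finite(gcw) || gcw < 0) stop("cuticularCorrect: gcw must be >= 0")
  g <- gcw / 1000  # mmol -> mol
  if (any(g >= curve$gs))
    stop("cuticularCorrect: gcw must be below the measured total conductance")
  curve$ci <- curve$ca - (curve$ca - curve$ci) * curve$gs / (curve$gs - g)
  curve
}
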