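#' Configuration for a synthetic climate-manipulation study
#'
#' Defines the design and generative parameters of a simulated growth-CO2 by
#' growth-temperature experiment: two measurement years (independent seedling
#' cohorts), five boreal species, six treatment cells (0T/4T/8T warming by
#' AC 410 / EC 750 ppm growth CO2), several trees per species-treatment cell,
#' A/Ci curves at four leaf temperatures over the standard 12-step CO2
#' sequence (starting at 400, dipping to 50, recovering at 400 and rising to
#' 2000 umol mol-1) at saturating light.
#'
#' Treatment effects act on the ground-truth thermal-response parameters:
#' warming multiplies the optimal rates of Vcmax and Jmax (defaults 0.90 at
#' +4 C, 0.70 at +8 C); growth CO2 leaves them untouched by default. The
#' thermal-optimum shift of Agrowth under elevated CO2 is not injected
#' directly: it emerges from reduced photorespiration at the higher operating
#' Ca. An optional `topt_shift_per_degc` knob can add a warming shift of the
#' capacity optima (default 0, i.e. off).
#'
#' @param seed mandatory RNG seed; every random draw of the study flows from
#'   it.
#' @param n_trees trees per species x treatment x year (default 5).
#' @param years measurement years (default 2019 and 2021; cohorts are
#'   independent).
#' @param species species labels (default the five boreal study species).
#' @param tleaf leaf temperatures of the curve series (degrees C).
#' @param ca_seq the stepped ambient CO2 sequence (umol mol-1).
#' @param noise_sd additive Gaussian noise on Anet (umol CO2 m-2 s-1).
#' @param tree_sd_frac lognormal tree random-intercept SD as a fraction of
#'   the optimal rate (default 0.10).
#' @param ci_ca_target operating Ci/Ca ratio of the stomatal supply closure.
#' @param kopt_mult named multipliers of the capacity optima per warming
#'   level.
#' @param co2_kopt_mult named multipliers per CO2 level (default no effect).
#' @param topt_shift_per_degc optional shift (degrees C of optimum per degree
#'   C of warming) applied to the Vcmax/Jmax thermal optima; default 0.
#' @param corrupt_fraction fraction of curves given one negative-Ci point
#'   (QC exercise; default 0).
#' @param q measurement irradiance (umol photons m-2 s-1).
#' @return Object of class `StudyConfig`.
#' @export
studyConfig <- function(seed,
                        n_trees = 5,
                        years = c(2019, 2021),
                        species = c("white_spruce", "black_spruce",
                                    "jack_pine", "tamarack", "paper_birch"),
                        tleaf = c(10, 20, 30, 40),
                        ca_seq = c(400, 300, 200, 150, 100, 50, 400, 600,
                                   800, 1000, 1500, 2000),
                        noise_sd = 0.5,
                        tree_sd_frac = 0.10,
                        ci_ca_target = 0.72,
                        kopt_mult = c("0T" = 1, "4T" = 0.90, "8T" = 0.70),
                        co2_kopt_mult = c(AC = 1, EC = 1),
                        topt_shift_per_degc = 0,
                        corrupt_fraction = 0,
                        q = 1800) {
  if (missing(seed)) stop("studyConfig: a seed is mandatory")
  stopifnot(n_trees >= 1, length(years) >= 1, length(species) >= 1,
            noise_sd >= 0, tree_sd_frac >= 0,
            corrupt_fraction >= 0, corrupt_fraction < 1)
  structure(list(seed = as.integer(seed), n_trees = n_trees, years = years,
                 species = species, tgrow = c("0T", "4T", "8T"),
                 cgrow = c(AC = 410, EC = 750), tleaf = tleaf,
                 ca_seq = ca_seq, noise_sd = noise_sd,
                 tree_sd_frac = tree_sd_frac, ci_ca_target = ci_ca_target,
                 kopt_mult = kopt_mult, co2_kopt_mult = co2_kopt_mult,
                 topt_shift_per_degc = topt_shift_per_degc,
                 corrupt_fraction = corrupt_fraction, q = q),
            class = "StudyConfig")
}

#' @export
print.StudyConfig <- function(x, ...) {
  cat("<StudyConfig> seed", x$seed, "\n")
  cat(sprintf("  %d year(s) x %d species x 6 treatments x %d trees x %d Tleaf x %d CO2 steps = %d rows\n",
              length(x$years), length(x$species), x$n_trees,
              length(x$tleaf), length(x$ca_seq),
              length(x$years) * length(x$species) * 6 * x$n_trees *
                length(x$tleaf) * length(x$ca_seq)))
  cat("  warming kopt multipliers:",
      paste(names(x$kopt_mult), x$kopt_mult, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# species-level baseline thermal-response truths; rates at the optimum in
# umol m-2 s-1, optima in K, energies in J mol-1
speciesBaselines <- function(species) {
  base <- data.frame(
    species = c("white_spruce", "black_spruce", "jack_pine", "tamarack",
                "paper_birch"),
    kopt_v = c(85, 80, 90, 95, 110),
    kopt_j = c(130, 120, 135, 145, 165),
    topt_v = 35 + KELVIN0,
    topt_j = 31 + KELVIN0,
    ea_v = 60000, ea_j = 43000, rl25 = 1.0,
    stringsAsFactors = FALSE)
  out <- base[match(species, base$species), ]
  # unlisted species fall back to the mid-range baseline
  miss <- is.na(out$kopt_v)
  if (any(miss)) {
    out[miss, -1] <- base[3, -1]
    out$species[miss] <- species[miss]
  }
  rownames(out) <- NULL
  out
}

#' Draw the ground-truth parameters of a synthetic study
#'
#' Assigns each tree its true peaked-Arrhenius parameters for Vcmax and Jmax
#' and its true basal respiration: species baselines, multiplied by the
#' configured treatment effects, with a shared lognormal tree random
#' intercept (SD `tree_sd_frac`) and small tree-level jitter on the thermal
#' optima and activation energies. Fully reproducible from `(config, seed)`.
#'
#' @param config a [studyConfig()].
#' @return data.frame, one row per tree x year, class `GroundTruth`.
#' @export
assignTrueParameters <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  cells <- expand.grid(rep = seq_len(config$n_trees),
                       cgrow = names(config$cgrow), tgrow = config$tgrow,
                       species = config$species, year = config$years,
                       stringsAsFactors = FALSE)
  base <- speciesBaselines(cells$species)
  dT <- c("0T" = 0, "4T" = 4, "8T" = 8)[cells$tgrow]
  mult <- unname(config$kopt_mult[cells$tgrow] *
                   config$co2_kopt_mult[cells$cgrow])
  truth <- withSeed(config$seed, {
    n <- nrow(cells)
    sdlog <- sqrt(log(1 + config$tree_sd_frac^2))
    intercept <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    data.frame(
      tree_id = sprintf("%s_%s_%s_%d_t%02d", abbreviate(cells$species, 6),
                        cells$tgrow, cells$cgrow, cells$year, cells$rep),
      species = cells$species, year = cells$year, tgrow = cells$tgrow,
      cgrow = cells$cgrow,
      kopt_v = base$kopt_v * mult * intercept,
      topt_v = base$topt_v + config$topt_shift_per_degc * dT +
        stats::rnorm(n, 0, 0.7),
      ea_v = base$ea_v * stats::rlnorm(n, 0, 0.05),
      kopt_j = base$kopt_j * mult * intercept,
      topt_j = base$topt_j + config$topt_shift_per_degc * dT +
        stats::rnorm(n, 0, 0.7),
      ea_j = base$ea_j * stats::rlnorm(n, 0, 0.05),
      rl25 = base$rl25 * stats::rlnorm(n, 0, 0.1),
      stringsAsFactors = FALSE)
  })
  class(truth) <- c("GroundTruth", "data.frame")
  truth
}

#' Generate the gas-exchange table of a synthetic study
#'
#' Produces one row per tree x leaf temperature x CO2 step. Intercellular CO2
#' follows a fixed-ratio stomatal supply closure (`ci = ci_ca_target * ca`);
#' net assimilation comes from the FvCB forward model at the tree's true
#' parameters (capacities evaluated at the leaf temperature through the
#' peaked Arrhenius truth, respiration Arrhenius-adjusted), plus additive
#' Gaussian measurement noise; stomatal conductance to water is back-computed
#' from the CO2 gradient with the 1.6 diffusivity ratio. Cosmetic leaf-trait
#' columns (`lma`, `narea`) and a leaf-to-air `vpd` column are emitted so
#' trait ANOVAs can be exercised; their generative model is declared
#' cosmetic. Optionally a seeded fraction of curves receives one negative-Ci
#' point to exercise QC.
#'
#' @param config a [studyConfig()].
#' @param truth optional [assignTrueParameters()] output (drawn from
#'   `config` if omitted).
#' @param kin kinetics preset used by the forward model.
#' @return Long-format data.frame with columns `tree_id, species, year,
#'   tgrow, cgrow, tleaf, ca, ci, anet, gs, q, step_index, lma, narea, vpd`.
#'   Attribute `"corrupt_curves"` lists curves given a negative-Ci point.
#' @export
generateStudy <- function(config, truth = NULL,
                          kin = loadKinetics("tobacco")) {
  stopifnot(inherits(config, "StudyConfig"))
  if (is.null(truth)) truth <- assignTrueParameters(config)
  n_steps <- length(config$ca_seq)
  n_tl <- length(config$tleaf)
  per_tree <- n_tl * n_steps

  idx <- rep(seq_len(nrow(truth)), each = per_tree)
  tl <- rep(rep(config$tleaf, each = n_steps), times = nrow(truth))
  step <- rep(seq_len(n_steps), times = nrow(truth) * n_tl)
  ca <- config$ca_seq[step]
  ci <- config$ci_ca_target * ca
  tk <- tl + KELVIN0

  kc <- arrheniusAdjust(kin$kc25, kin$ea_kc, tl)
  ko <- arrheniusAdjust(kin$ko25, kin$ea_ko, tl)
  gstar <- arrheniusAdjust(kin$gammastar25, kin$ea_gammastar, tl)

  vcmax <- peakedArrheniusRows(truth$kopt_v[idx], truth$topt_v[idx],
                               truth$ea_v[idx], tk)
  jmax <- peakedArrheniusRows(truth$kopt_j[idx], truth$topt_j[idx],
                              truth$ea_j[idx], tk)
  rl <- arrheniusAdjust(truth$rl25[idx], kin$ea_rl, tl)
  aq <- 0.24 * config$q
  jj <- ((aq + jmax) - sqrt((aq + jmax)^2 - 4 * 0.85 * aq * jmax)) /
    (2 * 0.85)
  ac <- vcmax * (ci - gstar) / (ci + kc * (1 + O2_DEFAULT / ko)) - rl
  aj <- jj / 4 * (ci - gstar) / (ci + 2 * gstar) - rl
  anet_true <- pmin(ac, aj)

  study <- withSeed(config$seed + 1L, {
    anet <- anet_true + stats::rnorm(length(anet_true), 0, config$noise_sd)
    n_trees_total <- nrow(truth)
    lma_base <- ifelse(truth$species == "paper_birch", 45, 180)
    dT <- c("0T" = 0, "4T" = 4, "8T" = 8)[truth$tgrow]
    lma_tree <- lma_base * (1 - 0.02 * dT) *
      stats::rlnorm(n_trees_total, 0, 0.08)
    narea_tree <- ifelse(truth$species == "paper_birch", 1.8, 3.2) *
      (1 - 0.025 * dT) * stats::rlnorm(n_trees_total, 0, 0.08)
    df <- data.frame(
      tree_id = truth$tree_id[idx], species = truth$species[idx],
      year = truth$year[idx], tgrow = truth$tgrow[idx],
      cgrow = truth$cgrow[idx], tleaf = tl, ca = ca, ci = ci, anet = anet,
      gs = 1.6 * pmax(anet, 0.05) / (ca - ci), q = config$q,
      step_index = step, lma = lma_tree[idx], narea = narea_tree[idx],
      vpd = round(0.35 * exp(0.06 * tl), 3), stringsAsFactors = FALSE)
    corrupt <- character()
    if (config$corrupt_fraction > 0) {
      curve_key <- paste(df$tree_id, df$tleaf, sep = "@")
      curves <- unique(curve_key)
      n_bad <- round(config$corrupt_fraction * length(curves))
      if (n_bad > 0) {
        corrupt <- sample(curves, n_bad)
        # poison the lowest-Ca step of each chosen curve
        bad_rows <- df$step_index == which.min(config$ca_seq) &
          curve_key %in% corrupt
        df$ci[bad_rows] <- -12
      }
    }
    attr(df, "corrupt_curves") <- corrupt
    df
  })
  attr(study, "truth") <- truth
  study
}

# vectorised peaked Arrhenius where the parameters vary by row
peakedArrheniusRows <- function(kopt, topt, ea, tl, hd = 200000) {
  x <- (tl - topt) / (tl * GAS_CONSTANT * topt)
  kopt * hd * exp(ea * x) / (hd - ea * (1 - exp(hd * x)))
}

#' Drop whole curves at random
#'
#' Emulates the unbalanced per-cell sample sizes of a real campaign by
#' removing complete curves (a tree x leaf-temperature series), never single
#' points. Seeded and deterministic.
#'
#' @param study table from [generateStudy()].
#' @param rate fraction of curves to drop, in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return The table minus the dropped curves.
#' @export
injectMissingness <- function(study, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5)
    stop("injectMissingness: rate must be in [0, 0.5)")
  if (rate == 0) return(study)
  key <- paste(study$tree_id, study$year, study$tleaf, sep = "@")
  curves <- unique(key)
  drop <- withSeed(seed, sample(curves, round(rate * length(curves))))
  study[!key %in% drop, , drop = FALSE]
}
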