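# shared fixtures: the stepped CO2 sequence and forward-model toy curves

CA_SEQ <- c(400, 300, 200, 150, 100, 50, 400, 600, 800, 1000, 1500, 2000)

tobaccoAt <- function(tleaf = 25) kineticsAt(loadKinetics("tobacco"), tleaf)

# noiseless (or noisy) forward-model curve at one leaf temperature
makeCurve <- function(vcmax = 50, jmax = 100, rl = 1, tleaf = 25,
                      noise_sd = 0, ca = CA_SEQ, ci_ca = 0.72, seed = NULL) {
  kat <- tobaccoAt(tleaf)
  ci <- ci_ca * ca
  fm <- fvcbAnet(vcmax, jmax, ci, kc = kat$kc, ko = kat$ko,
                 gammastar = kat$gammastar, rl = rl)
  anet <- fm$anet
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    anet <- anet + rnorm(length(anet), 0, noise_sd)
  }
  data.frame(ci = ci, anet = anet, ca = ca, tleaf = tleaf, q = 1800,
             step_index = seq_along(ca))
}

# brute-force SSR over a (vcmax, jmax) grid with rl fixed; the independent
# oracle for the NLS fitter
gridSearchACi <- function(curve, vc_grid, jm_grid, rl = 1, tleaf = 25) {
  kat <- tobaccoAt(tleaf)
  ci <- curve$ci
  denom <- ci + kat$kc * (1 + 210000 / kat$ko)
  ac_part <- (ci - kat$gammastar) / denom          # per point, times vcmax
  aj_frac <- (ci - kat$gammastar) / (ci + 2 * kat$gammastar)
  aq <- 0.24 * 1800
  best <- c(ssr = Inf, vcmax = NA, jmax = NA)
  for (jm in jm_grid) {
    J <- ((aq + jm) - sqrt((aq + jm)^2 - 4 * 0.85 * aq * jm)) / (2 * 0.85)
    aj <- J / 4 * aj_frac - rl
    ac_mat <- outer(vc_grid, ac_part) - rl          # n_vc x n_points
    pred <- pmin(ac_mat, matrix(aj, nrow = length(vc_grid),
                                ncol = length(ci), byrow = TRUE))
    ssr <- rowSums((matrix(curve$anet, nrow = length(vc_grid),
                           ncol = length(ci), byrow = TRUE) - pred)^2)
    k <- which.min(ssr)
    if (ssr[k] < best["ssr"]) best <- c(ssr = ssr[k], vcmax = vc_grid[k],
                                        jmax = jm)
  }
  best
}

tinyConfig <- function(seed = 1, ...) {
  studyConfig(seed = seed, n_trees = 2, years = 2019,
              species = "black_spruce", ...)
}
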