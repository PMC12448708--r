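#' Fit a peaked Arrhenius temperature response
#'
#' Fits [peakedArrhenius()] to (leaf temperature, rate) points for one tree and
#' process (Vcmax or Jmax), with the deactivation energy held at
#' `hd = 200000` J mol-1 to avoid over-parameterization. Free parameters are
#' `kopt`, `topt` (bounded to `[273.15, 333.15]` K) and `ea` (bounded to
#' `(0, 199999]`). Starts are deterministic (optimum seeded at the warmest /
#' best-observed temperature, activation energy over a coarse grid), so
#' repeated fits are identical.
#'
#' @param tleaf leaf temperatures (degrees C), at least 3 distinct values.
#' @param rate process rates at `tleaf` (umol CO2 m-2 s-1).
#' @param process label, `"Vcmax"`, `"Jmax"` or other.
#' @param hd fixed deactivation energy (J mol-1).
#' @return Object of class `ThermalResponseFit` with `kopt`, `topt` (K),
#'   `ea`, `hd`, `value_at_20`, `ssr`, `n` and `flags`
#'   (`"topt_extrapolated"` when the optimum falls on a bound or more than
#'   15 degrees C outside the measured range; `"degenerate_flat"` when the
#'   response is essentially flat).
#' @export
fitPeaked <- function(tleaf, rate, process = "Vcmax", hd = 200000) {
  ok <- is.finite(tleaf) & is.finite(rate)
  tleaf <- tleaf[ok]; rate <- rate[ok]
  if (length(unique(tleaf)) < 3)
    stop("fitPeaked: unfittable, fewer than 3 distinct temperatures")
  if (any(rate <= 0)) stop("fitPeaked: rates must be positive")
  tk <- tleaf + KELVIN0
  resid_fn <- function(p) rate - peakedArrhenius(p[1], p[2], p[3], hd, tk)
  lower <- c(1e-6, KELVIN0, 1)
  upper <- c(Inf, KELVIN0 + 60, 199999)
  t_best <- tk[which.max(rate)]
  starts <- list()
  for (t0 in unique(pmin(pmax(c(t_best, t_best + 5), lower[2]), upper[2])))
    for (ea0 in c(30000, 60000, 90000))
      starts[[length(starts) + 1]] <- c(max(rate), t0, ea0)
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12) {
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
    }
  }
  if (is.null(best)) stop("fitPeaked: optimizer failed on all starts")
  kopt <- best$par[1]; topt <- best$par[2]; ea <- best$par[3]
  flags <- character()
  if (topt <= lower[2] + 1e-6 || topt >= upper[2] - 1e-6 ||
      topt < min(tk) - 15 || topt > max(tk) + 15)
    flags <- c(flags, "topt_extrapolated")
  if (ea < 1000 || diff(range(rate)) < 1e-8 * max(rate))
    flags <- c(flags, "degenerate_flat")
  structure(list(process = process, model = "peaked_arrhenius",
                 kopt = kopt, topt = topt, ea = ea, hd = hd,
                 value_at_20 = peakedArrhenius(kopt, topt, ea, hd,
                                               20 + KELVIN0),
                 ssr = best$ssr, n = length(rate), flags = flags),
            class = "ThermalResponseFit")
}

#' Fit the quadratic thermal response of Agrowth
#'
#' Ordinary least squares of `agrowth` on leaf temperature and its square;
#' the thermal optimum `topta = -b/(2a)` and the rate there (`aopt`) follow
#' in closed form when the curvature is negative.
#'
#' @param tleaf leaf temperatures (degrees C), at least 3 distinct values.
#' @param agrowth net assimilation at growth CO2 (umol CO2 m-2 s-1).
#' @return Object of class `ThermalResponseFit` with coefficients `a`, `b`,
#'   `c`, derived `topta` and `aopt` (NA with flag `"no_optimum"` when
#'   `a >= 0`), `value_at_20`, `ssr`, `n`.
#' @export
fitQuadraticAgrowth <- function(tleaf, agrowth) {
  ok <- is.finite(tleaf) & is.finite(agrowth)
  tleaf <- tleaf[ok]; agrowth <- agrowth[ok]
  if (length(unique(tleaf)) < 3)
    stop("fitQuadraticAgrowth: unfittable, fewer than 3 distinct temperatures")
  fit <- stats::lm(agrowth ~ tleaf + I(tleaf^2))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)))
    stop("fitQuadraticAgrowth: rank-deficient design")
  a <- cf[[3]]; b <- cf[[2]]; cc <- cf[[1]]
  flags <- character()
  if (a >= 0) {
    flags <- c(flags, "no_optimum")
    topta <- NA_real_; aopt <- NA_real_
  } else {
    opt <- toptFromQuadratic(a, b, cc)
    topta <- opt$topta; aopt <- opt$aopt
  }
  structure(list(process = "Agrowth", model = "quadratic",
                 a = a, b = b, c = cc, topta = topta, aopt = aopt,
                 value_at_20 = quadraticAgrowth(a, b, cc, 20),
                 ssr = sum(stats::resid(fit)^2), n = length(agrowth),
                 flags = flags),
            class = "ThermalResponseFit")
}

#' @export
print.ThermalResponseFit <- function(x, ...) {
  cat("<ThermalResponseFit>", x$process, "-", x$model, "\n")
  if (x$model == "peaked_arrhenius") {
    cat(sprintf("  kopt = %.2f  Topt = %.2f C  Ea = %.0f  (Hd fixed %.0f)\n",
                x$kopt, x$topt - KELVIN0, x$ea, x$hd))
  } else {
    cat(sprintf("  a = %.4f  b = %.3f  c = %.3f  ToptA = %.2f C  Aopt = %.2f\n",
                x$a, x$b, x$c, x$topta, x$aopt))
  }
  cat(sprintf("  value at 20 C = %.2f  SSR = %.4g  n = %d\n",
              x$value_at_20, x$ssr, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Standardise a fitted thermal response to 20 degrees C
#'
#' Evaluates the fitted response at the 20 degrees C reference (293.15 K for
#' the peaked Arrhenius), giving the basal rates Vcmax20 / Jmax20 that the
#' treatment comparisons are made on. `ratioJV()` forms Jmax20/Vcmax20 and
#' propagates flags from either fit.
#'
#' @param fit a `ThermalResponseFit`.
#' @return `standardiseAt20()`: the rate at 20 degrees C.
#' @export
standardiseAt20 <- function(fit) {
  stopifnot(inherits(fit, "ThermalResponseFit"))
  fit$value_at_20
}

#' @rdname standardiseAt20
#' @param fitJ,fitV `ThermalResponseFit` objects for Jmax and Vcmax.
#' @return `ratioJV()`: a list with `ratio` (Jmax20/Vcmax20) and `flags`.
#' @export
ratioJV <- function(fitJ, fitV) {
  flags <- unique(c(fitJ$flags, fitV$flags))
  list(ratio = standardiseAt20(fitJ) / standardiseAt20(fitV), flags = flags)
}

#' Bootstrap standard errors for thermal-response parameters
#'
#' Nonparametric bootstrap over the temperature points (resampling with
#' replacement, redrawing when fewer than 3 distinct temperatures land in a
#' resample), refitting and summarising the derived parameters. Seeded and
#' deterministic.
#'
#' @param tleaf,rate the points the original fit used (degrees C, rate).
#' @param process passed to [fitPeaked()] (`"Agrowth"` uses the quadratic).
#' @param B number of resamples (default 500).
#' @param seed RNG seed.
#' @return data.frame of bootstrap standard errors per derived parameter.
#' @export
bootstrapThermal <- function(tleaf, rate, process = "Vcmax", B = 500,
                             seed = 1L) {
  quad <- identical(process, "Agrowth")
  draws <- withSeed(seed, {
    out <- vector("list", B)
    for (b in seq_len(B)) {
      for (try in 1:50) {
        idx <- sample.int(length(tleaf), replace = TRUE)
        if (length(unique(tleaf[idx])) >= 3) break
      }
      fit <- tryCatch(
        if (quad) fitQuadraticAgrowth(tleaf[idx], rate[idx])
        else fitPeaked(tleaf[idx], rate[idx], process = process),
        error = function(e) NULL)
      if (is.null(fit)) next
      out[[b]] <- if (quad) {
        c(topta = fit$topta, aopt = fit$aopt, value_at_20 = fit$value_at_20)
      } else {
        c(kopt = fit$kopt, topt = fit$topt, ea = fit$ea,
          value_at_20 = fit$value_at_20)
      }
    }
    out
  })
  mat <- do.call(rbind, draws)
  data.frame(parameter = colnames(mat),
             se = apply(mat, 2, stats::sd, na.rm = TRUE),
             n_boot = nrow(mat), row.names = NULL)
}

#' Derive per-tree thermal-response parameters for a whole study
#'
#' Takes the per-curve table from [fitStudyACi()], keeps QC-accepted curves,
#' and fits, per tree and year: the peaked Arrhenius response of Vcmax and
#' Jmax across the measured leaf temperatures, and the quadratic response of
#' Agrowth. Returns the tidy parameter table that the treatment ANOVAs run on.
#'
#' @param fits per-curve table from [fitStudyACi()].
#' @param min_temps minimum distinct leaf temperatures required (default 3).
#' @return data.frame, one row per tree x year, with columns
#'   `kopt_v`, `topt_v`, `ea_v`, `vcmax20`, `kopt_j`, `topt_j`, `ea_j`,
#'   `jmax20`, `jv_ratio20`, `topta`, `aopt` and flag columns. Thermal optima
#'   are reported in degrees C.
#' @export
fitStudyThermal <- function(fits, min_temps = 3) {
  acc <- fits[fits$accepted & is.finite(fits$vcmax), , drop = FALSE]
  key <- interaction(acc$tree_id, acc$year, drop = TRUE)
  rows <- lapply(split(acc, key), function(d) {
    first <- d[1, ]
    base <- data.frame(tree_id = first$tree_id, species = first$species,
                       year = first$year, tgrow = first$tgrow,
                       cgrow = first$cgrow, stringsAsFactors = FALSE)
    if (length(unique(d$tleaf)) < min_temps) return(NULL)
    fv <- tryCatch(fitPeaked(d$tleaf, d$vcmax, "Vcmax"),
                   error = function(e) NULL)
    fj <- tryCatch(fitPeaked(d$tleaf, d$jmax, "Jmax"),
                   error = function(e) NULL)
    fa <- tryCatch(fitQuadraticAgrowth(d$tleaf, d$agrowth),
                   error = function(e) NULL)
    if (is.null(fv) || is.null(fj)) return(NULL)
    jv <- ratioJV(fj, fv)
    cbind(base, data.frame(
      kopt_v = fv$kopt, topt_v = fv$topt - KELVIN0, ea_v = fv$ea,
      vcmax20 = fv$value_at_20, flags_v = paste(fv$flags, collapse = ";"),
      kopt_j = fj$kopt, topt_j = fj$topt - KELVIN0, ea_j = fj$ea,
      jmax20 = fj$value_at_20, flags_j = paste(fj$flags, collapse = ";"),
      jv_ratio20 = jv$ratio,
      topta = if (is.null(fa)) NA_real_ else fa$topta,
      aopt = if (is.null(fa)) NA_real_ else fa$aopt,
      flags_a = if (is.null(fa)) "unfittable" else
        paste(fa$flags, collapse = ";"),
      stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
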