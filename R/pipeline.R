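#' Treatment inference on a fitted study
#'
#' Runs the two analysis layers of the study design. (1) Gas-exchange layer:
#' per species and year, repeated-measures mixed ANOVA (tree random
#' intercepts, leaf temperature as a continuous covariate) on the per-curve
#' responses Agrowth, gs, Ci/Ca, Vcmax and Jmax. (2) Derived-parameter layer:
#' per species, ordinary ANOVA (each tree contributes one row per year, so
#' there is no within-tree replication) on the thermal-response parameters
#' with year, growth temperature and growth CO2 as candidate effects. Both
#' layers use AICc selection; dropped terms are reported as blank. Tukey
#' letters across the six treatment cells are computed for derived parameters
#' whose ANOVA shows a significant growth-temperature or interaction effect,
#' from a full two-way cell-means model.
#'
#' @param fits per-curve table from [fitStudyACi()] (QC-rejected curves are
#'   excluded here).
#' @param thermal per-tree table from [fitStudyThermal()].
#' @param alpha significance level for the post-hoc trigger and letters.
#' @param gas_responses,derived_responses response columns analysed in each
#'   layer.
#' @return list with `gas_anova`, `derived_anova` (long data.frames of
#'   per-term F and p with an `included` flag) and `tukey` (letter displays).
#' @export
analyzeStudy <- function(fits, thermal, alpha = 0.05,
                         gas_responses = c("agrowth", "gs_op", "ci_over_ca",
                                           "vcmax", "jmax"),
                         derived_responses = c("aopt", "topta", "kopt_v",
                                               "kopt_j", "topt_v", "topt_j",
                                               "ea_v", "ea_j", "vcmax20",
                                               "jmax20", "jv_ratio20")) {
  acc <- fits[fits$accepted, , drop = FALSE]
  gas <- list()
  for (sp in unique(acc$species)) for (yr in unique(acc$year)) {
    d <- acc[acc$species == sp & acc$year == yr, , drop = FALSE]
    if (!nrow(d)) next
    for (resp in gas_responses) {
      if (!resp %in% names(d) || all(is.na(d[[resp]]))) next
      tab <- tryCatch(
        repeatedMeasuresAnova(d, resp, c("tleaf", "tgrow", "cgrow"),
                              random = "tree_id"),
        error = function(e) NULL)
      if (is.null(tab)) next
      gas[[length(gas) + 1]] <-
        cbind(data.frame(species = sp, year = yr, response = resp,
                         stringsAsFactors = FALSE), as.data.frame(tab))
    }
  }
  derived <- list(); letters <- list()
  for (sp in unique(thermal$species)) {
    d <- thermal[thermal$species == sp, , drop = FALSE]
    d$year <- factor(d$year)
    d$treatment <- interaction(d$tgrow, d$cgrow, sep = "")
    multi_year <- length(unique(d$year)) > 1
    facs <- if (multi_year) c("year", "tgrow", "cgrow") else
      c("tgrow", "cgrow")
    for (resp in derived_responses) {
      if (!resp %in% names(d) || sum(is.finite(d[[resp]])) < 12) next
      dd <- d[is.finite(d[[resp]]), , drop = FALSE]
      tab <- tryCatch(
        repeatedMeasuresAnova(dd, resp, facs, random = NULL),
        error = function(e) NULL)
      if (is.null(tab)) next
      derived[[length(derived) + 1]] <-
        cbind(data.frame(species = sp, response = resp,
                         stringsAsFactors = FALSE), as.data.frame(tab))
      sig_trigger <- with(as.data.frame(tab),
                          any(included & grepl("tgrow", term) & !is.na(p) &
                                p < alpha))
      if (sig_trigger && length(unique(dd$treatment)) >= 2) {
        cell_model <- tryCatch(
          stats::lm(stats::reformulate("treatment", resp), data = dd),
          error = function(e) NULL)
        tk <- if (is.null(cell_model)) NULL else
          tryCatch(tukeyPosthoc(cell_model, "treatment", data = dd,
                                alpha = alpha), error = function(e) NULL)
        if (!is.null(tk))
          letters[[length(letters) + 1]] <-
            cbind(data.frame(species = sp, response = resp,
                             stringsAsFactors = FALSE), tk$letters)
      }
    }
  }
  list(gas_anova = do.call(rbind, gas),
       derived_anova = do.call(rbind, derived),
       tukey = if (length(letters)) do.call(rbind, letters) else NULL)
}

#' Qualitative treatment-effect pattern of an analysed study
#'
#' Reduces an [analyzeStudy()] result to the headline qualitative pattern the
#' synthetic generator injects: growth CO2 stimulates Agrowth but leaves
#' photosynthetic capacity unaffected, warming reduces capacity, and the
#' thermal optimum of Agrowth sits higher under elevated CO2 (an emergent
#' photorespiration effect). "Detected" means significant (term retained by
#' AICc and p below `alpha`) in at least half of the species-year analyses;
#' "absent" means significant in fewer than a third.
#'
#' @param analysis result of [analyzeStudy()].
#' @param thermal the [fitStudyThermal()] table (for the thermal-optimum
#'   shift).
#' @param alpha significance level.
#' @return list of logicals `co2_on_agrowth`, `no_co2_on_capacity`,
#'   `warming_on_capacity`, `ec_topta_shift_positive`, and `all_detected`.
#' @export
qualitativePattern <- function(analysis, thermal, alpha = 0.05) {
  ga <- analysis$gas_anova
  sig_frac <- function(response, term) {
    d <- ga[ga$response == response & ga$term == term, , drop = FALSE]
    if (!nrow(d)) return(NA_real_)
    mean(d$included & !is.na(d$p) & d$p < alpha)
  }
  co2_agrowth <- sig_frac("agrowth", "cgrow") >= 0.5
  no_co2_cap <- sig_frac("vcmax", "cgrow") < 1 / 3 &&
    sig_frac("jmax", "cgrow") < 1 / 3
  warm_cap <- sig_frac("vcmax", "tgrow") >= 0.5 &&
    sig_frac("jmax", "tgrow") >= 0.5
  shift <- mean(thermal$topta[thermal$cgrow == "EC"], na.rm = TRUE) -
    mean(thermal$topta[thermal$cgrow == "AC"], na.rm = TRUE)
  out <- list(co2_on_agrowth = isTRUE(co2_agrowth),
              no_co2_on_capacity = isTRUE(no_co2_cap),
              warming_on_capacity = isTRUE(warm_cap),
              ec_topta_shift_positive = isTRUE(shift > 0),
              ec_topta_shift_c = shift)
  out$all_detected <- out$co2_on_agrowth && out$no_co2_on_capacity &&
    out$warming_on_capacity && out$ec_topta_shift_positive
  out
}

#' Run the full synthetic-study pipeline
#'
#' simulate -> fit A/Ci curves -> QC -> thermal responses -> treatment
#' ANOVAs, deterministically from one seed. When `outdir` is given, each
#' stage's table is written as CSV with a provenance header, together with a
#' QC report (fitted/rejected counts with reasons) and a plain-text run log
#' recording the seed and package version. Re-running with the same
#' configuration reproduces every output byte for byte.
#'
#' @param config a [studyConfig()]; validated before any stage runs.
#' @param outdir optional output directory (created if needed).
#' @param kin kinetics preset.
#' @return list with `study`, `truth`, `fits`, `thermal`, `analysis`,
#'   `pattern`, `qc_summary`, invisibly.
#' @export
runPipeline <- function(config, outdir = NULL,
                        kin = loadKinetics("tobacco")) {
  if (!inherits(config, "StudyConfig"))
    stop("runPipeline: config must be a StudyConfig")
  stage <- "simulate"
  res <- tryCatch({
    study <- generateStudy(config, kin = kin)
    truth <- attr(study, "truth")
    stage <- "fit-aci"
    fits <- fitStudyACi(study, kin = kin)
    qc_summary <- qcReport(fits)
    stage <- "fit-tresponse"
    thermal <- fitStudyThermal(fits)
    stage <- "analyze"
    analysis <- analyzeStudy(fits, thermal)
    pattern <- qualitativePattern(analysis, thermal)
    list(study = study, truth = truth, fits = fits, thermal = thermal,
         analysis = analysis, pattern = pattern, qc_summary = qc_summary)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeGasExchange(res$study, file.path(outdir, "study.csv"))
    writeResultCSV(res$truth, file.path(outdir, "ground_truth.csv"), config)
    writeResultCSV(res$fits, file.path(outdir, "aci_fits.csv"), config)
    writeResultCSV(res$thermal, file.path(outdir, "thermal_fits.csv"),
                   config)
    writeResultCSV(res$analysis$gas_anova,
                   file.path(outdir, "anova_gas_exchange.csv"), config)
    writeResultCSV(res$analysis$derived_anova,
                   file.path(outdir, "anova_derived.csv"), config)
    if (!is.null(res$analysis$tukey))
      writeResultCSV(res$analysis$tukey,
                     file.path(outdir, "tukey_letters.csv"), config)
    writeResultCSV(res$qc_summary, file.path(outdir, "qc_report.csv"),
                   config)
    version <- tryCatch(as.character(utils::packageVersion("acitherm")),
                        error = function(e) "dev")
    writeLines(c(sprintf("acitherm %s", version),
                 sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", objectHash(config)),
                 sprintf("curves fitted: %d", nrow(res$fits)),
                 sprintf("curves accepted: %d", sum(res$fits$accepted))),
               file.path(outdir, "run_log.txt"))
  }
  invisible(res)
}

#' QC summary of a per-curve fit table
#'
#' @param fits table from [fitStudyACi()].
#' @return data.frame of QC outcomes (accepted and each rejection reason)
#'   with curve counts.
#' @export
qcReport <- function(fits) {
  reasons <- fits$reasons
  reasons[fits$accepted] <- "accepted"
  reasons[!nzchar(reasons)] <- "accepted"
  counts <- table(unlist(strsplit(reasons, "; ", fixed = TRUE)))
  data.frame(outcome = names(counts), n_curves = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
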