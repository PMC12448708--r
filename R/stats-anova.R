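#' Small-sample corrected Akaike Information Criterion
#'
#' \deqn{AICc = -2\,\ell + 2k + \frac{2k(k+1)}{n-k-1}}
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (including variance components).
#' @param n number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (!all(is.finite(c(loglik, k, n)))) stop("aicc: inputs must be finite")
  if (n <= k + 1) stop("aicc: undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# All marginality-respecting fixed-effect structures over the given factor
# names: every subset of {main effects, 2-way, 3-way interactions} in which
# each interaction is accompanied by its lower-order relatives. Includes the
# intercept-only model (empty character vector).
candidateStructures <- function(factors, max_order = min(3, length(factors))) {
  terms <- character()
  for (ord in seq_len(max_order)) {
    cmb <- utils::combn(factors, ord, simplify = FALSE)
    terms <- c(terms, vapply(cmb, paste, "", collapse = ":"))
  }
  contains <- function(set, term) {
    parts <- strsplit(term, ":")[[1]]
    subs <- unlist(lapply(seq_along(parts), function(o)
      vapply(utils::combn(parts, o, simplify = FALSE), paste, "",
             collapse = ":")))
    all(subs %in% c(set, term))
  }
  sets <- list(character(0))
  for (m in seq_len(2^length(terms) - 1)) {
    set <- terms[as.logical(bitwAnd(m, 2^(seq_along(terms) - 1)))]
    if (all(vapply(set, function(t) contains(set, t), TRUE)))
      sets[[length(sets) + 1]] <- set
  }
  sets
}

# Fit one candidate structure. Factors get sum-to-zero contrasts and numeric
# covariates are centered, so the marginal (Type-III style) F tests refer to
# effects at the data average rather than at an arbitrary reference cell.
fitModel <- function(data, response, terms, random = NULL, method = "REML",
                     vars = unique(unlist(strsplit(terms, ":")))) {
  for (v in vars) {
    if (is.numeric(data[[v]])) {
      data[[v]] <- data[[v]] - mean(data[[v]], na.rm = TRUE)
    } else {
      data[[v]] <- factor(data[[v]])
      stats::contrasts(data[[v]]) <- stats::contr.sum(nlevels(data[[v]]))
    }
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste(response, "~", rhs))
  if (is.null(random)) {
    stats::lm(form, data = data)
  } else {
    nlme::lme(fixed = form,
              random = stats::as.formula(paste("~ 1 |", random)),
              data = data, method = method,
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE))
  }
}

#' AICc-based selection of fixed effects
#'
#' Fits every marginality-respecting fixed-effect structure over the candidate
#' factors by maximum likelihood (mixed model with a tree random intercept
#' when `random` is given, ordinary least squares otherwise), ranks them by
#' [aicc()], and returns the minimum-AICc structure refit for reporting
#' (REML for mixed models). Ties go to the model with fewer parameters;
#' candidates that fail to fit are excluded with the reason recorded in the
#' ladder. The result does not depend on candidate ordering.
#'
#' @param data data.frame holding the response and factors.
#' @param response response column name.
#' @param factors candidate fixed-effect column names.
#' @param random optional grouping column for a random intercept
#'   (e.g. `"tree_id"`).
#' @param max_order highest interaction order considered (default up to
#'   3-way).
#' @return list with `model` (refit for reporting), `terms` (selected
#'   structure), and `ladder` (data.frame of structure, k, AICc, status).
#' @export
selectFixedEffects <- function(data, response, factors, random = NULL,
                               max_order = min(3, length(factors))) {
  sets <- candidateStructures(factors, max_order)
  if (length(sets) < 1) stop("selectFixedEffects: no candidate structures")
  rows <- lapply(sets, function(set) {
    fit <- tryCatch(fitModel(data, response, set, random, method = "ML"),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(structure = paste(set, collapse = "+"),
                        k = NA_real_, aicc = NA_real_,
                        status = paste("failed:", conditionMessage(fit)),
                        stringsAsFactors = FALSE))
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    n <- stats::nobs(fit)
    val <- tryCatch(aicc(as.numeric(ll), k, n), error = function(e) NA_real_)
    data.frame(structure = paste(set, collapse = "+"), k = k, aicc = val,
               status = if (is.na(val)) "undefined AICc" else "ok",
               stringsAsFactors = FALSE)
  })
  ladder <- do.call(rbind, rows)
  usable <- which(ladder$status == "ok")
  if (!length(usable)) stop("selectFixedEffects: all candidates failed")
  # min AICc; ties to fewer parameters, then fewer terms (deterministic)
  o <- usable[order(round(ladder$aicc[usable], 10), ladder$k[usable],
                    nchar(ladder$structure[usable]))]
  best <- o[1]
  terms <- sets[[best]]
  model <- fitModel(data, response, terms, random, method = "REML")
  list(model = model, terms = terms, ladder = ladder)
}

#' Per-term ANOVA table from a fitted model
#'
#' Marginal (drop-one) F tests for a mixed model (`nlme::lme`, which uses the
#' between-within containment denominator degrees of freedom) or an `lm`.
#'
#' @param model an `lme` or `lm` fit.
#' @return data.frame with `term`, `F`, `p`.
#' @export
anovaTable <- function(model) {
  if (inherits(model, "lme")) {
    tab <- stats::anova(model, type = "marginal")
    tab <- tab[rownames(tab) != "(Intercept)", , drop = FALSE]
    out <- data.frame(term = rownames(tab), F = tab[["F-value"]],
                      p = tab[["p-value"]], stringsAsFactors = FALSE)
  } else {
    tab <- stats::anova(model)
    tab <- tab[rownames(tab) != "Residuals", , drop = FALSE]
    out <- data.frame(term = rownames(tab), F = tab[["F value"]],
                      p = tab[["Pr(>F)"]], stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Repeated-measures treatment ANOVA with AICc model selection
#'
#' The inference step behind the treatment tables: selects fixed effects by
#' AICc ([selectFixedEffects()]), refits the chosen structure (REML when a
#' random intercept grouping is given), and reports per-term F and p. Terms
#' dropped by selection appear with `included = FALSE` and empty test columns,
#' mirroring the convention of reporting blank cells for effects that did not
#' contribute to model fit. A singular or failing mixed fit falls back to a
#' fixed-effects model with a warning. A response with no variance returns
#' F = 0, p = 1 for all candidate terms.
#'
#' @param data data.frame, one row per observation.
#' @param response response column name.
#' @param factors candidate fixed effects (e.g. `c("tleaf","tgrow","cgrow")`).
#' @param random random-intercept grouping column, `"tree_id"` for repeated
#'   measures, or `NULL` for ordinary ANOVA.
#' @param select apply AICc selection (default `TRUE`); otherwise the full
#'   factorial structure is fit.
#' @param max_order highest interaction order.
#' @return Object of class `AnovaTable`: data.frame with `term`, `included`,
#'   `F`, `p`, plus attributes `model` and `ladder`.
#' @export
repeatedMeasuresAnova <- function(data, response, factors,
                                  random = "tree_id", select = TRUE,
                                  max_order = min(3, length(factors))) {
  all_terms <- unlist(lapply(seq_len(max_order), function(o)
    vapply(utils::combn(factors, o, simplify = FALSE), paste, "",
           collapse = ":")))
  y <- data[[response]]
  if (stats::sd(y, na.rm = TRUE) < 1e-12 || all(is.na(y))) {
    out <- data.frame(term = all_terms, included = TRUE, F = 0, p = 1,
                      stringsAsFactors = FALSE)
    class(out) <- c("AnovaTable", "data.frame")
    return(out)
  }
  run <- function(rand) {
    if (select) {
      sel <- selectFixedEffects(data, response, factors, rand, max_order)
    } else {
      sel <- list(model = fitModel(data, response, all_terms, rand, "REML"),
                  terms = all_terms, ladder = NULL)
    }
    sel
  }
  sel <- tryCatch(run(random), error = function(e) e)
  if (inherits(sel, "error") && !is.null(random)) {
    warning("mixed model failed (", conditionMessage(sel),
            "); refitting as fixed-effects model")
    sel <- run(NULL)
  } else if (inherits(sel, "error")) stop(sel)
  tab <- anovaTable(sel$model)
  out <- data.frame(term = all_terms,
                    included = all_terms %in% sel$terms,
                    F = tab$F[match(all_terms, tab$term)],
                    p = tab$p[match(all_terms, tab$term)],
                    stringsAsFactors = FALSE)
  attr(out, "model") <- sel$model
  attr(out, "ladder") <- sel$ladder
  class(out) <- c("AnovaTable", "data.frame")
  out
}

#' Tukey post-hoc comparisons with a compact letter display
#'
#' All pairwise comparisons among the levels of a grouping factor (by
#' convention the 6 growth-temperature x growth-CO2 treatment cells),
#' studentized-range adjusted via \pkg{emmeans}, plus a compact letter
#' display: groups that share no letter differ at the chosen level. Letters
#' are assigned to the maximal cliques of the "not significantly different"
#' graph, ordered by decreasing estimated mean.
#'
#' @param model fitted `lm` or `lme` the comparisons are based on.
#' @param specs name of the grouping factor in the model.
#' @param data the data the model was fit to (needed for `lme`).
#' @param alpha significance level (default 0.05).
#' @return list with `pairs` (pairwise contrasts with Tukey-adjusted p) and
#'   `letters` (data.frame of group, estimated mean, letter string).
#' @export
tukeyPosthoc <- function(model, specs, data = NULL, alpha = 0.05) {
  emm <- if (is.null(data)) emmeans::emmeans(model, specs = specs)
  else emmeans::emmeans(model, specs = specs, data = data)
  means <- as.data.frame(emm)
  if (nrow(means) < 2) stop("tukeyPosthoc: fewer than 2 groups")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  groups <- as.character(means[[1]])
  est <- means$emmean
  # adjacency: TRUE where the pair is NOT significantly different
  ns <- matrix(TRUE, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (i in seq_len(nrow(prs))) {
    gg <- strsplit(as.character(prs$contrast[i]), " - ", fixed = TRUE)[[1]]
    gg <- gsub("^\\(|\\)$", "", gg)
    if (prs$p.value[i] < alpha) {
      ns[gg[1], gg[2]] <- FALSE
      ns[gg[2], gg[1]] <- FALSE
    }
  }
  lett <- letterDisplay(ns, est)
  list(pairs = prs,
       letters = data.frame(group = groups, emmean = est, letters = lett,
                            stringsAsFactors = FALSE))
}

# Compact letter display from a logical "not significantly different"
# adjacency matrix: enumerate maximal all-ns cliques (group counts here are
# tiny, so exhaustive subset search is fine) and letter them by decreasing
# group mean.
letterDisplay <- function(ns, est) {
  g <- nrow(ns)
  cliques <- list()
  for (m in seq_len(2^g - 1)) {
    idx <- which(as.logical(bitwAnd(m, 2^(seq_len(g) - 1))))
    if (all(ns[idx, idx])) cliques[[length(cliques) + 1]] <- idx
  }
  maximal <- Filter(function(cl) !any(vapply(cliques, function(other)
    length(other) > length(cl) && all(cl %in% other), TRUE)), cliques)
  ord <- order(-vapply(maximal, function(cl) max(est[cl]), 0),
               vapply(maximal, min, 0L))
  maximal <- maximal[ord]
  out <- rep("", g)
  for (k in seq_along(maximal))
    out[maximal[[k]]] <- paste0(out[maximal[[k]]], letters[k])
  out
}
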