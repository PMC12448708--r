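#' Read a long-format gas-exchange CSV
#'
#' Reads instrument-export style tables (one row per A/Ci step) into the
#' validated internal layout. The default header dialect is
#' `tree_id, species, year, t_growth, co2_growth, t_leaf, Ca, Ci, A, gsw, Q`
#' (plus optional `step_index`); `column_map` remaps other dialects. Rows
#' whose numeric fields fail to parse are quarantined, not dropped silently:
#' the returned table carries a `"validation"` attribute with counts and the
#' quarantined rows.
#'
#' @param path CSV path (lines starting with `#` are ignored).
#' @param column_map named character vector mapping internal names
#'   (`tree_id, species, year, tgrow, cgrow, tleaf, ca, ci, anet, gs, q`) to
#'   file column names, overriding the defaults.
#' @return data.frame in internal layout; unknown columns are preserved.
#' @export
readGasExchange <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("readGasExchange: no such file: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  map <- c(tree_id = "tree_id", species = "species", year = "year",
           tgrow = "t_growth", cgrow = "co2_growth", tleaf = "t_leaf",
           ca = "Ca", ci = "Ci", anet = "A", gs = "gsw", q = "Q",
           step_index = "step_index")
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  mandatory <- c("tree_id", "tgrow", "cgrow", "tleaf", "ca", "ci", "anet")
  for (nm in mandatory) {
    if (!map[[nm]] %in% names(raw))
      stop("readGasExchange: missing mandatory column '", map[[nm]], "'")
  }
  present <- names(map)[map %in% names(raw)]
  out <- stats::setNames(raw[map[present]], present)
  extra <- setdiff(names(raw), map[present])
  if (length(extra)) out <- cbind(out, raw[extra])

  numeric_cols <- intersect(c("year", "tleaf", "ca", "ci", "anet", "gs", "q",
                              "step_index"), names(out))
  parsed <- out
  bad <- rep(FALSE, nrow(out))
  for (nm in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[nm]]))
    bad <- bad | (is.na(v) & !is.na(out[[nm]]) & nzchar(trimws(out[[nm]])))
    parsed[[nm]] <- v
  }
  quarantined <- parsed[bad, , drop = FALSE]
  accepted <- parsed[!bad, , drop = FALSE]
  rownames(accepted) <- NULL
  attr(accepted, "validation") <- list(
    n_read = nrow(out), n_accepted = nrow(accepted),
    n_quarantined = sum(bad), quarantined = quarantined)
  accepted
}

#' @rdname readGasExchange
#' @param study internal-layout table (e.g. from [generateStudy()]).
#' @param path output path.
#' @return `writeGasExchange()`: `path`, invisibly. The file uses the default
#'   header dialect, so it round-trips through `readGasExchange()`.
#' @export
writeGasExchange <- function(study, path) {
  ext <- c(tree_id = "tree_id", species = "species", year = "year",
           tgrow = "t_growth", cgrow = "co2_growth", tleaf = "t_leaf",
           ca = "Ca", ci = "Ci", anet = "A", gs = "gsw", q = "Q",
           step_index = "step_index")
  keep <- intersect(names(ext), names(study))
  out <- stats::setNames(study[keep], ext[keep])
  extra <- setdiff(names(study), keep)
  if (length(extra)) out <- cbind(out, study[extra])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
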