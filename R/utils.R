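# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so package randomness never leaks into user code.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# md5 of a deparsed R object, used to stamp output files with a config hash
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Write a result table with a provenance header
#'
#' Writes CSV with a leading comment line carrying the package version and a
#' hash of the generating configuration, so outputs are traceable to a run.
#' Files written this way read back with [readResultCSV()] (or any CSV reader
#' that skips `#` comment lines).
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param config optional configuration object hashed into the header.
#' @return `path`, invisibly.
#' @export
writeResultCSV <- function(x, path, config = NULL) {
  version <- tryCatch(as.character(utils::packageVersion("acitherm")),
                      error = function(e) "dev")
  hash <- if (is.null(config)) "none" else objectHash(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# acitherm %s config_hash=%s", version, hash), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultCSV
#' @export
readResultCSV <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
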