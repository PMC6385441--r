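# Shared I/O helpers.

.pkg_version <- function() {
  as.character(utils::packageVersion("irontraffic"))
}

# md5 of a canonical serialization of a config list (written to a temp file;
# only the digest survives, so identical configs give bitwise-identical
# output headers).
.config_hash <- function(config) {
  config <- config[setdiff(names(config), "out")]  # output location is not config
  if (length(config) == 0) return("default")
  txt <- paste(vapply(names(config), function(k) {
    paste0(k, "=", paste(format(config[[k]], digits = 15), collapse = ","))
  }, character(1)), collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Write a data frame as CSV with a provenance header
#'
#' Prepends a comment line carrying the package version and a hash of the
#' run configuration, so identical configurations reproduce identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config Named list describing the run.
#' @return `path`, invisibly.
#' @export
write_csv_with_header <- function(df, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# irontraffic %s config=%s", .pkg_version(),
                     .config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
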