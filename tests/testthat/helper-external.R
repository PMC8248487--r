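# Externally sourced study tables (cohort extracts, per-variant scores,
# replicate ddG scans, per-site rates, the reference CDS) are not
# redistributable and are not bundled. When a user places them under
# inst/extdata/external/ (see the README there for the expected formats),
# the checks that reproduce the published headline numbers run against
# them; otherwise those checks record a single explanatory failure.
external_path <- function(name) {
  p <- system.file("extdata", "external", name, package = "pepscape")
  if (nzchar(p) && file.exists(p)) return(p)
  local <- file.path("..", "..", "inst", "extdata", "external", name)
  if (file.exists(local)) return(local)
  NULL
}

# returns the paths, or NULL after recording one failure if any is absent;
# callers return early on NULL so only the missing-input failure is reported
external_or_fail <- function(...) {
  names <- c(...)
  paths <- lapply(names, external_path)
  missing <- names[vapply(paths, is.null, logical(1))]
  if (length(missing)) {
    testthat::fail(sprintf(
      "requires the non-redistributable study table(s) %s under inst/extdata/external (see the README there for formats)",
      paste(missing, collapse = ", ")))
    return(NULL)
  }
  stats::setNames(unlist(paths), names)
}
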