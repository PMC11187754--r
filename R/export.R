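# Profile and report serialization.

#' Write a solved profile as CSV
#'
#' Columns: `eta, f, fp, fpp, fppp, g, gp, theta, thetap, chi, chip`.
#'
#' @param profile an `hnf_profile`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write a solved profile as JSON
#'
#' Embeds the grid, the ten state columns, the resolved parameters, the
#' mixture ratios, solver diagnostics and the package version (provenance).
#'
#' @param profile an `hnf_profile`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_profile_json <- function(profile, path) {
  df <- as.data.frame(profile)
  x <- list(
    package = "hnflow",
    version = as.character(utils::packageVersion("hnflow")),
    params = lapply(unclass(profile$params),
                    function(v) if (is.infinite(v)) "Inf" else v),
    ratios = unclass(profile$ratios),
    diagnostics = profile$diagnostics,
    profile = df)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
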