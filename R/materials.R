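#' Thermophysical constants of particles and base fluids
#'
#' A particle (or base-fluid) record holds the four SI constants every
#' mixture closure needs: specific heat `cp` (J/kg K), thermal conductivity
#' `k` (W/m K), electrical conductivity `sigma` (1/Ohm m) and density `rho`
#' (kg/m^3).  All four must be strictly positive.
#'
#' @param cp specific heat capacity (J/kg K)
#' @param k thermal conductivity (W/m K)
#' @param sigma electrical conductivity (1/Ohm m)
#' @param rho density (kg/m^3)
#' @param name optional material label
#' @return an object of class `particle_properties`
#' @export
#' @examples
#' particle_properties(cp = 129, k = 318, sigma = 4.1e6, rho = 19300, name = "Au")
particle_properties <- function(cp, k, sigma, rho, name = NULL) {
  vals <- c(cp = cp, k = k, sigma = sigma, rho = rho)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all of cp, k, sigma, rho must be finite and strictly positive")
  }
  structure(list(cp = cp, k = k, sigma = sigma, rho = rho, name = name),
            class = "particle_properties")
}

#' @export
print.particle_properties <- function(x, ...) {
  cat(sprintf("<material%s> cp=%g J/kgK  k=%g W/mK  sigma=%g /Ohm m  rho=%g kg/m^3\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$cp, x$k, x$sigma, x$rho))
  invisible(x)
}

# Built-in registry: gold and titanium-dioxide nanoparticles in blood.
# Values are the published SI constants commonly used for blood-based
# hybrid-nanofluid studies; users are free to register anything else.
.hnflow_materials <- list(
  Au    = list(cp = 129,   k = 318,    sigma = 4.1e6,   rho = 19300),
  TiO2  = list(cp = 4250,  k = 8.9538, sigma = 6.27e-5, rho = 686.20),
  blood = list(cp = 3594,  k = 0.492,  sigma = 0.667,   rho = 1063)
)

#' Look up a built-in material
#'
#' The read-only registry ships gold (`"Au"`), titanium dioxide (`"TiO2"`)
#' and blood (`"blood"`).  Note the well-known data quirk in this literature:
#' several papers name Ag in their titles while tabulating Au constants; the
#' registry ships the tabulated constants under the honest label `"Au"` and
#' leaves any silver study to a user-supplied record.
#'
#' @param name material key, one of `names(list_materials())`
#' @return a [particle_properties] object
#' @export
#' @examples
#' material("blood")
material <- function(name) {
  if (!name %in% names(.hnflow_materials)) {
    stop(sprintf("unknown material '%s'; known: %s", name,
                 paste(names(.hnflow_materials), collapse = ", ")))
  }
  m <- .hnflow_materials[[name]]
  particle_properties(m$cp, m$k, m$sigma, m$rho, name = name)
}

#' List the built-in materials
#' @return named list of the registry constants
#' @export
list_materials <- function() .hnflow_materials

#' Load a user material from a JSON file
#'
#' The file must contain a single object with numeric fields
#' `cp`, `k`, `sigma`, `rho` (and optionally `name`).
#'
#' @param path path to a JSON file
#' @return a [particle_properties] object
#' @export
load_material <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("cp", "k", "sigma", "rho")
  if (!all(need %in% names(x))) {
    stop("material JSON must contain fields: ", paste(need, collapse = ", "))
  }
  particle_properties(as.numeric(x$cp), as.numeric(x$k),
                      as.numeric(x$sigma), as.numeric(x$rho),
                      name = if (!is.null(x$name)) as.character(x$name) else NULL)
}
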