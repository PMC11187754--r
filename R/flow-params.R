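.param_fields <- c("K", "K1", "alpha1", "alpha2", "M", "beta0", "gamma",
                   "beta", "Ec", "Pr", "Lb", "lam", "Omega", "m0", "Q")

#' Dimensionless groups governing the similarity system
#'
#' Collects every dimensionless parameter of the coupled boundary-layer
#' system in one validated object.  Defaults are the package's documented
#' baseline for sweep/trend studies (see the methods vignette): blood
#' Prandtl number `Pr = 21`, sweep anchors of 0.1 for the swept parameters,
#' and small values for the rheological constants.
#'
#' @param K curvature parameter (dimensionless surface radius; `Inf` selects
#'   the exact flat-sheet limit, handled analytically, not as a large number)
#' @param K1 micropolar material parameter (vortex/dynamic viscosity ratio)
#' @param alpha1,alpha2 Eyring-Powell fluid parameters (linear and cubic)
#' @param M magnetic parameter (Lorentz/inertial force ratio)
#' @param beta0 porosity (Darcy drag) parameter
#' @param gamma unsteadiness parameter (`c/a` of the `1/(1-ct)` scaling)
#' @param beta variable-thermal-conductivity parameter
#' @param Ec Eckert number (viscous dissipation)
#' @param Pr Prandtl number (about 21 for blood)
#' @param Lb bioconvection Lewis number `nu_f/D_n`
#' @param lam dimensionless maximum bacterial growth rate
#' @param Omega bacterial density-difference parameter
#' @param m0 microrotation wall-slip constant in `[0, 1]`
#'   (0 = strong particle concentration, `g(0) = 0`)
#' @param Q optional heat generation/absorption coefficient (default 0; the
#'   energy equation carries no such printed term, so this is off by default)
#' @return object of class `flow_params`
#' @export
#' @examples
#' flow_params(M = 0.2)
#' classical_limit_params(1)
flow_params <- function(K = 0.3, K1 = 0.2, alpha1 = 0.1, alpha2 = 0.01,
                        M = 0.1, beta0 = 0.1, gamma = 0.1, beta = 0.1,
                        Ec = 0.1, Pr = 21, Lb = 0.1, lam = 0.1,
                        Omega = 0.1, m0 = 0, Q = 0) {
  p <- list(K = K, K1 = K1, alpha1 = alpha1, alpha2 = alpha2, M = M,
            beta0 = beta0, gamma = gamma, beta = beta, Ec = Ec, Pr = Pr,
            Lb = Lb, lam = lam, Omega = Omega, m0 = m0, Q = Q)
  v <- unlist(p)
  if (any(is.na(v))) stop("flow parameters must not be NA")
  if (!(K > 0)) stop("curvature parameter K must be > 0 (Inf = flat limit)")
  if (!(Pr > 0)) stop("Pr must be > 0")
  if (!(Lb > 0)) stop("Lb must be > 0")
  nonneg <- c("K1", "alpha1", "alpha2", "M", "beta0", "gamma", "beta",
              "Ec", "lam", "Omega")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) stop("parameters must be >= 0: ", paste(bad, collapse = ", "))
  if (m0 < 0 || m0 > 1) stop("m0 must lie in [0, 1]")
  structure(p, class = "flow_params")
}

#' @export
print.flow_params <- function(x, ...) {
  cat("<flow_params>\n")
  v <- unlist(x)
  cat(paste(sprintf("  %-6s = %g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Reduced configuration for the classical flat-plate MHD limit
#'
#' Returns the parameter set for which the full curved model must collapse
#' to the flat stretching-sheet problem `f''' + f f'' - f'^2 - M f' = 0`,
#' whose exact solution is `f = (1 - exp(-m eta))/m`, `m = sqrt(1 + M)`.
#' The flat limit is encoded as `K = Inf` and handled by an exact sentinel
#' (curvature terms are dropped, not evaluated at large `K`).
#'
#' @param M magnetic parameter, `M >= 0`
#' @return a [flow_params] object
#' @export
classical_limit_params <- function(M) {
  stopifnot(is.numeric(M), length(M) == 1, M >= 0)
  flow_params(K = Inf, K1 = 0, alpha1 = 0, alpha2 = 0, M = M, beta0 = 0,
              gamma = 0, beta = 0, Ec = 0, Pr = 21, Lb = 0.1, lam = 0,
              Omega = 0, m0 = 0, Q = 0)
}

#' Serialize flow parameters to JSON
#'
#' Writes a flat JSON object with exactly the [flow_params] field names
#' (`Inf` is stored as the string `"Inf"`).
#'
#' @param params a [flow_params] object
#' @param path optional file path; if `NULL` the JSON string is returned
#' @return the JSON string, invisibly when written to a file
#' @export
flow_params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "flow_params"))
  x <- lapply(unclass(params), function(v) if (is.infinite(v)) "Inf" else v)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read flow parameters from JSON
#'
#' Accepts exactly the [flow_params] field names; unknown keys are rejected.
#' Missing fields fall back to the documented defaults.
#'
#' @param path path to a JSON file, or a JSON string
#' @return a [flow_params] object
#' @export
flow_params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), .param_fields)
  if (length(unknown)) {
    stop("unknown flow parameter keys: ", paste(unknown, collapse = ", "))
  }
  x <- lapply(x, function(v) if (identical(v, "Inf")) Inf else as.numeric(v))
  do.call(flow_params, x)
}

#' A dimensional flow scenario
#'
#' Physical (SI) inputs of one configuration, converted to dimensionless
#' groups by [dimensionless_groups].
#'
#' @param a stretching rate (1/s), `a > 0`
#' @param c unsteadiness rate (1/s), `c >= 0` with `c*t < 1`
#' @param t time (s)
#' @param s arc position along the surface (m)
#' @param R surface radius (m)
#' @param B0 magnetic field strength (T)
#' @param k1 permeability of the porous medium (m^2); `Inf` = non-porous
#' @param beta1,c1 Eyring-Powell material constants
#' @param Dn microorganism diffusivity (m^2/s)
#' @param lam0 bacterial growth-rate scale (1/s)
#' @param nu_f kinematic viscosity of the base fluid (m^2/s)
#' @param fluid [particle_properties] of the base fluid
#' @param deltaT wall-to-ambient temperature difference (K); used only to
#'   form the Eckert number (`Ec = 0` when `NULL`)
#' @return object of class `dimensional_scenario`
#' @export
dimensional_scenario <- function(a, c = 0, t = 0, s = 1, R = 1, B0 = 0,
                                 k1 = Inf, beta1 = 1, c1 = 1, Dn = 1e-6,
                                 lam0 = 0, nu_f = 2.7e-6,
                                 fluid = material("blood"), deltaT = NULL) {
  if (!(a > 0)) stop("stretching rate a must be > 0")
  if (c < 0) stop("unsteadiness rate c must be >= 0")
  if (c * t >= 1) stop("similarity scaling breaks down: c*t must be < 1")
  if (!(R > 0)) stop("radius R must be > 0")
  structure(list(a = a, c = c, t = t, s = s, R = R, B0 = B0, k1 = k1,
                 beta1 = beta1, c1 = c1, Dn = Dn, lam0 = lam0, nu_f = nu_f,
                 fluid = fluid, deltaT = deltaT),
            class = "dimensional_scenario")
}

#' Convert a dimensional scenario to dimensionless groups
#'
#' Applies the similarity scalings: `K = R*sqrt(a/(nu_f (1-ct)))`,
#' `M = sigma_f B0^2/(rho_f a)`, `beta0 = mu_f (1-ct)/(rho_f k1 a)`,
#' `alpha1 = 1/(mu_f beta1 c1)`,
#' `alpha2 = a^3 s^2 / (2 beta1 c1^3 rho_f nu_f^2 (1-ct)^3)`,
#' `gamma = c/a`, `Lb = nu_f/Dn`, `lam = lam0/(a (1-ct))`,
#' `Pr = nu_f (rho cp)_f / k_f`, and (when `deltaT` is supplied)
#' `Ec = Uw^2/(cp_f deltaT)` with `Uw = a s/(1-ct)`.
#'
#' @param scenario a [dimensional_scenario]
#' @param K1,beta,Omega,m0,Q dimensionless parameters with no dimensional
#'   counterpart in the scenario; passed through to [flow_params]
#' @return a [flow_params] object
#' @export
dimensionless_groups <- function(scenario, K1 = 0, beta = 0, Omega = 0,
                                 m0 = 0, Q = 0) {
  stopifnot(inherits(scenario, "dimensional_scenario"))
  sc <- scenario
  fac <- 1 - sc$c * sc$t
  if (fac <= 0) stop("similarity scaling breaks down: c*t must be < 1")
  rho <- sc$fluid$rho
  mu_f <- sc$nu_f * rho
  Uw <- sc$a * sc$s / fac
  Ec <- if (is.null(sc$deltaT)) 0 else Uw^2 / (sc$fluid$cp * sc$deltaT)
  flow_params(
    K = sc$R * sqrt(sc$a / (sc$nu_f * fac)),
    K1 = K1,
    alpha1 = 1 / (mu_f * sc$beta1 * sc$c1),
    alpha2 = sc$a^3 * sc$s^2 / (2 * sc$beta1 * sc$c1^3 * rho * sc$nu_f^2 * fac^3),
    M = sc$fluid$sigma * sc$B0^2 / (rho * sc$a),
    beta0 = mu_f * fac / (rho * sc$k1 * sc$a),
    gamma = sc$c / sc$a,
    beta = beta,
    Ec = Ec,
    Pr = sc$nu_f * rho * sc$fluid$cp / sc$fluid$k,
    Lb = sc$nu_f / sc$Dn,
    lam = sc$lam0 / (sc$a * fac),
    Omega = Omega, m0 = m0, Q = Q)
}
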