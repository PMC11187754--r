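#' Volume fractions of a two-particle hybrid nanofluid
#'
#' @param phi1,phi2 volume fractions of particle species 1 and 2;
#'   both must be non-negative with `phi1 + phi2 < 1`.
#' @return object of class `volume_fractions`
#' @export
volume_fractions <- function(phi1, phi2) {
  if (!is.finite(phi1) || !is.finite(phi2) || phi1 < 0 || phi2 < 0) {
    stop("volume fractions must be finite and non-negative")
  }
  if (phi1 + phi2 >= 1) {
    stop("unphysical particle loading: phi1 + phi2 must be < 1")
  }
  structure(list(phi1 = phi1, phi2 = phi2), class = "volume_fractions")
}

.as_fractions <- function(fractions) {
  if (inherits(fractions, "volume_fractions")) return(fractions)
  if (is.numeric(fractions) && length(fractions) == 2) {
    return(volume_fractions(fractions[[1]], fractions[[2]]))
  }
  stop("fractions must be a volume_fractions object or a numeric pair")
}

#' Brinkman viscosity ratio of a hybrid nanofluid
#'
#' `mu_hnf / mu_f = (1 - phi1 - phi2)^(-2.5)`.
#'
#' @param fractions a [volume_fractions] object (or numeric pair)
#' @return dimensionless viscosity ratio
#' @export
#' @examples
#' viscosity_ratio(volume_fractions(0.05, 0.05))  # (0.9)^-2.5
viscosity_ratio <- function(fractions) {
  fr <- .as_fractions(fractions)
  (1 - fr$phi1 - fr$phi2)^(-2.5)
}

#' Linear mixture density ratio
#'
#' `rho_hnf / rho_f = phi1 rho1/rho_f + phi2 rho2/rho_f + (1 - phi1 - phi2)`.
#'
#' @inheritParams viscosity_ratio
#' @param p1,p2 [particle_properties] of the two particle species
#' @param bf [particle_properties] of the base fluid
#' @return dimensionless density ratio
#' @export
density_ratio <- function(fractions, p1, p2, bf) {
  fr <- .as_fractions(fractions)
  fr$phi1 * p1$rho / bf$rho + fr$phi2 * p2$rho / bf$rho + (1 - fr$phi1 - fr$phi2)
}

#' Linear mixture volumetric heat-capacity ratio
#'
#' `(rho cp)_hnf / (rho cp)_f`, linear in each fraction with each particle's
#' own `rho*cp` (the standard mixture rule).
#'
#' @inheritParams density_ratio
#' @return dimensionless heat-capacity ratio
#' @export
heat_capacity_ratio <- function(fractions, p1, p2, bf) {
  fr <- .as_fractions(fractions)
  rcp <- function(p) p$rho * p$cp
  fr$phi1 * rcp(p1) / rcp(bf) + fr$phi2 * rcp(p2) / rcp(bf) +
    (1 - fr$phi1 - fr$phi2)
}

# Hybrid Maxwell-type closure shared by the thermal and electrical
# conductivity ratios.  kbar = (phi1 k1 + phi2 k2)/Phi is the effective
# particle conductivity; the Phi -> 0 limit is exactly 1 (the printed
# formula is 0/0 there) and is handled by a dedicated branch.
.maxwell_hybrid <- function(phi1, phi2, k1, k2, kb) {
  Phi <- phi1 + phi2
  if (Phi == 0) return(1)
  pk <- phi1 * k1 + phi2 * k2
  num <- pk / Phi + 2 * kb + 2 * pk - 2 * Phi * kb
  den <- pk / Phi + 2 * kb - pk + Phi * kb
  num / den
}

#' Hybrid Maxwell thermal-conductivity ratio
#'
#' Evaluates the two-particle Maxwell closure
#' `k_hnf/k_f = (kbar + 2 k_f + 2(phi1 k1 + phi2 k2) - 2 Phi k_f) /
#'             (kbar + 2 k_f -   (phi1 k1 + phi2 k2) +   Phi k_f)`
#' with `kbar = (phi1 k1 + phi2 k2)/Phi`.  With a single particle species it
#' reduces to the classical Maxwell form; at `Phi = 0` it returns exactly 1.
#'
#' @inheritParams density_ratio
#' @return dimensionless thermal-conductivity ratio
#' @export
thermal_conductivity_ratio <- function(fractions, p1, p2, bf) {
  fr <- .as_fractions(fractions)
  .maxwell_hybrid(fr$phi1, fr$phi2, p1$k, p2$k, bf$k)
}

#' Hybrid Maxwell electrical-conductivity ratio
#'
#' Mirror of [thermal_conductivity_ratio] with electrical conductivities.
#'
#' @inheritParams density_ratio
#' @return dimensionless electrical-conductivity ratio
#' @export
electrical_conductivity_ratio <- function(fractions, p1, p2, bf) {
  fr <- .as_fractions(fractions)
  .maxwell_hybrid(fr$phi1, fr$phi2, p1$sigma, p2$sigma, bf$sigma)
}

#' Bundle the five hybrid-nanofluid property ratios
#'
#' Pure function of the fractions and material constants; all five ratios
#' equal 1 when both fractions are zero, and the result is invariant under
#' exchanging `(p1, phi1)` with `(p2, phi2)`.
#'
#' @inheritParams density_ratio
#' @return object of class `mixture_ratios` with fields `mu_r`, `rho_r`,
#'   `rhocp_r`, `k_r`, `sigma_r`
#' @export
#' @examples
#' mixture_ratios(volume_fractions(0.01, 0.01),
#'                material("Au"), material("TiO2"), material("blood"))
mixture_ratios <- function(fractions,
                           p1 = material("Au"),
                           p2 = material("TiO2"),
                           bf = material("blood")) {
  fr <- .as_fractions(fractions)
  out <- list(
    mu_r    = viscosity_ratio(fr),
    rho_r   = density_ratio(fr, p1, p2, bf),
    rhocp_r = heat_capacity_ratio(fr, p1, p2, bf),
    k_r     = thermal_conductivity_ratio(fr, p1, p2, bf),
    sigma_r = electrical_conductivity_ratio(fr, p1, p2, bf)
  )
  if (any(!is.finite(unlist(out))) || any(unlist(out) <= 0)) {
    stop("mixture ratios must be finite and strictly positive")
  }
  structure(out, class = "mixture_ratios")
}

#' @rdname mixture_ratios
#' @export
compute_all <- mixture_ratios

#' Base-fluid (unit) mixture ratios
#' @return `mixture_ratios` with all five ratios exactly 1
#' @export
unit_ratios <- function() {
  structure(list(mu_r = 1, rho_r = 1, rhocp_r = 1, k_r = 1, sigma_r = 1),
            class = "mixture_ratios")
}

#' @export
print.mixture_ratios <- function(x, ...) {
  cat(sprintf(
    "<mixture_ratios> mu_r=%.6g rho_r=%.6g rhocp_r=%.6g k_r=%.6g sigma_r=%.6g\n",
    x$mu_r, x$rho_r, x$rhocp_r, x$k_r, x$sigma_r))
  invisible(x)
}
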