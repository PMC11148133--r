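# Cough transient and foramen magnum obstruction models.

#' Cough source-term specification
#'
#' The cough is emulated as a volumetric mass source in the spinal
#' compartment: a steep positive Gaussian lobe (venous compression pushing
#' CSF cranially) followed by an equal negative lobe (venous re-expansion),
#' each with its t = 0 value subtracted so the source starts exactly at zero:
#'
#' `S(t) = A/(sigma sqrt(2 pi)) * [ g(t; mu_p) - g(0; mu_p) - g(t; mu_n) + g(0; mu_n) ]`
#'
#' with `g(t; mu) = exp(-(t - mu)^2 / (2 sigma^2))`.
#'
#' `V_spinal_m3` converts the source into a volumetric inflow; its default is
#' back-solved so that the default amplitude `A = 2356.30` kg/(m^3 s) yields a
#' peak inflow of exactly 50.46 ml/s (the source maximum is 9033.82 kg/(m^3 s)
#' at t = 1.8709 s, slightly above its value at mu_p).
#'
#' @param A_kg_m3_s Scaling factor A (kg/(m^3 s)), default 2356.30.
#' @param sigma_s Standard deviation of both lobes (s), default 0.1.
#' @param mu_p_s Mean of the positive lobe (s), default 1.88.
#' @param mu_n_s Mean of the negative lobe (s), default 2.13; must exceed
#'   `mu_p_s`.
#' @param V_spinal_m3 Spinal source-compartment volume (m^3).
#' @param rho_kg_m3 CSF density (kg/m^3).
#' @return An object of class `cough_spec`.
#' @export
cough_spec <- function(A_kg_m3_s = 2356.30, sigma_s = 0.1,
                       mu_p_s = 1.88, mu_n_s = 2.13,
                       V_spinal_m3 = geometry_config()$V_spinal_m3,
                       rho_kg_m3 = fluid_properties()$rho_kg_m3) {
  if (!is.finite(sigma_s) || sigma_s <= 0) stop("sigma_s must be positive")
  if (!(mu_p_s < mu_n_s)) stop("mu_p_s must be smaller than mu_n_s")
  if (!is.finite(A_kg_m3_s) || A_kg_m3_s < 0) stop("A must be non-negative")
  if (V_spinal_m3 <= 0 || rho_kg_m3 <= 0) stop("volume and density must be positive")
  structure(
    list(A_kg_m3_s = A_kg_m3_s, sigma_s = sigma_s,
         mu_p_s = mu_p_s, mu_n_s = mu_n_s,
         V_spinal_m3 = V_spinal_m3, rho_kg_m3 = rho_kg_m3),
    class = "cough_spec"
  )
}

#' Evaluate the cough source term
#'
#' @param t Time(s) in seconds (vectorised), t >= 0.
#' @param spec A [cough_spec()].
#' @return Source strength in kg/(m^3 s); exactly 0 at t = 0.
#' @examples
#' cough_source(0)            # 0
#' cough_source(1.88)         # ~8987.3
#' @export
cough_source <- function(t, spec = cough_spec()) {
  g <- function(x, mu) exp(-0.5 * (x - mu)^2 / spec$sigma_s^2)
  spec$A_kg_m3_s / (spec$sigma_s * sqrt(2 * pi)) *
    (g(t, spec$mu_p_s) - g(0, spec$mu_p_s) -
       g(t, spec$mu_n_s) + g(0, spec$mu_n_s))
}

#' Cough volumetric inflow
#'
#' `Q(t) = S_cough(t) V_spinal / rho`, reported in ml/s.
#'
#' @param t_grid Time grid in seconds.
#' @param spec A [cough_spec()].
#' @return Numeric vector of inflows (ml/s).
#' @export
cough_inflow <- function(t_grid, spec = cough_spec()) {
  cough_source(t_grid, spec) * spec$V_spinal_m3 / spec$rho_kg_m3 * 1e6
}

#' Porous-zone specification
#'
#' Darcy description of a porous obstruction zone: neglecting inertia, the
#' pressure drop over a zone of length `d` and cross-section `A` is
#' `dP = R_viscous * mu * d * Q / A`.
#'
#' @param R_viscous_m2 Viscous resistance (1/m^2), >= 0.
#' @param length_m Axial extent of the zone (m), default 0.01 (the 1 cm disc).
#' @param area_m2 Cross-sectional area of the zone (m^2).
#' @param mu_kg_ms Dynamic viscosity (kg/(m.s)).
#' @return An object of class `porous_zone_spec`.
#' @export
porous_zone_spec <- function(R_viscous_m2, length_m = 0.01,
                             area_m2, mu_kg_ms = fluid_properties()$mu_kg_ms) {
  if (!is.finite(R_viscous_m2) || R_viscous_m2 < 0) {
    stop("R_viscous_m2 must be non-negative")
  }
  if (length_m <= 0 || area_m2 <= 0 || mu_kg_ms <= 0) {
    stop("length, area and viscosity must be positive")
  }
  structure(
    list(R_viscous_m2 = R_viscous_m2, length_m = length_m,
         area_m2 = area_m2, mu_kg_ms = mu_kg_ms),
    class = "porous_zone_spec"
  )
}

#' Hydraulic resistance of a porous zone
#'
#' Converts the Darcy law into a lumped hydraulic resistance
#' `R_h = R_viscous * mu * d / A`, reported in mmHg.s/ml
#' (1 mmHg.s/ml = 1.33322e8 Pa.s/m^3).
#'
#' @param zone A [porous_zone_spec()].
#' @return Resistance in mmHg.s/ml.
#' @export
hydraulic_resistance <- function(zone) {
  stopifnot(inherits(zone, "porous_zone_spec"))
  r_si <- zone$R_viscous_m2 * zone$mu_kg_ms * zone$length_m / zone$area_m2
  r_si / .mmHg_s_ml_SI
}

#' Foramen magnum obstruction presets
#'
#' The porous disc at the foramen magnum is split into an anterior zone
#' (25% of the canal cross-section) and a posterior zone (75%, where the
#' cerebellar tonsils herniate in Chiari type 1). The graded cases carry
#' these viscous resistances (1/m^2):
#'
#' | case    | anterior | posterior |
#' |---------|----------|-----------|
#' | control | 0        | 0         |
#' | OBS-1   | 0        | 1e14      |
#' | OBS-2   | 1e8      | 1e14      |
#' | OBS-3   | 1e10     | 1e14      |
#'
#' @param name One of `"control"`, `"OBS-1"`, `"OBS-2"`, `"OBS-3"`, or
#'   `"custom"` (then supply both resistances).
#' @param R_v_anterior_m2,R_v_posterior_m2 Viscous resistances (1/m^2);
#'   ignored unless `name = "custom"`.
#' @param posterior_area_fraction Fraction of the canal cross-section filled
#'   by the posterior zone, in (0, 1); default 0.75.
#' @return An object of class `obstruction_case`.
#' @examples
#' obstruction_case("OBS-2")
#' @export
obstruction_case <- function(name = c("control", "OBS-1", "OBS-2", "OBS-3", "custom"),
                             R_v_anterior_m2 = NULL, R_v_posterior_m2 = NULL,
                             posterior_area_fraction = 0.75) {
  name <- match.arg(name)
  if (!is.finite(posterior_area_fraction) ||
      posterior_area_fraction <= 0 || posterior_area_fraction >= 1) {
    stop("posterior_area_fraction must lie strictly in (0, 1)")
  }
  presets <- list(
    "control" = c(0, 0),
    "OBS-1"   = c(0, 1e14),
    "OBS-2"   = c(1e8, 1e14),
    "OBS-3"   = c(1e10, 1e14)
  )
  if (name == "custom") {
    if (is.null(R_v_anterior_m2) || is.null(R_v_posterior_m2)) {
      stop("custom case needs both R_v_anterior_m2 and R_v_posterior_m2")
    }
    rv <- c(R_v_anterior_m2, R_v_posterior_m2)
    if (any(!is.finite(rv)) || any(rv < 0)) stop("viscous resistances must be >= 0")
  } else {
    rv <- presets[[name]]
  }
  structure(
    list(name = name, R_v_anterior_m2 = rv[1L], R_v_posterior_m2 = rv[2L],
         posterior_area_fraction = posterior_area_fraction),
    class = "obstruction_case"
  )
}

#' Lumped trans-foramen resistance for an obstruction case
#'
#' The open foramen pathway of resistance `R_open` is split into an anterior
#' and a posterior parallel path by area fraction (resistance scales with the
#' inverse of the area fraction); each path is put in series with its zone's
#' Darcy resistance, and the two paths are recombined in parallel:
#'
#' `R_FM = ( 1/(R_open/f_a + R_a,darcy) + 1/(R_open/f_p + R_p,darcy) )^-1`
#'
#' For the control case (no Darcy term) this recombines exactly to `R_open`.
#'
#' @param case An [obstruction_case()].
#' @param geom A [geometry_config()] supplying the canal area at the disc.
#' @param fluid A [fluid_properties()].
#' @param R_open Baseline resistance of the unobstructed foramen pathway
#'   (mmHg.s/ml), >= 0; default 0.05, small against the outlet resistances.
#' @param length_m Axial length of the porous disc (m), default 0.01.
#' @return Trans-foramen resistance in mmHg.s/ml.
#' @examples
#' foramen_resistance(obstruction_case("control")) # = R_open
#' @export
foramen_resistance <- function(case, geom = geometry_config(),
                               fluid = fluid_properties(),
                               R_open = 0.05, length_m = 0.01) {
  stopifnot(inherits(case, "obstruction_case"))
  if (!is.finite(R_open) || R_open < 0) stop("R_open must be non-negative")
  f_p <- case$posterior_area_fraction
  f_a <- 1 - f_p
  r_darcy <- function(rv, frac) {
    hydraulic_resistance(porous_zone_spec(
      R_viscous_m2 = rv, length_m = length_m,
      area_m2 = frac * geom$A_canal_m2, mu_kg_ms = fluid$mu_kg_ms
    ))
  }
  r_a <- R_open / f_a + r_darcy(case$R_v_anterior_m2, f_a)
  r_p <- R_open / f_p + r_darcy(case$R_v_posterior_m2, f_p)
  1 / (1 / r_a + 1 / r_p)
}
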