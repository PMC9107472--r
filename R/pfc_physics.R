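# Superheat and homogeneous-nucleation physics of perfluorocarbon
# nanodroplet cores.  The LET threshold produced here gates the
# radiation-induced vaporization used throughout the simulation.

#' Built-in perfluorocarbon property table
#'
#' Thermophysical constants for candidate superheated-droplet core liquids.
#' One row per compound; anchors taken from standard literature tabulations:
#' molar mass, boiling point at 1 atm, critical temperature and pressure,
#' liquid density, a surface-tension reference point, and the latent heat of
#' vaporization at the boiling point.  Temperature-dependent correlations are
#' constructed from these anchors by [pfc_properties()].
#'
#' @return A data frame with one row per perfluorocarbon.
#' @export
pfc_table <- function() {
  path <- system.file("extdata", "pfc_properties.csv", package = "ndvap")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Thermophysical property set of a perfluorocarbon core liquid
#'
#' Builds the property object used by the nucleation model.  Correlations:
#' saturated vapor pressure by a two-point Clausius-Clapeyron fit through the
#' normal boiling point and the critical point; surface tension by the
#' Guggenheim-Katayama form \eqn{\sigma_0 (1 - T/T_c)^{11/9}} anchored at a
#' reference temperature; latent heat by the Watson correlation from its
#' boiling-point value; vapor density by the ideal-gas law (documented
#' approximation).
#'
#' @param name Compound name, a row of [pfc_table()] (default `"PFB"`,
#'   perfluorobutane).
#' @param table Property table; override to supply custom constants.
#' @return An object of class `"pfc"`: named constants plus the closures
#'   `sigma(T_C)` (N/m), `p_v(T_C)` (Pa), `h_fg(T_C)` (J/kg) and
#'   `rho_vapor(T_C, p)` (kg/m^3).  Temperatures at the interface are degrees
#'   Celsius; all thermodynamics run internally in kelvin.
#' @export
pfc_properties <- function(name = "PFB", table = pfc_table()) {
  row <- table[table$name == name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown perfluorocarbon: ", name)
  T_b <- row$T_b_C
  T_c <- row$T_c_C
  if (!is.finite(T_b) || !is.finite(T_c) || T_b >= T_c)
    stop("invalid properties: boiling point must lie below the critical point")
  TbK <- T_b + 273.15
  TcK <- T_c + 273.15
  M   <- row$M_g_mol / 1000            # kg/mol
  p_atm <- 101325
  # Clausius-Clapeyron through (T_b, 1 atm) and (T_c, p_c)
  B <- log(row$p_c_Pa / p_atm) / (1 / TbK - 1 / TcK)
  A <- log(p_atm) + B / TbK
  # Guggenheim-Katayama anchored at (sigma_ref_T_C, sigma_ref_N_m)
  sig0 <- row$sigma_ref_N_m / (1 - (row$sigma_ref_T_C + 273.15) / TcK)^(11 / 9)
  hfg_b <- row$h_fg_b_J_kg

  obj <- list(
    name = row$name,
    T_b = T_b, T_c = T_c,
    M = row$M_g_mol,
    rho_liquid = row$rho_liquid_kg_m3,
    sigma = function(T_C) {
      TK <- T_C + 273.15
      ifelse(TK >= TcK, 0, sig0 * (1 - TK / TcK)^(11 / 9))
    },
    p_v = function(T_C) exp(A - B / (T_C + 273.15)),
    h_fg = function(T_C) {
      TK <- pmin(T_C + 273.15, TcK)
      hfg_b * ((1 - TK / TcK) / (1 - TbK / TcK))^0.38
    },
    rho_vapor = function(T_C, p) p * M / (8.31446 * (T_C + 273.15))
  )
  class(obj) <- "pfc"
  obj
}

#' @export
print.pfc <- function(x, ...) {
  cat(sprintf("<pfc> %s: T_b = %.1f C, T_c = %.1f C, M = %.1f g/mol\n",
              x$name, x$T_b, x$T_c, x$M))
  invisible(x)
}

#' Degree of superheat
#'
#' Normalized excess of the operating temperature above the boiling point,
#' \eqn{s = (T - T_b)/(T_c - T_b)}.  Values outside \[0, 1\] are allowed
#' (liquid below its boiling point, or beyond the critical point) and flagged
#' with a warning.
#'
#' @param T Temperature (degrees C).
#' @param props A [pfc_properties()] object.
#' @return Dimensionless fraction.
#' @export
degree_of_superheat <- function(T, props) {
  stopifnot(is.finite(T))
  if (props$T_b >= props$T_c)
    stop("invalid properties: T_b >= T_c")
  s <- (T - props$T_b) / (props$T_c - props$T_b)
  if (any(s < 0 | s > 1))
    warning("degree of superheat outside [0, 1]: liquid not superheated or supercritical")
  s
}

#' Critical vapor-embryo radius
#'
#' Mechanical-equilibrium radius of a vapor nucleus in the superheated
#' liquid, \eqn{R_c = 2\sigma(T) / (p_v(T) - p_0)}.
#'
#' @param T Temperature (degrees C).
#' @param p0 Ambient pressure (Pa), default 1 atm.
#' @param props A [pfc_properties()] object.
#' @return Radius in metres.
#' @export
critical_radius <- function(T, p0 = 101325, props) {
  dp <- props$p_v(T) - p0
  if (dp <= 0)
    stop("not superheated: vapor pressure does not exceed ambient pressure at ",
         T, " C")
  2 * props$sigma(T) / dp
}

#' Nucleation energy of a critical vapor embryo
#'
#' Energy required to create a critical nucleus: surface term
#' \eqn{4\pi R_c^2 \sigma} plus vaporization term
#' \eqn{(4/3)\pi R_c^3 \rho_v h_{fg}}.  An expansion-work term
#' \eqn{(4/3)\pi R_c^3 (p_v - p_0)} can be switched on; it is off by default
#' (the default composition reproduces the published threshold for
#' perfluorobutane within tolerance).
#'
#' @param R_c Critical radius (m).
#' @param T Temperature (degrees C).
#' @param props A [pfc_properties()] object.
#' @param include_expansion_work Add the p.dV term (default `FALSE`).
#' @param p0 Ambient pressure (Pa), used only by the expansion-work term.
#' @return Energy in joules.
#' @export
nucleation_energy <- function(R_c, T, props, include_expansion_work = FALSE,
                              p0 = 101325) {
  stopifnot(R_c >= 0)
  pv <- props$p_v(T)
  W <- 4 * pi * R_c^2 * props$sigma(T) +
    (4 / 3) * pi * R_c^3 * props$rho_vapor(T, pv) * props$h_fg(T)
  if (include_expansion_work)
    W <- W + (4 / 3) * pi * R_c^3 * (pv - p0)
  W
}

# 1 keV = 1.602176634e-16 J
.kev_per_joule <- 1 / 1.602176634e-16

#' Thermal-spike LET threshold for radiation-induced vaporization
#'
#' Minimum linear energy transfer for which a single particle track
#' nucleates a critical vapor embryo, computed as the ratio of the
#' nucleation energy to twice the critical radius,
#' \eqn{LET_{th} = W_{tot} / (2 R_c)}, converted to keV/um.
#'
#' @inheritParams critical_radius
#' @param ... Passed to [nucleation_energy()].
#' @return An object of class `"nucleation_result"` with fields `R_c` (m),
#'   `W_tot` (J), `LET_threshold` (keV/um), `temperature` (C) and
#'   `ambient_pressure` (Pa).
#' @export
let_threshold <- function(T, p0 = 101325, props, ...) {
  R_c <- critical_radius(T, p0, props)
  W <- nucleation_energy(R_c, T, props, p0 = p0, ...)
  let <- W / (2 * R_c) * 1e-6 * .kev_per_joule   # J/m -> J/um -> keV/um
  structure(
    list(R_c = R_c, W_tot = W, LET_threshold = let,
         temperature = T, ambient_pressure = p0),
    class = "nucleation_result")
}

#' @export
print.nucleation_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<nucleation_result> T = %.1f C, p0 = %.0f Pa\n",
    "  R_c = %.3e m, W_tot = %.3e J, LET threshold = %.1f keV/um\n"),
    x$temperature, x$ambient_pressure, x$R_c, x$W_tot, x$LET_threshold))
  invisible(x)
}
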