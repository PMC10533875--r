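#' Fluid properties
#'
#' Bundle of the four thermophysical constants used by every solver in the
#' package.  The defaults describe blood: `density` 1060 kg/m3,
#' `dynamic_viscosity` 2.78e-3 Pa s, `specific_heat` 3617 J/(kg K),
#' `thermal_conductivity` 0.52 W/(m K).  The viscosity default is calibrated so
#' that a 2 cm diameter vessel at 0.11 m/s gives a Reynolds number of about
#' 838, the laminar reference condition for the descending aorta.
#'
#' @param density kg/m3, > 0.
#' @param dynamic_viscosity Pa s, > 0.
#' @param specific_heat J/(kg K), > 0.
#' @param thermal_conductivity W/(m K), > 0.
#' @return An object of class `fluid_properties`.
#' @examples
#' blood <- fluid_properties()
#' reynolds(blood, diameter = 0.02, velocity = 0.11)
#' @export
fluid_properties <- function(density = 1060,
                             dynamic_viscosity = 2.78e-3,
                             specific_heat = 3617,
                             thermal_conductivity = 0.52) {
  for (nm in c("density", "dynamic_viscosity", "specific_heat",
               "thermal_conductivity")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single strictly positive finite number",
           call. = FALSE)
  }
  structure(
    list(density = density,
         dynamic_viscosity = dynamic_viscosity,
         specific_heat = specific_heat,
         thermal_conductivity = thermal_conductivity),
    class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties>\n")
  cat(sprintf("  density              %g kg/m3\n", x$density))
  cat(sprintf("  dynamic_viscosity    %g Pa s\n", x$dynamic_viscosity))
  cat(sprintf("  specific_heat        %g J/(kg K)\n", x$specific_heat))
  cat(sprintf("  thermal_conductivity %g W/(m K)\n", x$thermal_conductivity))
  cat(sprintf("  (nu = %.3e m2/s, Pr = %.3g)\n",
              kinematic_viscosity(x), prandtl(x)))
  invisible(x)
}

kinematic_viscosity <- function(props) props$dynamic_viscosity / props$density

#' Vessel geometry
#'
#' Straight (optionally tapered) circular vessel.  The local radius is
#' `inner_radius + taper_rate * z`; a physiological aorta narrows slightly
#' along the flow so `taper_rate <= 0` is typical.
#'
#' @param inner_radius m, radius at the inlet (z = 0); default 0.01 (aorta).
#' @param length m, axial extent; default 0.20 (descending aorta segment).
#' @param taper_rate m/m, radius change per unit z (default 0, may be
#'   negative); the radius must stay positive over the whole length.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(inner_radius = 0.01, length = 0.20,
                            taper_rate = 0) {
  if (!is.numeric(inner_radius) || inner_radius <= 0)
    stop("`inner_radius` must be > 0", call. = FALSE)
  if (!is.numeric(length) || length <= 0)
    stop("`length` must be > 0", call. = FALSE)
  if (inner_radius + taper_rate * length <= 0)
    stop("radius(z) must remain positive over [0, length]", call. = FALSE)
  structure(list(inner_radius = inner_radius, length = length,
                 taper_rate = taper_rate),
            class = "vessel_geometry")
}

#' Local vessel radius
#'
#' @param geometry A [vessel_geometry()].
#' @param z m, axial position(s) in `[0, length]`.
#' @return Radius in m at each `z`.
#' @export
vessel_radius <- function(geometry, z) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (any(z < -1e-12 | z > geometry$length + 1e-12))
    stop("z outside [0, length]", call. = FALSE)
  geometry$inner_radius + geometry$taper_rate * z
}

#' Reynolds number
#'
#' `Re = rho * v * D / mu` for pipe flow with diameter `D`.
#'
#' @param props A [fluid_properties()].
#' @param diameter m, > 0.
#' @param velocity m/s, >= 0 (mean axial velocity).
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(props, diameter, velocity) {
  stopifnot(inherits(props, "fluid_properties"))
  if (!is.numeric(diameter) || any(diameter <= 0))
    stop("`diameter` must be > 0", call. = FALSE)
  if (any(velocity < 0)) stop("`velocity` must be >= 0", call. = FALSE)
  props$density * velocity * diameter / props$dynamic_viscosity
}

#' Prandtl number
#'
#' `Pr = cp * mu / k`, the ratio of momentum to thermal diffusivity.  For blood
#' at the package defaults Pr is about 19, so thermal development is far slower
#' than hydrodynamic development.
#'
#' @param props A [fluid_properties()].
#' @return Dimensionless Prandtl number.
#' @export
prandtl <- function(props) {
  stopifnot(inherits(props, "fluid_properties"))
  props$specific_heat * props$dynamic_viscosity / props$thermal_conductivity
}

#' Hydrodynamic and thermal entry lengths
#'
#' Laminar pipe-flow correlations `L_h = 0.05 * Re * D` and
#' `L_th = L_h * Pr`.  Note that for the aortic reference condition
#' (Re = 838, D = 0.02 m) this formula gives `L_h = 0.838 m`; a figure of
#' 0.42 m sometimes quoted for that condition corresponds to `0.05 * Re * r`
#' (radius instead of diameter).  This function uses the diameter form.
#'
#' @param Re Reynolds number, >= 0.
#' @param diameter m, > 0.
#' @param Pr Prandtl number, > 0.
#' @return Named list with `L_h` and `L_th` in m.
#' @export
entry_lengths <- function(Re, diameter, Pr) {
  if (any(Re < 0)) stop("`Re` must be >= 0", call. = FALSE)
  if (any(diameter <= 0)) stop("`diameter` must be > 0", call. = FALSE)
  L_h <- 0.05 * Re * diameter
  list(L_h = L_h, L_th = L_h * Pr)
}

#' Womersley number
#'
#' `alpha = r * sqrt(2 * pi * f * rho / mu)`, the dimensionless pulsation
#' frequency.  `alpha < 1` lets the velocity profile develop quasi-steadily
#' within each cycle; `alpha > 10` (about 15 for the aorta at 1 Hz) yields a
#' flat, inertia-dominated oscillatory profile.
#'
#' @param radius m, > 0.
#' @param frequency Hz, >= 0.
#' @param props A [fluid_properties()].
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(radius, frequency, props) {
  stopifnot(inherits(props, "fluid_properties"))
  if (any(radius <= 0)) stop("`radius` must be > 0", call. = FALSE)
  if (any(frequency < 0)) stop("`frequency` must be >= 0", call. = FALSE)
  radius * sqrt(2 * pi * frequency * props$density / props$dynamic_viscosity)
}

.regime_labels <- c("laminar_developing",
                    "laminar_hydro_developed_thermally_developing",
                    "laminar_fully_developed",
                    "transitional",
                    "turbulent")

#' Classify the flow regime at one station
#'
#' Laminar flow (`Re <= 2300`) is sub-classified by position relative to the
#' entry lengths: developing where `z < min(L_h, L_th)`, hydrodynamically
#' developed but thermally developing where `L_h < z < L_th`, and fully
#' developed where `z > max(L_h, L_th)`.  `2300 < Re <= 8000` is the
#' transitional (low-Reynolds turbulent) region and `Re > 8000` is turbulent.
#' Values exactly on a Reynolds threshold belong to the lower regime.
#'
#' @param Re Reynolds number, >= 0.
#' @param z m, axial distance from the inlet, >= 0.
#' @param L_h m, hydrodynamic entry length.
#' @param L_th m, thermal entry length.
#' @return A single regime label (character).
#' @export
classify_regime <- function(Re, z, L_h, L_th) {
  stopifnot(length(Re) == 1L, length(z) == 1L)
  if (any(c(Re, z, L_h, L_th) < 0)) stop("arguments must be >= 0",
                                         call. = FALSE)
  if (Re > 8000) return("turbulent")
  if (Re > 2300) return("transitional")
  if (z < min(L_h, L_th)) return("laminar_developing")
  if (z < max(L_h, L_th))
    return("laminar_hydro_developed_thermally_developing")
  "laminar_fully_developed"
}

#' Regime map over a velocity/position grid
#'
#' Evaluates [classify_regime()] on the outer product of a velocity grid and an
#' axial grid for the given vessel and fluid, reproducing the classical
#' regime-map view of the descending aorta (physiological window
#' 0 < z < 0.20 m, 0.11 < v < 0.65 m/s).
#'
#' @param geometry A [vessel_geometry()].
#' @param props A [fluid_properties()].
#' @param v_grid m/s, non-empty vector of mean velocities, >= 0.
#' @param z_grid m, non-empty vector of axial positions within the vessel.
#' @return A data.frame with columns `v`, `z`, `Re`, `label`.
#' @export
regime_map <- function(geometry, props, v_grid, z_grid) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(props, "fluid_properties"))
  if (length(v_grid) == 0L || length(z_grid) == 0L)
    stop("`v_grid` and `z_grid` must be non-empty", call. = FALSE)
  if (any(v_grid < 0)) stop("velocities must be >= 0", call. = FALSE)
  if (any(z_grid < 0 | z_grid > geometry$length))
    stop("z values must lie within the vessel", call. = FALSE)
  D <- 2 * geometry$inner_radius
  Pr <- prandtl(props)
  grid <- expand.grid(z = z_grid, v = v_grid)[, c("v", "z")]
  grid$Re <- reynolds(props, D, grid$v)
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    el <- entry_lengths(grid$Re[i], D, Pr)
    classify_regime(grid$Re[i], grid$z[i], el$L_h, el$L_th)
  }, character(1))
  grid
}
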