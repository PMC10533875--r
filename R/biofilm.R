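#' Biofilm thermal-power model
#'
#' Converts the metabolic heat of a single bacterium into the volumetric power
#' density of a surface biofilm.  Defaults describe E. coli: 3.5 pW per cell,
#' a cell volume of 1.49 um3, and a 15% volumetric occupancy of the biofilm
#' matrix by cells.
#'
#' @param single_cell_power W, > 0 (default 3.5e-12).
#' @param single_cell_volume m3, > 0 (default 1.49e-18).
#' @param occupancy_fraction dimensionless in (0, 1] (default 0.15).
#' @return Object of class `biofilm_power_model`.
#' @export
biofilm_power_model <- function(single_cell_power = 3.5e-12,
                                single_cell_volume = 1.49e-18,
                                occupancy_fraction = 0.15) {
  if (single_cell_power <= 0 || single_cell_volume <= 0)
    stop("cell power and volume must be > 0", call. = FALSE)
  if (occupancy_fraction <= 0 || occupancy_fraction > 1)
    stop("`occupancy_fraction` must be in (0, 1]", call. = FALSE)
  structure(list(single_cell_power = single_cell_power,
                 single_cell_volume = single_cell_volume,
                 occupancy_fraction = occupancy_fraction),
            class = "biofilm_power_model")
}

#' Thermal power density of a single bacterium
#'
#' `single_cell_power / single_cell_volume`.  With the defaults this is
#' 2.349e6 W/m3, presented as 2,350,000 W/m3 (3 significant figures).
#'
#' @param model A [biofilm_power_model()].
#' @return List with `value` (W/m3, exact) and `presented` (rounded to 3
#'   significant figures).
#' @export
bacterium_power_density <- function(model = biofilm_power_model()) {
  stopifnot(inherits(model, "biofilm_power_model"))
  v <- model$single_cell_power / model$single_cell_volume
  list(value = v, presented = signif(v, 3))
}

#' Thermal power density of a developed biofilm
#'
#' `occupancy_fraction * bacterium_power_density`; 352,350 W/m3 exactly at the
#' defaults, presented as 350,000 W/m3 (2 significant figures).  The presented
#' value is the reference base for [percent_of_biofilm()].
#'
#' @param model A [biofilm_power_model()].
#' @return List with `value` (exact W/m3) and `presented` (2 significant
#'   figures).
#' @export
biofilm_power_density <- function(model = biofilm_power_model()) {
  stopifnot(inherits(model, "biofilm_power_model"))
  v <- model$occupancy_fraction * bacterium_power_density(model)$value
  list(value = v, presented = signif(v, 2))
}

#' Express a heat-source density as percent of a developed biofilm
#'
#' `100 * Q / reference`, where the reference is the *presented* (rounded)
#' biofilm power density, 350,000 W/m3 at the defaults; this base makes the
#' canonical percentages come out as 0.29, 0.57, 1.14, 2.86 and 14.29.
#'
#' @param Q W/m3, >= 0 (vectorized).
#' @param model A [biofilm_power_model()].
#' @return List with `value` (exact percent) and `presented` (2 decimals).
#' @export
percent_of_biofilm <- function(Q, model = biofilm_power_model()) {
  if (any(Q < 0)) stop("`Q` must be >= 0", call. = FALSE)
  ref <- biofilm_power_density(model)$presented
  p <- 100 * Q / ref
  list(value = p, presented = round(p, 2))
}

#' Reference table of sweep heat sources as biofilm percentages
#'
#' @param Q W/m3 grid (default the canonical sweep 1000...50000).
#' @param model A [biofilm_power_model()].
#' @return data.frame with columns `Q_W_m3`, `percent`.
#' @export
biofilm_reference_table <- function(Q = c(1000, 2000, 4000, 10000, 50000),
                                    model = biofilm_power_model()) {
  data.frame(Q_W_m3 = Q, percent = percent_of_biofilm(Q, model)$presented)
}

# documented comparison constants (W/m3): metabolic power of muscle and
# viscera, orders of magnitude below a developed biofilm
tissue_power_density <- c(muscle = 684, viscera = 3852)
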