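#' Material conductivity library
#'
#' Thermal conductivities (W/m K) of the graft and tissue materials.  The
#' defaults respect the ordering k_PDMS < k_PTFE < k_ePTFE < k_Dacron; PDMS,
#' having the lowest conductivity, is the conservative (worst-case) wall
#' material.  `sensor` is the effective conductivity of the heat-flux sensor
#' stack.
#'
#' @param ... named overrides, e.g. `PDMS = 0.16`.
#' @return Named numeric vector of conductivities.
#' @export
material_library <- function(...) {
  k <- c(PDMS = 0.15, PTFE = 0.25, ePTFE = 0.28, Dacron = 0.33,
         aortic_tissue = 0.48, sensor = 1.0)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(k))
    if (length(bad)) stop("unknown material(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    k[names(over)] <- unlist(over)
  }
  if (!(k["PDMS"] < k["PTFE"] && k["PTFE"] < k["ePTFE"] &&
        k["ePTFE"] < k["Dacron"]))
    stop("conductivities must satisfy PDMS < PTFE < ePTFE < Dacron",
         call. = FALSE)
  k
}

#' Thermal boundary conditions for the graft model
#'
#' Robin (convective) condition at the lumen wall with blood-side
#' heat-transfer coefficient `h_inner`, and fixed body temperature on the
#' outer tissue surface and the axial ends.
#'
#' @param h_inner W/(m2 K), > 0; the physiological envelope is 200-4800.
#' @param T_blood K (default 310.15).
#' @param T_outer K (default 310.15).
#' @return Object of class `thermal_bcs`.
#' @export
thermal_bcs <- function(h_inner = 1200, T_blood = 310.15, T_outer = 310.15) {
  if (h_inner <= 0) stop("`h_inner` must be > 0", call. = FALSE)
  structure(list(h_inner = h_inner, T_blood = T_blood, T_outer = T_outer),
            class = "thermal_bcs")
}

#' Discretized sensor-bearing graft model
#'
#' Builds the finite-volume grid for the 3D steady conduction model: three
#' nested cylindrical shells (graft wall on the lumen, a 450 um infection
#' layer on the graft outer surface, surrounding tissue out to `tissue_outer`),
#' with a rectangular heat-flux sensor embedded mid-wall.  The wall material
#' around the sensor defaults to PDMS; with the default 1.05 mm wall and
#' 0.5 mm sensor the encapsulation layer on each side is 275 um, the nominal
#' quarter-millimetre PDMS case.  An infection is represented at solve time as
#' a volumetric heat source in a disc of the infection layer, offset from the
#' sensor centre by an arc length `d` along the graft surface
#' (`d = graft_outer_radius * dtheta`).
#'
#' The grid is cylindrical `(r, theta, z)`: radial faces conform to every
#' material interface; theta and z are uniform.  Conductances use serial
#' (harmonic) averaging across interfaces, so material jumps are exact.
#'
#' @param inner_radius m (default 0.010), lumen wall.
#' @param graft_outer_radius m (default 0.01105).
#' @param tissue_outer_radius m (default 0.020), outer Dirichlet surface.
#' @param axial_length m (default 0.06); end effects on the sensor flux are
#'   below 0.1% at this length.
#' @param wall_material name in [material_library()] (default `"PDMS"`).
#' @param materials a [material_library()] vector.
#' @param sensor_footprint m, side of the square sensor patch (default
#'   0.0044).
#' @param sensor_thickness m (default 0.0005), centred in the wall.
#' @param infection_thickness m (default 450e-6).
#' @param n_theta,n_z angular and axial cells (defaults 96, 60).
#' @param nr_wall,nr_sensor,nr_infection,nr_tissue radial cells per layer.
#' @param include_tissue logical (default `TRUE`).  The full three-cylinder
#'   model carries the infection layer and tissue shell and is used for the
#'   infection sweeps.  With `FALSE` the domain is the graft wall alone
#'   (the wall-characterization variant used for the heat-transfer-efficiency
#'   study): the outer wall surface is held at body temperature except over
#'   the sensor-congruent patch, where a prescribed inward heat flux enters,
#'   so the applied flux is exactly defined.
#' @return Object of class `graft_model`.
#' @export
graft_model <- function(inner_radius = 0.010, graft_outer_radius = 0.01105,
                        tissue_outer_radius = 0.020, axial_length = 0.06,
                        wall_material = "PDMS",
                        materials = material_library(),
                        sensor_footprint = 0.0044,
                        sensor_thickness = 0.0005,
                        infection_thickness = 450e-6,
                        n_theta = 96, n_z = 60,
                        nr_wall = 2, nr_sensor = 3, nr_infection = 2,
                        nr_tissue = 8, include_tissue = TRUE) {
  if (!(inner_radius < graft_outer_radius &&
        graft_outer_radius < tissue_outer_radius))
    stop("need inner_radius < graft_outer_radius < tissue_outer_radius",
         call. = FALSE)
  wall_t <- graft_outer_radius - inner_radius
  if (sensor_thickness >= wall_t)
    stop("sensor thicker than the graft wall", call. = FALSE)
  if (!wall_material %in% names(materials))
    stop("unknown wall material: ", wall_material, call. = FALSE)
  pad <- (wall_t - sensor_thickness) / 2
  r_s_in <- inner_radius + pad
  r_s_out <- r_s_in + sensor_thickness
  r_inf_out <- graft_outer_radius + infection_thickness
  if (r_inf_out >= tissue_outer_radius)
    stop("infection layer extends beyond the tissue shell", call. = FALSE)
  geo_seq <- function(a, b, n, grow = 1.3) {
    # faces from a to b, widths growing geometrically away from a
    w <- grow^(seq_len(n) - 1)
    a + c(0, cumsum(w)) / sum(w) * (b - a)
  }
  rf <- c(seq(inner_radius, r_s_in, length.out = nr_wall + 1L),
          seq(r_s_in, r_s_out, length.out = nr_sensor + 1L)[-1],
          seq(r_s_out, graft_outer_radius, length.out = nr_wall + 1L)[-1])
  if (include_tissue)
    rf <- c(rf,
            seq(graft_outer_radius, r_inf_out,
                length.out = nr_infection + 1L)[-1],
            geo_seq(r_inf_out, tissue_outer_radius, nr_tissue)[-1])
  nr <- length(rf) - 1L
  rc <- 0.5 * (rf[-1] + rf[-length(rf)])
  dth <- 2 * pi / n_theta
  thc <- (seq_len(n_theta) - 0.5) * dth
  dz <- axial_length / n_z
  zc <- (seq_len(n_z) - 0.5) * dz
  # layer tags per radial index
  if (include_tissue) {
    layer <- cut(rc, c(inner_radius, r_s_in, r_s_out, graft_outer_radius,
                       r_inf_out, tissue_outer_radius),
                 labels = c("wall_in", "sensor_layer", "wall_out",
                            "infection_layer", "tissue"))
  } else {
    layer <- cut(rc, c(inner_radius, r_s_in, r_s_out, graft_outer_radius),
                 labels = c("wall_in", "sensor_layer", "wall_out"))
  }
  theta_c <- pi          # sensor centre angle
  z_c <- axial_length / 2
  r_mid <- 0.5 * (r_s_in + r_s_out)
  half_arc <- sensor_footprint / 2
  wrap <- function(x) { y <- (x + pi) %% (2 * pi) - pi; y }
  foot_th <- abs(wrap(thc - theta_c)) * r_mid <= half_arc + 1e-12
  foot_z <- abs(zc - z_c) <= half_arc + 1e-12
  # conductivity array (nr x n_theta x n_z)
  K <- array(materials[[wall_material]], dim = c(nr, n_theta, n_z))
  if (include_tissue)
    K[layer == "infection_layer" | layer == "tissue", , ] <-
      materials[["aortic_tissue"]]
  sens_mask <- array(FALSE, dim = c(nr, n_theta, n_z))
  sens_mask[layer == "sensor_layer",
            foot_th, foot_z] <- TRUE
  K[sens_mask] <- materials[["sensor"]]
  structure(list(
    rf = rf, rc = rc, thc = thc, zc = zc, dth = dth, dz = dz,
    nr = nr, n_theta = n_theta, n_z = n_z,
    inner_radius = inner_radius, graft_outer_radius = graft_outer_radius,
    tissue_outer_radius = tissue_outer_radius, axial_length = axial_length,
    layer = layer, K = K, sensor_mask = sens_mask,
    foot_th = foot_th, foot_z = foot_z,
    sensor_theta = theta_c, sensor_z = z_c, r_sensor_mid = r_mid,
    sensor_footprint = sensor_footprint,
    infection_thickness = infection_thickness,
    wall_material = wall_material, materials = materials,
    include_tissue = include_tissue),
    class = "graft_model")
}

#' @export
print.graft_model <- function(x, ...) {
  cat(sprintf(
    "<graft_model> %s wall %.0f um, sensor %.1f x %.1f mm; grid %d x %d x %d = %d cells\n",
    x$wall_material, 1e6 * (x$graft_outer_radius - x$inner_radius),
    1e3 * x$sensor_footprint, 1e3 * x$sensor_footprint,
    x$nr, x$n_theta, x$n_z, x$nr * x$n_theta * x$n_z))
  invisible(x)
}

# assemble the symmetric FV conduction matrix for the model under Robin
# (h_inner) + Dirichlet BCs; unknowns are temperature rises above T_outer.
# Returns list(A, Gin, Gout, Gz) with the boundary conductance vectors kept
# for flux bookkeeping.
graft_matrix <- function(model, h_inner) {
  nr <- model$nr; nth <- model$n_theta; nz <- model$n_z
  N <- nr * nth * nz
  K <- model$K
  rf <- model$rf; rc <- model$rc; dth <- model$dth; dz <- model$dz
  dr <- diff(rf)
  idx <- function(i, j, k) i + nr * ((j - 1L) + nth * (k - 1L))
  II <- integer(0); JJ <- integer(0); GG <- numeric(0)
  diagG <- numeric(N)
  add_faces <- function(p, q, G) {
    II <<- c(II, p); JJ <<- c(JJ, q); GG <<- c(GG, G)
    diagG[p] <<- diagG[p] + G
    diagG[q] <<- diagG[q] + G
  }
  JK <- expand.grid(j = seq_len(nth), k = seq_len(nz))
  # radial faces
  for (i in seq_len(nr - 1L)) {
    A <- rf[i + 1L] * dth * dz
    G <- A / (0.5 * dr[i] / K[i, , ] + 0.5 * dr[i + 1L] / K[i + 1L, , ])
    add_faces(idx(i, JK$j, JK$k), idx(i + 1L, JK$j, JK$k), as.vector(G))
  }
  # theta faces (periodic)
  for (j in seq_len(nth)) {
    j2 <- if (j == nth) 1L else j + 1L
    A <- dr * dz                                  # per radial layer
    harm <- 1 / (0.5 * rc * dth / K[, j, ] + 0.5 * rc * dth / K[, j2, ])
    G <- sweep(harm, 1, A, `*`)                   # nr x nz
    IK <- expand.grid(i = seq_len(nr), k = seq_len(nz))
    add_faces(idx(IK$i, j, IK$k), idx(IK$i, j2, IK$k), as.vector(G))
  }
  # z faces
  Az <- rc * dr * dth
  for (k in seq_len(nz - 1L)) {
    harm <- 1 / (0.5 * dz / K[, , k] + 0.5 * dz / K[, , k + 1L])
    G <- sweep(harm, 1, Az, `*`)                  # nr x nth
    IJ <- expand.grid(i = seq_len(nr), j = seq_len(nth))
    add_faces(idx(IJ$i, IJ$j, k), idx(IJ$i, IJ$j, k + 1L), as.vector(G))
  }
  # inner Robin boundary (r = inner_radius)
  Ain <- rf[1] * dth * dz
  Gin <- Ain / (1 / h_inner + 0.5 * dr[1] / K[1, , ])     # nth x nz
  p <- idx(1L, JK$j, JK$k)
  diagG[p] <- diagG[p] + as.vector(Gin)
  # outer Dirichlet surface; in the wall-characterization variant the
  # sensor-congruent patch is a prescribed-flux (Neumann) window instead
  Aout <- rf[nr + 1L] * dth * dz
  Gout <- Aout / (0.5 * dr[nr] / K[nr, , ])
  if (!model$include_tissue)
    Gout[model$foot_th, model$foot_z] <- 0
  p <- idx(nr, JK$j, JK$k)
  diagG[p] <- diagG[p] + as.vector(Gout)
  # axial Dirichlet ends
  IJ <- expand.grid(i = seq_len(nr), j = seq_len(nth))
  Gz1 <- sweep(2 * K[, , 1] / dz, 1, Az, `*`)
  Gz2 <- sweep(2 * K[, , nz] / dz, 1, Az, `*`)
  p1 <- idx(IJ$i, IJ$j, 1L); p2 <- idx(IJ$i, IJ$j, nz)
  diagG[p1] <- diagG[p1] + as.vector(Gz1)
  diagG[p2] <- diagG[p2] + as.vector(Gz2)
  A <- Matrix::sparseMatrix(i = c(II, seq_len(N)), j = c(JJ, seq_len(N)),
                            x = c(-GG, diagG), dims = c(N, N),
                            symmetric = FALSE)
  A <- Matrix::forceSymmetric(A + Matrix::t(A) -
                                Matrix::Diagonal(N, diagG))
  list(A = A, Gin = Gin, Gout = Gout, Gz1 = Gz1, Gz2 = Gz2)
}

# volumetric source vector (W per cell) for an infection disc with density Q
# (W/m3), radius `radius`, thickness the model's infection layer, centred at
# arc-length offset d from the sensor centre along the graft outer wall.
infection_source <- function(model, Q, radius, d) {
  nr <- model$nr; nth <- model$n_theta; nz <- model$n_z
  b <- numeric(nr * nth * nz)
  if (Q == 0 || radius <= 0) return(b)
  if (!model$include_tissue)
    stop("infection sources need the full model (include_tissue = TRUE)",
         call. = FALSE)
  if (model$sensor_z + radius > model$axial_length ||
      model$sensor_z - radius < 0)
    stop("infection disc extends beyond the axial domain", call. = FALSE)
  Rg <- model$graft_outer_radius
  th0 <- model$sensor_theta + d / Rg
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  ir <- which(model$layer == "infection_layer")
  dr <- diff(model$rf)
  # fractional overlap of each (theta, z) cell footprint with the disc,
  # by 4x4 subsampling in the unrolled (arc, z) plane; keeps the total
  # source power grid-independent
  ss <- (seq_len(4) - 0.5) / 4 - 0.5
  arc_sub <- outer(wrap(model$thc - th0), ss * model$dth, `+`) * Rg  # nth x 4
  z_sub <- outer(model$zc - model$sensor_z, ss * model$dz, `+`)      # nz x 4
  frac <- matrix(0, nth, nz)
  for (a in 1:4) for (bq in 1:4) {
    inside <- outer(arc_sub[, a]^2, z_sub[, bq]^2, `+`) <= radius^2
    frac <- frac + inside
  }
  frac <- frac / 16
  hit <- which(frac > 0, arr.ind = TRUE)
  for (m_i in seq_len(nrow(hit))) {
    j <- hit[m_i, 1]; k <- hit[m_i, 2]
    for (i in ir) {
      V <- model$rc[i] * dr[i] * model$dth * model$dz
      b[i + nr * ((j - 1L) + nth * (k - 1L))] <- Q * V * frac[j, k]
    }
  }
  b
}

# boundary-patch source (W per cell): inward flux q_app applied on the graft
# outer wall over the sensor-footprint-congruent patch.  With tissue present
# the patch is a heat sheet on the wall-tissue interface, distributed to the
# two adjacent cell rings in proportion to their half-cell conductances (the
# exact finite-volume representation of an interface source).  In the
# wall-characterization variant the patch is the Neumann window of the outer
# boundary and is deposited in the outermost wall cells.
patch_source <- function(model, q_app) {
  nr <- model$nr; nth <- model$n_theta; nz <- model$n_z
  b <- numeric(nr * nth * nz)
  dr <- diff(model$rf)
  jj <- which(model$foot_th); kk <- which(model$foot_z)
  Af <- model$graft_outer_radius * model$dth * model$dz
  if (model$include_tissue) {
    iw <- max(which(model$layer == "wall_out"))
    for (k in kk) for (j in jj) {
      GL <- model$K[iw, j, k] / (0.5 * dr[iw])
      GR <- model$K[iw + 1L, j, k] / (0.5 * dr[iw + 1L])
      b[iw + nr * ((j - 1L) + nth * (k - 1L))] <- q_app * Af * GL / (GL + GR)
      b[iw + 1L + nr * ((j - 1L) + nth * (k - 1L))] <-
        q_app * Af * GR / (GL + GR)
    }
  } else {
    for (k in kk)
      b[nr + nr * ((jj - 1L) + nth * (k - 1L))] <- q_app * Af
  }
  b
}

#' Solve the steady conduction problem
#'
#' Solves `div(k grad T) + Q = 0` on the graft model grid with the Robin
#' blood-side condition `-k dT/dr = h (T - T_blood)` at the lumen wall and
#' fixed `T_outer` on the outer and end surfaces, by sparse Cholesky
#' factorization of the symmetric finite-volume system.  The factor is reused
#' for every right-hand side at the same `h_inner`, which is what makes the
#' parametric sweeps cheap.
#'
#' @param model A [graft_model()].
#' @param bcs A [thermal_bcs()].
#' @param Q W/m3, infection source density (default 0).
#' @param infection_radius m, disc radius (default 0.004).
#' @param d m, arc-length offset of the infection centre from the sensor
#'   centre (default 0).
#' @param factor optionally, a prebuilt [graft_factor()] for this model and
#'   `bcs` (skips re-assembly).
#' @param extra_source optional additional source vector (W per cell).
#' @return Object of class `graft_solution` with the temperature-rise vector
#'   `dT` (K above `T_outer`), the model, bcs and solver bookkeeping.
#' @export
solve_conduction <- function(model, bcs, Q = 0, infection_radius = 0.004,
                             d = 0, factor = NULL, extra_source = NULL) {
  stopifnot(inherits(model, "graft_model"), inherits(bcs, "thermal_bcs"))
  if (is.null(factor)) factor <- graft_factor(model, bcs)
  b <- infection_source(model, Q, infection_radius, d)
  if (!is.null(extra_source)) b <- b + extra_source
  dT <- as.numeric(Matrix::solve(factor$chol, b))
  structure(list(dT = dT, model = model, bcs = bcs, Q = Q,
                 infection_radius = infection_radius, d = d,
                 source = b, mats = factor$mats),
            class = "graft_solution")
}

#' Prefactorized conduction operator
#'
#' Assembles and Cholesky-factorizes the conduction matrix for one
#' `h_inner`; pass the result to [solve_conduction()] to amortize the
#' factorization over many sources.
#'
#' @param model A [graft_model()].
#' @param bcs A [thermal_bcs()].
#' @return List with elements `chol` and `mats`.
#' @export
graft_factor <- function(model, bcs) {
  mats <- graft_matrix(model, bcs$h_inner)
  list(chol = Matrix::Cholesky(mats$A, LDL = FALSE), mats = mats)
}

#' Energy balance of a graft solution
#'
#' Total generated power versus net boundary outflow; discrete conservation
#' makes these equal to solver precision.
#'
#' @param sol A `graft_solution`.
#' @return List with `generated`, `outflow` (W) and `relative_error`.
#' @export
energy_balance <- function(sol) {
  m <- sol$model; nr <- m$nr; nth <- m$n_theta; nz <- m$n_z
  x <- array(sol$dT, dim = c(nr, nth, nz))
  out_in <- sum(sol$mats$Gin * x[1, , ])
  out_out <- sum(sol$mats$Gout * x[nr, , ])
  out_z <- sum(sol$mats$Gz1 * x[, , 1]) + sum(sol$mats$Gz2 * x[, , nz])
  gen <- sum(sol$source)
  out <- out_in + out_out + out_z
  list(generated = gen, outflow = out,
       relative_error = if (gen > 0) abs(out - gen) / gen else abs(out))
}

#' Average heat flux through the sensor
#'
#' Area-averaged conductive flux through the sensor faces: the face toward
#' the infection (`front`, at the sensor's outer radius) and the face toward
#' the lumen (`back`, at its inner radius), both taken positive for heat
#' flowing toward the lumen.  The default `"mean"` convention reports the
#' average of the two through-fluxes, which is the printed
#' half-difference when each face carries its own outward normal;
#' `"signed_difference"` reports `(q_front - q_back)/2` with both fluxes
#' lumen-oriented (the net heat absorbed by the sensor sheet, near zero in
#' steady state).
#'
#' @param sol A `graft_solution`.
#' @param convention `"mean"` (default) or `"signed_difference"`.
#' @return List with `q_avg`, `q_front`, `q_back` (W/m2).
#' @export
sensor_flux <- function(sol, convention = c("mean", "signed_difference")) {
  convention <- match.arg(convention)
  m <- sol$model
  nr <- m$nr; nth <- m$n_theta; nz <- m$n_z
  x <- array(sol$dT, dim = c(nr, nth, nz))
  K <- m$K; rf <- m$rf; dr <- diff(rf)
  is_s <- which(m$layer == "sensor_layer")
  i_top <- max(is_s); i_bot <- min(is_s)
  jj <- which(m$foot_th); kk <- which(m$foot_z)
  # face conductance arrays for the two interface radii
  face_q <- function(i_in, i_out) {
    A <- rf[i_out] * m$dth * m$dz
    G <- A / (0.5 * dr[i_in] / K[i_in, jj, kk] +
              0.5 * dr[i_out] / K[i_out, jj, kk])
    # inward (toward lumen) heat flow through the face, W
    Fw <- G * (x[i_out, jj, kk] - x[i_in, jj, kk])
    sum(Fw) / (length(jj) * length(kk) * A)
  }
  q_front <- face_q(i_top, i_top + 1L)     # infection-facing interface
  q_back <- face_q(i_bot - 1L, i_bot)      # lumen-facing interface
  q_avg <- switch(convention,
                  mean = (q_front + q_back) / 2,
                  signed_difference = (q_front - q_back) / 2)
  list(q_avg = q_avg, q_front = q_front, q_back = q_back)
}

#' Heat-transfer efficiency of the graft wall
#'
#' Applies a uniform inward heat flux on the graft outer wall over a patch
#' congruent with the sensor footprint (no volumetric source) and reports the
#' percentage of it recovered as sensor-average flux,
#' `100 * q_avg / applied_flux`.  By linearity the result is independent of
#' the applied magnitude.
#'
#' @param model A [graft_model()].
#' @param bcs A [thermal_bcs()].
#' @param applied_flux W/m2, > 0 (default 1).
#' @param factor optional prebuilt [graft_factor()].
#' @return Efficiency in percent.
#' @export
heat_transfer_efficiency <- function(model, bcs, applied_flux = 1,
                                     factor = NULL) {
  if (applied_flux <= 0)
    stop("`applied_flux` must be > 0", call. = FALSE)
  sol <- solve_conduction(model, bcs, Q = 0,
                          extra_source = patch_source(model, applied_flux),
                          factor = factor)
  100 * sensor_flux(sol)$q_avg / applied_flux
}

#' Temperature rise at the sensor
#'
#' @param sol A `graft_solution`.
#' @return List with `dT_sensor` (max rise over the sensor cells, K) and
#'   `dT_global` (max rise anywhere).
#' @export
max_temperature_rise <- function(sol) {
  list(dT_sensor = max(sol$dT[as.vector(sol$model$sensor_mask)]),
       dT_global = max(sol$dT))
}

#' Detectability sweep over the infection parameter space
#'
#' One conduction solve per combination of blood-side `h`, source density
#' `Q`, infection radius and sensor-infection arc length `d`; the conduction
#' factor is reused across all rows sharing an `h`.  A row is detectable when
#' the sensor-average flux reaches the sensor resolution.
#'
#' @param model A [graft_model()].
#' @param h_grid W/(m2 K) values (default the canonical 200...4800 set).
#' @param Q_grid W/m3 values (default 1000...50000).
#' @param radius_grid m (default 2 and 4 mm).
#' @param d_grid m (default 0 to 8 mm).
#' @param resolution W/m2 (default 0.41).
#' @return A data.frame of class `sweep_result` with columns `h_W_m2K`,
#'   `Q_W_m3`, `radius_mm`, `d_mm`, `q_sensor_W_m2`, `detectable`, `dT_K`.
#' @export
detectability_sweep <- function(model,
                                h_grid = c(200, 600, 1200, 2400, 4800),
                                Q_grid = c(1000, 2000, 4000, 10000, 50000),
                                radius_grid = c(0.002, 0.004),
                                d_grid = seq(0, 0.008, by = 0.002),
                                resolution = 0.41) {
  stopifnot(inherits(model, "graft_model"))
  if (!length(h_grid) || !length(Q_grid) || !length(radius_grid) ||
      !length(d_grid))
    stop("all sweep grids must be non-empty", call. = FALSE)
  rows <- list()
  for (h in h_grid) {
    fac <- graft_factor(model, thermal_bcs(h_inner = h))
    for (rad in radius_grid) for (d in d_grid) {
      # solve at unit density once, scale by linearity over Q
      base <- try(solve_conduction(model, thermal_bcs(h_inner = h), Q = 1,
                                   infection_radius = rad, d = d,
                                   factor = fac), silent = TRUE)
      for (Q in Q_grid) {
        if (inherits(base, "try-error")) {
          rows[[length(rows) + 1L]] <-
            data.frame(h_W_m2K = h, Q_W_m3 = Q, radius_mm = 1e3 * rad,
                       d_mm = 1e3 * d, q_sensor_W_m2 = NA_real_,
                       detectable = NA, dT_K = NA_real_)
          next
        }
        q <- Q * sensor_flux(base)$q_avg
        dT <- Q * max_temperature_rise(base)$dT_sensor
        rows[[length(rows) + 1L]] <-
          data.frame(h_W_m2K = h, Q_W_m3 = Q, radius_mm = 1e3 * rad,
                     d_mm = 1e3 * d, q_sensor_W_m2 = q,
                     detectable = q >= resolution, dT_K = dT)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "resolution") <- resolution
  class(out) <- c("sweep_result", "data.frame")
  out
}
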