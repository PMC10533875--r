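# Shared fixtures, built lazily and cached for the session so expensive
# solves (marching flow, 3D factorizations) run once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

blood <- function() fluid_properties()

# water-like fluid used where exact constants are convenient
water_like <- function() fluid_properties(density = 1000,
                                          dynamic_viscosity = 1e-3,
                                          specific_heat = 4000,
                                          thermal_conductivity = 0.6)

# low-Prandtl fluid so thermal development completes inside the domain
air_like <- function() fluid_properties(density = 1.2,
                                        dynamic_viscosity = 1.8e-5,
                                        specific_heat = 1005,
                                        thermal_conductivity = 0.026)

aorta <- function() vessel_geometry(inner_radius = 0.01, length = 0.20)

# steady transitional-regime flow/temperature at the canonical 0.35 m/s
flow_035 <- function() fixture("flow_035", function()
  solve_steady_flow(aorta(), blood(), 0.35, closure = "mixing_length"))
temp_035 <- function() fixture("temp_035", function()
  solve_temperature(flow_035(), blood()))

# coarse 3D graft model (full three-cylinder) and a matching factor cache
graft_coarse <- function() fixture("graft_coarse", function()
  graft_model(n_theta = 48, n_z = 30, nr_wall = 2, nr_sensor = 2,
              nr_infection = 1, nr_tissue = 6))
graft_factor_at <- function(h) fixture(paste0("gfac_", h), function()
  graft_factor(graft_coarse(), thermal_bcs(h_inner = h)))

# scaled-down pulsatile h runs shared by the transient and acceptance tests
transient_fixtures <- function() fixture("transient_set", function() {
  fl <- flow_035()
  g <- radial_grid(0.01, length(fl$eta), stretch = 2.5)
  b <- blood()
  u0 <- solve_oscillatory(g, b, source_term("constant_zero"),
                          t_end = 4, dt = 0.01)
  us <- solve_oscillatory(g, b, source_term("sinusoidal", amplitude = 100,
                                            frequency = 1),
                          t_end = 4, dt = 0.01)
  list(
    fl = fl,
    h0 = transient_h(fl, u0, b, t_end = 4, n_z_t = 100),
    hs = transient_h(fl, us, b, t_end = 4, n_z_t = 100))
})
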