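#' Radial grid from axis to wall
#'
#' Node grid for the 1D radial solvers: first node on the axis (r = 0), last
#' node on the wall (r = R).  `stretch = 0` gives uniform spacing; positive
#' values cluster nodes toward the wall with a tanh mapping, which resolves
#' the thin Stokes layer at high Womersley number.
#'
#' @param R m, wall radius, > 0.
#' @param n number of nodes, >= 32.
#' @param stretch wall-clustering strength (0 = uniform, ~2-3 typical).
#' @return Object of class `radial_grid` with fields `r` (nodes) and `R`.
#' @export
radial_grid <- function(R, n = 64, stretch = 0) {
  if (R <= 0) stop("`R` must be > 0", call. = FALSE)
  if (n < 32) stop("need at least 32 radial nodes", call. = FALSE)
  xi <- seq(0, 1, length.out = n)
  r <- if (stretch > 0) R * tanh(stretch * xi) / tanh(stretch)
       else R * xi
  structure(list(r = r, R = R), class = "radial_grid")
}

# tridiagonal solver (Thomas algorithm); a = sub, b = diag, c = super
solve_tridiag <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]; dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- if (i < n) c[i] / m else 0
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# radial cylindrical-Laplacian operator mu*(u'' + u'/r) as tridiagonal bands
# for the node grid `r` (first node at axis, symmetry limit 2*u'' there).
# Returns list(a, b, c): sub/diag/super coefficients of L (wall row excluded
# from the returned operator; Dirichlet handled by caller).
radial_laplacian_bands <- function(r, mu) {
  n <- length(r)
  a <- numeric(n); b <- numeric(n); cc <- numeric(n)
  h1 <- r[2] - r[1]
  # axis node: L u = 2 mu u'' with u'(0) = 0 -> 4 mu (u2 - u1)/h1^2
  b[1] <- -4 * mu / h1^2
  cc[1] <- 4 * mu / h1^2
  for (i in 2:(n - 1)) {
    hm <- r[i] - r[i - 1]
    hp <- r[i + 1] - r[i]
    rp <- 0.5 * (r[i + 1] + r[i])
    rm <- 0.5 * (r[i] + r[i - 1])
    w <- r[i] * 0.5 * (hm + hp)
    a[i] <- mu * rm / (hm * w)
    cc[i] <- mu * rp / (hp * w)
    b[i] <- -(a[i] + cc[i])
  }
  list(a = a, b = b, c = cc)
}

#' Solve for the oscillatory velocity component
#'
#' Integrates the linear momentum equation for the oscillatory axial velocity
#' `u(r, t)`,
#' `rho du/dt = mu (d2u/dr2 + (1/r) du/dr) + s(t, z)`,
#' with no-slip at the wall (`u(R, t) = 0`), symmetry at the axis and `u = 0`
#' initial condition, using a Crank-Nicolson (trapezoidal) step, which is
#' unconditionally stable and second order in time.  The `(1/r) du/dr` axis
#' singularity is removable and replaced by its symmetry limit `2 d2u/dr2`.
#'
#' The forcing is evaluated at the retarded time for station `z`, matching the
#' travelling-wave character of the pressure pulse; the radial problem at each
#' axial station is otherwise decoupled.
#'
#' @param grid A [radial_grid()].
#' @param props A [fluid_properties()].
#' @param source A [source_term()].
#' @param z m, axial station for retarded-time evaluation (default 0).
#' @param t_end s, integration horizon (default 10).
#' @param dt s, time step; must resolve the forcing with at least 20 steps per
#'   period (50 or more recommended).
#' @return Object of class `oscillatory_velocity_field`: `u` is an
#'   `nt x nr` matrix (rows = times in `times`, columns = nodes in `grid$r`).
#' @export
solve_oscillatory <- function(grid, props, source, z = 0, t_end = 10,
                              dt = 0.005) {
  stopifnot(inherits(grid, "radial_grid"),
            inherits(props, "fluid_properties"),
            inherits(source, "source_term"))
  if (dt <= 0 || t_end <= 0) stop("`dt` and `t_end` must be > 0",
                                  call. = FALSE)
  Tp <- source_period(source)
  if (is.finite(Tp) && Tp / dt < 20)
    stop("`dt` too coarse: ", round(Tp / dt, 1), " steps per forcing period; ",
         "use at least 20 (>= 50 recommended)", call. = FALSE)
  r <- grid$r
  n <- length(r)
  rho <- props$density
  L <- radial_laplacian_bands(r, props$dynamic_viscosity)
  nt <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = nt + 1L)
  U <- matrix(0, nrow = nt + 1L, ncol = n)
  # Crank-Nicolson bands for interior + axis nodes (wall row is identity)
  ai <- -0.5 * dt / rho * L$a
  bi <- 1 - 0.5 * dt / rho * L$b
  ci <- -0.5 * dt / rho * L$c
  ai[n] <- 0; bi[n] <- 1; ci[n] <- 0
  u <- numeric(n)
  for (k in seq_len(nt)) {
    s_mid <- evaluate_source(source, times[k] + dt / 2, z)
    Lu <- numeric(n)
    Lu[1] <- L$b[1] * u[1] + L$c[1] * u[2]
    i <- 2:(n - 1)
    Lu[i] <- L$a[i] * u[i - 1] + L$b[i] * u[i] + L$c[i] * u[i + 1]
    rhs <- u + 0.5 * dt / rho * Lu + dt / rho * s_mid
    rhs[n] <- 0
    u <- solve_tridiag(ai, bi, ci, rhs)
    U[k + 1L, ] <- u
  }
  structure(list(u = U, times = times, grid = grid, source = source,
                 z = z, dt = dt, props = props),
            class = "oscillatory_velocity_field")
}

# complex Bessel function of the first kind, order zero, by power series.
# Accurate to ~1e-12 relative for |z| <= 30.
besselJ0_complex <- function(z) {
  if (Mod(z) > 30)
    stop("|argument| > 30: power-series J0 loses accuracy; ",
         "use an asymptotic branch for such Womersley numbers", call. = FALSE)
  term <- 1 + 0i
  s <- term
  q <- -(z / 2)^2
  for (k in 1:200) {
    term <- term * q / k^2
    s <- s + term
    if (Mod(term) < 1e-18 * max(Mod(s), 1e-300)) break
  }
  s
}

#' Analytic Womersley velocity profile
#'
#' Closed-form periodic solution of the oscillatory pipe-flow equation with
#' forcing `K exp(i w t)` (w = 2 pi f):
#' `u_hat(r) = (K / (i rho w)) * (1 - J0(i^{3/2} alpha r/R) / J0(i^{3/2} alpha))`,
#' with the physical velocity `Re(u_hat(r) exp(i w t))`.  For a sinusoidal
#' forcing `K sin(w t)` the physical velocity is `Im(u_hat(r) exp(i w t))`.
#' Serves as the independent verification oracle for [solve_oscillatory()].
#'
#' As `alpha -> 0` the profile reduces to the quasi-steady Poiseuille form
#' `K (R^2 - r^2) / (4 mu)`.
#'
#' @param alpha Womersley number, > 0 (and <= 30 for the power-series Bessel).
#' @param forcing_amplitude K, Pa/m.
#' @param f Hz, forcing frequency.
#' @param props A [fluid_properties()].
#' @param R m, pipe radius.
#' @param r_over_R radial positions as fractions of R, in `[0, 1]`.
#' @return Complex vector of velocity amplitudes (m/s), one per `r_over_R`.
#' @export
analytic_womersley <- function(alpha, forcing_amplitude, f, props, R,
                               r_over_R) {
  stopifnot(inherits(props, "fluid_properties"))
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (any(r_over_R < 0 | r_over_R > 1))
    stop("`r_over_R` must lie in [0, 1]", call. = FALSE)
  omega <- 2 * pi * f
  i32 <- complex(modulus = 1, argument = 3 * pi / 4)  # i^{3/2}
  denom <- besselJ0_complex(i32 * alpha)
  num <- vapply(r_over_R,
                function(x) besselJ0_complex(i32 * alpha * x),
                complex(1))
  (forcing_amplitude / (1i * props$density * omega)) * (1 - num / denom)
}

#' Total axial velocity field
#'
#' Superposition `v_z(r, t) = v_mean_profile(r) + u(r, t)` of a steady profile
#' and an oscillatory component on the same radial grid.
#'
#' @param v_mean_profile m/s, steady velocity at each node of the grid of `u`.
#' @param u An `oscillatory_velocity_field`.
#' @return Matrix `nt x nr` of total velocity.
#' @export
total_velocity <- function(v_mean_profile, u) {
  stopifnot(inherits(u, "oscillatory_velocity_field"))
  if (length(v_mean_profile) != ncol(u$u))
    stop("steady profile and oscillatory field grids differ", call. = FALSE)
  sweep(u$u, 2, v_mean_profile, `+`)
}

#' Area-weighted cross-sectional mean of a radial profile
#'
#' `2/R^2 * int_0^R v(r) r dr` by the trapezoidal rule on the node grid.
#'
#' @param v velocity (or any scalar) at the grid nodes.
#' @param grid A [radial_grid()].
#' @return Scalar mean.
#' @export
profile_mean <- function(v, grid) {
  stopifnot(inherits(grid, "radial_grid"))
  r <- grid$r
  2 / grid$R^2 * sum(diff(r) * 0.5 * (v[-1] * r[-1] + v[-length(v)] * r[-length(r)]))
}
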