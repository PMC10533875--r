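#' Periodic pressure waveform
#'
#' Container for a periodic pressure trace sampled on a uniform time grid
#' covering exactly one period.  Samples are stored over `[0, period)`; the
#' value at `t = period` wraps to the first sample.
#'
#' @param times s, strictly increasing uniform grid starting at 0.
#' @param pressures Pa, finite values, one per time sample.
#' @param period s; defaults to `n * dt` (grid step times sample count).
#' @return An object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(times, pressures, period = NULL) {
  if (length(times) < 8L) stop("need at least 8 samples", call. = FALSE)
  if (length(times) != length(pressures))
    stop("`times` and `pressures` lengths differ", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9 * mean(dt))
    stop("`times` must be uniformly spaced", call. = FALSE)
  if (!all(is.finite(pressures))) stop("pressures must be finite",
                                       call. = FALSE)
  if (is.null(period)) period <- length(times) * mean(dt)
  structure(list(times = times - times[1], pressures = pressures,
                 period = period),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf(
    "<pressure_waveform> %d samples, period %.4g s, range [%.4g, %.4g] Pa\n",
    length(x$times), x$period, min(x$pressures), max(x$pressures)))
  invisible(x)
}

#' Synthesize an aortic pressure waveform
#'
#' Builds a smooth band-limited periodic pressure trace with the qualitative
#' features of an aortic root measurement: a systolic upstroke, a dicrotic
#' notch with a damped secondary oscillation, and a diastolic decay.  The
#' trace is the truncated Fourier series (up to `n_harmonics`) of a template
#' pulse, affinely rescaled so that its maximum and minimum equal `systolic`
#' and `diastolic` exactly.  A small seeded perturbation of the harmonic
#' amplitudes makes distinct seeds distinct while keeping the physiology.
#'
#' This is a synthetic surrogate for a digitized physiological recording; it
#' matches published aortic traces only in frequency content and amplitude,
#' not beat-to-beat morphology.
#'
#' @param heart_rate beats/min, > 0 (default 60, i.e. 1 Hz).
#' @param systolic Pa, peak pressure (default 15999 Pa = 120 mmHg).
#' @param diastolic Pa, trough pressure (default 10666 Pa = 80 mmHg).
#' @param n_harmonics number of Fourier harmonics retained, >= 2 (default 8).
#' @param n_samples samples per period (default 256).
#' @param seed integer seed controlling the harmonic perturbation.
#' @return A [pressure_waveform()].
#' @export
synth_aortic_waveform <- function(heart_rate = 60, systolic = 15999,
                                  diastolic = 10666, n_harmonics = 8,
                                  n_samples = 256, seed = 1L) {
  if (heart_rate <= 0) stop("`heart_rate` must be > 0", call. = FALSE)
  if (diastolic <= 0 || systolic <= diastolic)
    stop("need systolic > diastolic > 0", call. = FALSE)
  if (n_harmonics < 2) stop("`n_harmonics` must be >= 2", call. = FALSE)
  period <- 60 / heart_rate
  x <- seq(0, 1, length.out = n_samples + 1L)[seq_len(n_samples)]
  # template pulse on the unit interval: systolic bump + damped dicrotic wave
  base <- exp(-((x - 0.16) / 0.09)^2) +
    0.28 * exp(-((x - 0.46) / 0.06)^2) -
    0.10 * exp(-((x - 0.38) / 0.035)^2) +
    0.15 * (1 - x)
  co <- stats::fft(base) / n_samples
  keep <- rep(0, n_samples)
  keep[1] <- 1
  idx <- seq_len(n_harmonics)
  jit <- withr_seed(seed, stats::runif(n_harmonics, -0.03, 0.03))
  keep[1 + idx] <- 1 + jit
  keep[n_samples + 1 - idx] <- 1 + jit
  smooth <- Re(stats::fft(co * keep, inverse = TRUE))
  lo <- min(smooth); hi <- max(smooth)
  p <- diastolic + (smooth - lo) / (hi - lo) * (systolic - diastolic)
  pressure_waveform(times = x * period, pressures = p, period = period)
}

# run `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a pressure waveform from CSV
#'
#' Expects a header `time_s,pressure_pa` and at least 8 rows covering one
#' period (the first and last rows are taken as the same phase one period
#' apart).  Arbitrary, possibly non-uniform, strictly increasing time grids
#' are accepted and linearly resampled to a uniform grid.
#'
#' @param path CSV file path.
#' @param n_samples uniform samples per period in the result (default 256).
#' @return A [pressure_waveform()].
#' @export
load_waveform_csv <- function(path, n_samples = 256) {
  df <- utils::read.csv(path)
  need <- c("time_s", "pressure_pa")
  if (!all(need %in% names(df)))
    stop("CSV must have columns `time_s,pressure_pa`", call. = FALSE)
  if (nrow(df) < 8L)
    stop("need at least 8 rows, got ", nrow(df), call. = FALSE)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop("non-monotone times at row ", bad[1] + 1L, call. = FALSE)
  period <- df$time_s[nrow(df)] - df$time_s[1]
  tt <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  p <- stats::approx(df$time_s - df$time_s[1], df$pressure_pa, xout = tt,
                     rule = 2)$y
  pressure_waveform(times = tt, pressures = p, period = period)
}

#' Write a pressure waveform to CSV
#'
#' Inverse of [load_waveform_csv()]; writes `time_s,pressure_pa` rows covering
#' one period plus the wrap sample.
#'
#' @param w A [pressure_waveform()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "pressure_waveform"))
  df <- data.frame(time_s = c(w$times, w$period),
                   pressure_pa = c(w$pressures, w$pressures[1]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Periodic time derivative of a waveform
#'
#' Spectral differentiation: the derivative of the trigonometric interpolant
#' of the periodic samples.  The mean of the derivative over one period is
#' zero by construction.
#'
#' @param w A [pressure_waveform()].
#' @return Numeric vector, Pa/s, one value per sample of `w`.
#' @export
waveform_time_derivative <- function(w) {
  stopifnot(inherits(w, "pressure_waveform"))
  n <- length(w$pressures)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0  # drop the unmatched Nyquist mode
  omega <- 2i * pi * k / w$period
  Re(stats::fft(omega * stats::fft(w$pressures) / n, inverse = TRUE))
}

#' PDE forcing terms for the oscillatory velocity component
#'
#' Constructs the source term `s(t, z)` driving the oscillatory-velocity
#' momentum equation.  Three kinds are supported:
#' \describe{
#'   \item{`constant_zero`}{no pulsation, `s = 0`.}
#'   \item{`sinusoidal`}{`s = A sin(2 pi f (t - z/c))` under the default
#'     amplitude convention, where `A` (Pa/m) is the amplitude of the full
#'     forcing, `f` the frequency and `c` the pulse wave velocity.  With
#'     `convention = "divided_by_c"` the forcing is additionally divided by
#'     `c`, the literal transliteration of writing the source as
#'     `(1/c) dP/dt` with `A` carrying units of Pa/m.}
#'   \item{`waveform`}{`s = (1/c) dP/dt` evaluated at the retarded time
#'     `t - z/c` with periodic wrap, for a measured or synthetic pressure
#'     trace `P`.}
#'   \item{`constant`}{steady forcing `s = A` (Pa/m), the step-forcing case
#'     whose long-time solution is the Poiseuille profile; used mainly for
#'     solver verification.}
#' }
#'
#' @param kind one of `"constant_zero"`, `"sinusoidal"`, `"waveform"`.
#' @param amplitude Pa/m, sinusoidal amplitude `A` (>= 0).
#' @param frequency Hz, sinusoidal frequency (> 0).
#' @param c_wave m/s, pulse wave velocity (default 8.8).
#' @param waveform A [pressure_waveform()] for the `waveform` kind.
#' @param convention `"amplitude"` (default) or `"divided_by_c"`.
#' @return An object of class `source_term`.
#' @export
source_term <- function(kind = c("constant_zero", "sinusoidal", "waveform",
                                 "constant"),
                        amplitude = 100, frequency = 1, c_wave = 8.8,
                        waveform = NULL,
                        convention = c("amplitude", "divided_by_c")) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  if (c_wave <= 0) stop("`c_wave` must be > 0", call. = FALSE)
  if (kind == "sinusoidal") {
    if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
    if (frequency <= 0) stop("`frequency` must be > 0", call. = FALSE)
  }
  if (kind == "waveform") {
    if (!inherits(waveform, "pressure_waveform"))
      stop("`waveform` must be a pressure_waveform", call. = FALSE)
    waveform$dpdt <- waveform_time_derivative(waveform)
  }
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 c_wave = c_wave, waveform = waveform,
                 convention = convention),
            class = "source_term")
}

#' Evaluate a forcing term
#'
#' @param s A [source_term()].
#' @param t s, time(s) >= 0.
#' @param z m, axial position (scalar), >= 0.
#' @return Forcing in Pa/m, same length as `t`.
#' @export
evaluate_source <- function(s, t, z = 0) {
  stopifnot(inherits(s, "source_term"), length(z) == 1L)
  if (any(t < 0) || z < 0) stop("`t` and `z` must be >= 0", call. = FALSE)
  tau <- t - z / s$c_wave
  switch(s$kind,
    constant_zero = rep(0, length(t)),
    constant = rep(s$amplitude, length(t)),
    sinusoidal = {
      amp <- if (s$convention == "divided_by_c")
        s$amplitude / s$c_wave else s$amplitude
      amp * sin(2 * pi * s$frequency * tau)
    },
    waveform = {
      w <- s$waveform
      ph <- (tau %% w$period) / w$period * length(w$times)
      i0 <- floor(ph) %% length(w$times)
      i1 <- (i0 + 1L) %% length(w$times)
      fr <- ph - floor(ph)
      ((1 - fr) * w$dpdt[i0 + 1L] + fr * w$dpdt[i1 + 1L]) / s$c_wave
    })
}

#' Period of a forcing term
#'
#' @param s A [source_term()].
#' @return Period in s (`Inf` for the zero source).
#' @export
source_period <- function(s) {
  stopifnot(inherits(s, "source_term"))
  switch(s$kind,
    constant_zero = Inf,
    constant = Inf,
    sinusoidal = 1 / s$frequency,
    waveform = s$waveform$period)
}
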