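#' Acoustic medium
#'
#' A lossless fluid described by density and sound speed. Constructors are
#' provided for the fluids used in the sorting analyses: water (droplet
#' phase), fluorinated carrier oil (HFE-7500 class) and an MCF-7-like cell
#' treated as an effective fluid sphere.
#'
#' @param density kg/m^3 (> 0).
#' @param sound_speed m/s (> 0).
#' @return An `acoustic_medium` object.
#' @export
acoustic_medium <- function(density, sound_speed) {
  stopifnot(density > 0, sound_speed > 0)
  structure(list(density = density, sound_speed = sound_speed),
            class = "acoustic_medium")
}

#' @rdname acoustic_medium
#' @export
acoustic_water <- function() acoustic_medium(998, 1481)

#' @rdname acoustic_medium
#' @export
acoustic_hfe7500 <- function() acoustic_medium(1614, 660)

#' @rdname acoustic_medium
#' @export
acoustic_mcf7 <- function() acoustic_medium(1068, 1550)

#' Acoustic radiation setup
#'
#' Traveling-wave actuation of a spherical particle (droplet or cell) in a
#' host fluid. Defaults follow the sorting configuration: 132 MHz drive
#' (30 um surface-wave wavelength on the substrate; the fluid wavenumber
#' uses the host sound speed) and a nominal energy density chosen so that
#' a 5 ms pulse deflects a droplet across the outlet bifurcation.
#'
#' @param frequency_hz Drive frequency (default 132e6).
#' @param energy_density Mean acoustic energy density E in J/m^3
#'   (default 5).
#' @param particle_radius_um Particle radius (um).
#' @param host,particle `acoustic_medium` objects.
#' @return An `arf_setup` object.
#' @export
arf_setup <- function(frequency_hz = 132e6, energy_density = 5,
                      particle_radius_um = 20,
                      host = acoustic_hfe7500(),
                      particle = acoustic_water()) {
  stopifnot(frequency_hz > 0, energy_density >= 0, particle_radius_um > 0)
  structure(list(frequency_hz = frequency_hz,
                 energy_density = energy_density,
                 particle_radius_um = particle_radius_um,
                 host = host, particle = particle),
            class = "arf_setup")
}

# spherical Bessel functions via half-integer-order cylindrical Bessels;
# warnings from the far series tail (n >> kr) are benign: j underflows, y
# overflows, and the scattering coefficient correctly collapses to zero
sph_jn <- function(n, x)
  suppressWarnings(sqrt(pi / (2 * x)) * besselJ(x, n + 0.5))
sph_yn <- function(n, x)
  suppressWarnings(sqrt(pi / (2 * x)) * besselY(x, n + 0.5))
sph_hn <- function(n, x) complex(real = sph_jn(n, x),
                                 imaginary = sph_yn(n, x))

# derivative by recurrence: f_n'(x) = f_{n-1}(x) - (n+1)/x f_n(x)
sph_jn_d <- function(n, x) {
  if (n == 0) return(-sph_jn(1, x))
  sph_jn(n - 1, x) - (n + 1) / x * sph_jn(n, x)
}
sph_yn_d <- function(n, x) {
  if (n == 0) return(-sph_yn(1, x))
  sph_yn(n - 1, x) - (n + 1) / x * sph_yn(n, x)
}
sph_hn_d <- function(n, x) complex(real = sph_jn_d(n, x),
                                   imaginary = sph_yn_d(n, x))

#' Partial-wave scattering coefficient of a fluid sphere
#'
#' For an incident plane wave \eqn{p_{inc} = \sum_n i^n (2n+1) j_n(kr)
#' P_n(\cos\theta)}, the scattered wave is \eqn{\sum_n i^n (2n+1) c_n
#' h_n^{(1)}(kr) P_n} with \eqn{c_n} fixed by continuity of pressure and
#' normal velocity at the sphere surface:
#' \deqn{c_n = -\frac{j_n'(x)\, j_n(x_1) - \zeta\, j_n(x)\, j_n'(x_1)}
#'                  {h_n'(x)\, j_n(x_1) - \zeta\, h_n(x)\, j_n'(x_1)},}
#' where \eqn{x = k a}, \eqn{x_1 = k_1 a} and \eqn{\zeta = \rho c /
#' (\rho_1 c_1)} is the host-to-particle specific impedance ratio.
#'
#' @param n Partial-wave order (>= 0).
#' @param setup An [arf_setup()].
#' @return Complex coefficient; identically 0 when particle and host
#'   match.
#' @export
scattering_coefficient <- function(n, setup) {
  stopifnot(n >= 0)
  a <- setup$particle_radius_um * 1e-6
  w <- 2 * pi * setup$frequency_hz
  k0 <- w / setup$host$sound_speed
  k1 <- w / setup$particle$sound_speed
  x <- k0 * a; x1 <- k1 * a
  zeta <- (setup$host$density * setup$host$sound_speed) /
    (setup$particle$density * setup$particle$sound_speed)
  num <- sph_jn_d(n, x) * sph_jn(n, x1) - zeta * sph_jn(n, x) * sph_jn_d(n, x1)
  den <- sph_hn_d(n, x) * sph_jn(n, x1) - zeta * sph_hn(n, x) * sph_jn_d(n, x1)
  if (!is.finite(Re(den)) || !is.finite(Im(den)))
    return(complex(real = 0, imaginary = 0)) # series tail beyond overflow
  -num / den
}

#' Boundary-condition residual of a scattering coefficient
#'
#' Checks that the computed coefficients satisfy the fluid-fluid matching
#' conditions: the interior amplitude implied by pressure continuity must
#' also satisfy velocity continuity. Returns the relative residual of the
#' velocity condition.
#'
#' @inheritParams scattering_coefficient
#' @return Non-negative residual (machine-precision small for valid
#'   coefficients).
#' @export
scattering_residual <- function(n, setup) {
  a <- setup$particle_radius_um * 1e-6
  w <- 2 * pi * setup$frequency_hz
  k0 <- w / setup$host$sound_speed
  k1 <- w / setup$particle$sound_speed
  x <- k0 * a; x1 <- k1 * a
  zeta <- (setup$host$density * setup$host$sound_speed) /
    (setup$particle$density * setup$particle$sound_speed)
  cn <- scattering_coefficient(n, setup)
  bn <- (sph_jn(n, x) + cn * sph_hn(n, x)) / sph_jn(n, x1) # pressure
  lhs <- sph_jn_d(n, x) + cn * sph_hn_d(n, x)              # velocity
  rhs <- zeta * bn * sph_jn_d(n, x1)
  scale <- max(Mod(lhs), Mod(rhs), .Machine$double.eps)
  Mod(lhs - rhs) / scale
}

#' Traveling-wave acoustic radiation force factor
#'
#' Computes the dimensionless radiation force factor \eqn{Y_T} of a fluid
#' sphere in a plane traveling wave from the partial-wave series
#' (Yosioka-Kawasima / Hasegawa form). With \eqn{c_n = \alpha_n +
#' i\beta_n},
#' \deqn{Y_T = -\frac{4}{x^2}\sum_{n\ge 0}(n+1)\left[\alpha_n +
#'   \alpha_{n+1} + 2(\alpha_n\alpha_{n+1} + \beta_n\beta_{n+1})\right],}
#' and the force is \eqn{F = Y_T \pi a^2 E}. The series is truncated
#' adaptively once terms fall below `tol` times the partial sum
#' (safeguarded past the geometric-optics shoulder at \eqn{n \approx x}).
#'
#' @param setup An [arf_setup()].
#' @param n_max Hard cap on the series order (default `kr + 60`).
#' @param tol Relative truncation tolerance (default 1e-12).
#' @return Dimensionless \eqn{Y_T} (0 for a contrast-matched particle).
#' @export
radiation_force_factor <- function(setup, n_max = NULL, tol = 1e-12) {
  a <- setup$particle_radius_um * 1e-6
  x <- 2 * pi * setup$frequency_hz / setup$host$sound_speed * a
  if (is.null(n_max)) n_max <- ceiling(x) + 60
  cn <- vapply(0:(n_max + 1), scattering_coefficient, complex(1),
               setup = setup)
  al <- Re(cn); be <- Im(cn)
  n <- 0:n_max
  terms <- -(4 / x^2) * (n + 1) *
    (al[n + 1] + al[n + 2] + 2 * (al[n + 1] * al[n + 2] +
                                  be[n + 1] * be[n + 2]))
  # adaptive cutoff: ignore terms after they drop below tol * running sum,
  # but never before the series shoulder at n ~ x
  csum <- cumsum(terms)
  shoulder <- which(n > x + 10)
  if (length(shoulder) > 0) {
    small <- abs(terms) < tol * pmax(abs(csum), .Machine$double.eps)
    idx <- shoulder[small[shoulder]]
    if (length(idx) > 0) return(csum[idx[1]])
    warning("partial-wave series not converged at n_max = ", n_max)
  }
  csum[length(csum)]
}

#' Rayleigh-regime radiation force factor (closed form)
#'
#' Small-particle (\eqn{ka \ll 1}) limit of the traveling-wave radiation
#' force on a fluid sphere, from monopole and dipole scattering:
#' \deqn{Y_T \approx \frac{4}{9}(ka)^4\left[f_0^2 + f_0 f_1 +
#'   \frac{3}{4}f_1^2\right],\quad f_0 = 1 -
#'   \frac{\kappa_p}{\kappa_0},\quad f_1 =
#'   \frac{2(\tilde\rho - 1)}{2\tilde\rho + 1},}
#' with \eqn{\tilde\rho = \rho_p/\rho_0} and compressibilities
#' \eqn{\kappa = 1/(\rho c^2)}.
#'
#' @param setup An [arf_setup()].
#' @return Dimensionless \eqn{Y_T} approximation.
#' @export
rayleigh_force_factor <- function(setup) {
  a <- setup$particle_radius_um * 1e-6
  x <- 2 * pi * setup$frequency_hz / setup$host$sound_speed * a
  kap0 <- 1 / (setup$host$density * setup$host$sound_speed^2)
  kap1 <- 1 / (setup$particle$density * setup$particle$sound_speed^2)
  f0 <- 1 - kap1 / kap0
  rho_t <- setup$particle$density / setup$host$density
  f1 <- 2 * (rho_t - 1) / (2 * rho_t + 1)
  (4 / 9) * x^4 * (f0^2 + f0 * f1 + 0.75 * f1^2)
}

#' Acoustic radiation force on a particle
#'
#' \eqn{F = Y_T \, \pi r^2 \, E}: linear in the energy density and
#' quadratic in the radius at fixed \eqn{Y_T}.
#'
#' @param Y_T Radiation force factor (dimensionless, >= 0 for the cases
#'   considered).
#' @param radius_um Particle radius in um.
#' @param energy_density E in J/m^3.
#' @return Force in newtons.
#' @export
arf_force <- function(Y_T, radius_um, energy_density) {
  stopifnot(radius_um >= 0, energy_density >= 0)
  Y_T * pi * (radius_um * 1e-6)^2 * energy_density
}

#' Y_T versus particle diameter table
#'
#' @param diameters_um Particle diameters to evaluate.
#' @param setup Base [arf_setup()]; the droplet column uses its
#'   host/particle pair, the cell column uses an MCF-7-like sphere in
#'   water.
#' @return data.frame with `diameter_um`, `Y_T_droplet`, `Y_T_cell`,
#'   `force_droplet_N`.
#' @export
yt_table <- function(diameters_um = seq(10, 80, by = 10),
                     setup = arf_setup()) {
  rows <- lapply(diameters_um, function(d) {
    s_drop <- arf_setup(setup$frequency_hz, setup$energy_density,
                        d / 2, setup$host, setup$particle)
    s_cell <- arf_setup(setup$frequency_hz, setup$energy_density,
                        d / 2, acoustic_water(), acoustic_mcf7())
    yd <- radiation_force_factor(s_drop)
    yc <- radiation_force_factor(s_cell)
    data.frame(diameter_um = d, Y_T_droplet = yd, Y_T_cell = yc,
               force_droplet_N = arf_force(yd, d / 2,
                                           setup$energy_density))
  })
  do.call(rbind, rows)
}

#' Can a pulse deflect a droplet to the target outlet?
#'
#' Simplified Stokes-drag mechanics: the radiation force accelerates the
#' droplet to its terminal lateral velocity essentially instantly, so the
#' lateral displacement over a pulse of duration t is \eqn{y = F t /
#' (6\pi\mu R)}. The droplet is deflected if y exceeds the required
#' lateral shift into the target outlet.
#'
#' @param force_N Applied radiation force (N).
#' @param droplet_diameter_um Droplet diameter (um).
#' @param pulse_ms Pulse duration (default 5 ms).
#' @param required_shift_um Lateral shift needed to cross the outlet
#'   bifurcation (default 30 um, one channel width).
#' @param viscosity_pa_s Carrier oil dynamic viscosity (default 1.24e-3).
#' @return `TRUE` if the displacement reaches the required shift.
#' @export
deflection_feasible <- function(force_N, droplet_diameter_um = 40,
                                pulse_ms = 5, required_shift_um = 30,
                                viscosity_pa_s = 1.24e-3) {
  stopifnot(pulse_ms > 0, droplet_diameter_um > 0)
  R <- droplet_diameter_um / 2 * 1e-6
  y <- force_N * (pulse_ms * 1e-3) / (6 * pi * viscosity_pa_s * R)
  y * 1e6 >= required_shift_um
}
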