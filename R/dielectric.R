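#' @keywords internal
EPS0 <- 8.8541878128e-12 # vacuum permittivity, F/m

#' Dielectric medium
#'
#' A homogeneous medium described by its DC conductivity and relative
#' permittivity. Convenience constructors are provided for the media used
#' throughout: near-insulating fluorinated carrier oil (HFE-7500 class,
#' \eqn{\varepsilon_r = 5.8}), a low-conductivity isotonic buffer
#' (\eqn{\sigma = 8\times 10^{-5}} S/m) and PBS (\eqn{\sigma = 1.6} S/m).
#'
#' @param sigma Conductivity in S/m (>= 0).
#' @param eps_r Relative permittivity (>= 1).
#' @return A `dielectric_medium` object.
#' @export
dielectric_medium <- function(sigma, eps_r) {
  stopifnot(sigma >= 0, eps_r >= 1)
  structure(list(sigma = sigma, eps_r = eps_r), class = "dielectric_medium")
}

#' @rdname dielectric_medium
#' @export
medium_oil <- function() dielectric_medium(1e-12, 5.8)

#' @rdname dielectric_medium
#' @export
medium_low_conductivity <- function() dielectric_medium(8e-5, 80)

#' @rdname dielectric_medium
#' @export
medium_pbs <- function() dielectric_medium(1.6, 80)

#' Complex conductivity and complex relative permittivity
#'
#' `complex_sigma()` returns \eqn{\sigma^* = \sigma + j\omega\varepsilon_0
#' \varepsilon_r}; `complex_eps_r()` returns \eqn{\varepsilon^* =
#' \varepsilon_r - j\sigma/(\omega\varepsilon_0)}. The two are related by
#' \eqn{\sigma^* = j\omega\varepsilon_0\varepsilon^*}.
#'
#' @param medium A `dielectric_medium` (or anything with `$sigma`,
#'   `$eps_r`).
#' @param f Frequency in Hz (> 0).
#' @return A complex scalar.
#' @export
complex_sigma <- function(medium, f) {
  stopifnot(f > 0)
  complex(real = medium$sigma, imaginary = 2 * pi * f * EPS0 * medium$eps_r)
}

#' @rdname complex_sigma
#' @export
complex_eps_r <- function(medium, f) {
  stopifnot(f > 0)
  w <- 2 * pi * f
  complex(real = medium$eps_r, imaginary = -medium$sigma / (w * EPS0))
}

#' Single-shell cell description
#'
#' A biological cell modelled as a conductive cytoplasm sphere coated by a
#' thin, poorly conducting membrane. Defaults are literature values for an
#' MCF-7-like cell: radius 9 um, membrane 7 nm with specific capacitance
#' close to 1 uF/cm^2, cytoplasm 0.5 S/m. A permeabilized (non-viable)
#' membrane lets the cytoplasm equilibrate with the suspending buffer, which
#' is modelled by replacing the cytoplasm conductivity with the medium's.
#'
#' @param radius_um Cell radius (um).
#' @param membrane_thickness_nm Membrane thickness (nm); must be small
#'   relative to the radius.
#' @param sigma_mem,eps_mem_r Membrane conductivity (S/m) and relative
#'   permittivity. The default `eps_mem_r` reproduces ~1 uF/cm^2 at 7 nm.
#' @param sigma_cyto,eps_cyto_r Cytoplasm conductivity (S/m) and relative
#'   permittivity.
#' @param viable Logical; `FALSE` marks a permeabilized cell.
#' @return A `shell_cell` object.
#' @export
shell_cell <- function(radius_um = 9, membrane_thickness_nm = 7,
                       sigma_mem = 1e-6, eps_mem_r = 7.9,
                       sigma_cyto = 0.5, eps_cyto_r = 60,
                       viable = TRUE) {
  stopifnot(radius_um > 0, membrane_thickness_nm > 0,
            membrane_thickness_nm * 1e-3 < 0.1 * radius_um,
            sigma_mem >= 0, sigma_cyto >= 0)
  structure(list(radius_um = radius_um,
                 membrane_thickness_nm = membrane_thickness_nm,
                 sigma_mem = sigma_mem, eps_mem_r = eps_mem_r,
                 sigma_cyto = sigma_cyto, eps_cyto_r = eps_cyto_r,
                 viable = viable),
            class = "shell_cell")
}

#' Complex permittivity of a single-shell cell
#'
#' Collapses the membrane-covered sphere into an equivalent homogeneous
#' sphere using the Maxwell-Wagner single-shell formula
#' \deqn{\varepsilon^*_{cell} = \varepsilon^*_{mem}
#'   \frac{\gamma^3 + 2K}{\gamma^3 - K}, \quad
#'   \gamma = \frac{r}{r - d}, \quad
#'   K = \frac{\varepsilon^*_{cyto} - \varepsilon^*_{mem}}
#'            {\varepsilon^*_{cyto} + 2\varepsilon^*_{mem}}.}
#' At frequencies of tens of MHz the membrane is electrically shorted and
#' the result approaches the cytoplasm value.
#'
#' @param cell A [shell_cell()].
#' @param f Frequency in Hz.
#' @param medium The suspending `dielectric_medium`; used only for
#'   permeabilized cells, whose cytoplasm conductivity is replaced by the
#'   medium's.
#' @return Complex relative permittivity of the equivalent homogeneous
#'   sphere.
#' @export
cell_complex_permittivity <- function(cell, f, medium = NULL) {
  stopifnot(inherits(cell, "shell_cell"), f > 0)
  sig_cyto <- cell$sigma_cyto
  if (!cell$viable) {
    if (is.null(medium))
      stop("permeabilized cell requires the suspending medium")
    sig_cyto <- medium$sigma
  }
  e_cyto <- complex_eps_r(list(sigma = sig_cyto, eps_r = cell$eps_cyto_r), f)
  e_mem <- complex_eps_r(list(sigma = cell$sigma_mem,
                              eps_r = cell$eps_mem_r), f)
  r <- cell$radius_um
  d <- cell$membrane_thickness_nm * 1e-3
  gam3 <- (r / (r - d))^3
  K <- (e_cyto - e_mem) / (e_cyto + 2 * e_mem)
  denom <- gam3 - K
  if (abs(denom) < 1e-12 * abs(gam3))
    stop("degenerate shell composition: gamma^3 == K")
  e_mem * (gam3 + 2 * K) / denom
}

#' Maxwell-Garnett effective permittivity
#'
#' Dilute mixing of spherical inclusions into a host:
#' \deqn{\varepsilon^*_{eff} = \varepsilon^*_h
#'   \frac{1 + 2\phi\beta}{1 - \phi\beta}, \quad
#'   \beta = \frac{\varepsilon^*_i - \varepsilon^*_h}
#'                {\varepsilon^*_i + 2\varepsilon^*_h}.}
#'
#' @param eps_host,eps_incl Complex relative permittivities.
#' @param phi Inclusion volume fraction in `[0, 1)`.
#' @return Complex effective relative permittivity.
#' @export
maxwell_garnett <- function(eps_host, eps_incl, phi) {
  stopifnot(phi >= 0, phi < 1)
  beta <- (eps_incl - eps_host) / (eps_incl + 2 * eps_host)
  eps_host * (1 + 2 * phi * beta) / (1 - phi * beta)
}

#' Effective complex conductivity of a cell-laden droplet
#'
#' Fast effective-medium surrogate for the field solver: each cell is
#' collapsed by [cell_complex_permittivity()] and mixed into the droplet
#' medium with [maxwell_garnett()] at the cells' total volume fraction.
#'
#' @param scene A [droplet_scene()].
#' @param f Frequency in Hz.
#' @return Complex conductivity \eqn{\sigma^*_{eff}} (S/m) of the droplet
#'   contents. Reduces exactly to the medium value with no cells. A warning
#'   is raised when the total cell volume fraction reaches 0.5, where the
#'   dilute assumption is no longer tenable.
#' @export
droplet_effective_sigma <- function(scene, f) {
  stopifnot(inherits(scene, "droplet_scene"))
  e_med <- complex_eps_r(scene$medium, f)
  cells <- scene$cells
  if (length(cells) == 0)
    return(2i * pi * f * EPS0 * e_med)
  v_drop <- (pi / 6) * scene$droplet_diameter_um^3
  v_cells <- sum(vapply(cells, function(c) (4 / 3) * pi * c$radius_um^3, 0))
  phi <- v_cells / v_drop
  if (phi >= 0.5)
    warning("cell volume fraction >= 0.5: dilute mixing assumption violated")
  # cells share one equivalent permittivity when identical; average otherwise
  e_cells <- vapply(cells, function(c) {
    cell_complex_permittivity(c, f, scene$medium)
  }, complex(1))
  w <- vapply(cells, function(c) c$radius_um^3, 0)
  e_incl <- sum(e_cells * w) / sum(w)
  e_eff <- maxwell_garnett(e_med, e_incl, phi)
  2i * pi * f * EPS0 * e_eff
}
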