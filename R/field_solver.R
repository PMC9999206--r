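#' Coplanar electrode geometry
#'
#' The sensing region is a 2D axial-height cross-section of the channel:
#' a rectangle with two coplanar electrodes on the bottom wall, centered
#' symmetrically. The excited electrode is held at `excitation_v`, the
#' other grounded; all remaining boundaries carry zero normal current.
#'
#' @param domain_length_um,domain_height_um Fluid domain size (default
#'   180 x 20 um).
#' @param electrode_width_um Width of each electrode (default 20 um).
#' @param electrode_gap_um Gap between the electrodes (default 20 um).
#' @param electrode_thickness_nm Metal thickness (default 100 nm); thin
#'   relative to the channel, so electrodes are treated as boundary lines.
#' @param excitation_v Excitation amplitude (default 5 V).
#' @param depth_um Out-of-plane channel width used to scale the per-unit-
#'   depth 2D current to amperes (default 30 um).
#' @return An `electrode_geometry` object.
#' @export
electrode_geometry <- function(domain_length_um = 180, domain_height_um = 20,
                               electrode_width_um = 20, electrode_gap_um = 20,
                               electrode_thickness_nm = 100,
                               excitation_v = 5, depth_um = 30) {
  span <- 2 * electrode_width_um + electrode_gap_um
  stopifnot(domain_length_um > 0, domain_height_um > 0,
            electrode_width_um > 0, electrode_gap_um >= 0,
            span < domain_length_um, excitation_v != 0, depth_um > 0)
  x0 <- (domain_length_um - span) / 2
  structure(list(domain_length_um = domain_length_um,
                 domain_height_um = domain_height_um,
                 electrode_width_um = electrode_width_um,
                 electrode_gap_um = electrode_gap_um,
                 electrode_thickness_nm = electrode_thickness_nm,
                 excitation_v = excitation_v,
                 depth_um = depth_um,
                 left_um = c(x0, x0 + electrode_width_um),
                 right_um = c(x0 + electrode_width_um + electrode_gap_um,
                              x0 + span)),
            class = "electrode_geometry")
}

#' Droplet scene
#'
#' Describes what sits in the sensing region: carrier oil, optionally a
#' droplet of aqueous medium, and cells inside the droplet. A droplet wider
#' than the channel height is squeezed to a pancake and modelled as a
#' full-height region of axial extent equal to its diameter; a smaller
#' droplet is a disk at mid-height. Cells are disks at mid-height whose
#' axial centers are set by fractional positions along the droplet.
#'
#' @param droplet_diameter_um Droplet diameter; `0` means no droplet
#'   (carrier oil only).
#' @param droplet_center_um Axial position of the droplet center; default
#'   centers it over the electrode pair.
#' @param medium Aqueous medium inside the droplet
#'   ([medium_low_conductivity()] by default).
#' @param carrier Continuous phase ([medium_oil()] by default).
#' @param cells List of [shell_cell()] objects.
#' @param cell_fracs Fractional axial positions of the cells in `[0, 1]`
#'   along the droplet (0.5 = droplet center). Length must match `cells`.
#' @param cell_layout `"aggregate"` (default): co-encapsulated cells form
#'   a clump whose members touch or overlap — rasterized as a row of
#'   disks spanning at most one cell diameter, centered at the mean cell
#'   position and resting `wall_clearance_um` above the bottom wall.
#'   Cells beyond the second overlap the pair in projection (in 3D they
#'   sit out of the sensing plane), so the two- and three-cell amplitudes
#'   come out nearly alike while one-to-two is a large step.
#'   `"dispersed"`: each cell is an independent disk at mid-height at its
#'   own fractional position.
#' @param wall_clearance_um Clearance between aggregate and bottom wall
#'   (default 1 um).
#' @param homogenize If `TRUE`, the droplet interior is painted with the
#'   Maxwell-Garnett effective conductivity of the cell suspension
#'   ([droplet_effective_sigma()]) instead of explicit cell disks. The
#'   mixing rule carries the true 3D cell volume fraction, which a 2D
#'   cross-section with explicit disks overstates; use this mode for
#'   amplitude-level contrast claims and the explicit mode for
#'   geometry-dependent ones.
#' @return A `droplet_scene` object.
#' @export
droplet_scene <- function(droplet_diameter_um = 40, droplet_center_um = NULL,
                          medium = medium_low_conductivity(),
                          carrier = medium_oil(),
                          cells = list(), cell_fracs = NULL,
                          cell_layout = c("aggregate", "dispersed"),
                          wall_clearance_um = 1, homogenize = FALSE) {
  cell_layout <- match.arg(cell_layout)
  if (is.null(cell_fracs)) cell_fracs <- default_cell_fracs(length(cells))
  stopifnot(droplet_diameter_um >= 0, length(cells) == length(cell_fracs),
            wall_clearance_um >= 0)
  if (length(cells) > 0 && droplet_diameter_um == 0)
    stop("cells require a droplet")
  structure(list(droplet_diameter_um = droplet_diameter_um,
                 droplet_center_um = droplet_center_um,
                 medium = medium, carrier = carrier,
                 cells = cells, cell_fracs = cell_fracs,
                 cell_layout = cell_layout,
                 wall_clearance_um = wall_clearance_um,
                 homogenize = homogenize),
            class = "droplet_scene")
}

# canonical cell placements: spread symmetrically about the droplet center,
# mimicking an aggregate sitting over the electrode gap
default_cell_fracs <- function(k) {
  if (k == 0) return(numeric(0))
  0.5 + 0.2 * (seq_len(k) - (k + 1) / 2)
}

#' Scene for k encapsulated cells
#'
#' Convenience builder used by the spectra and amplitude functions.
#'
#' @param k Number of cells (0-3 typical).
#' @param medium,droplet_diameter_um,cell,homogenize Passed through to
#'   [droplet_scene()] / [shell_cell()].
#' @return A `droplet_scene`.
#' @export
scene_k_cells <- function(k, medium = medium_low_conductivity(),
                          droplet_diameter_um = 40, cell = shell_cell(),
                          homogenize = FALSE) {
  droplet_scene(droplet_diameter_um = droplet_diameter_um, medium = medium,
                cells = rep(list(cell), k), homogenize = homogenize)
}

# rasterize the scene onto node coordinates -> complex sigma* per node
rasterize_sigma <- function(geometry, scene, f, xs, ys) {
  nx <- length(xs); ny <- length(ys)
  sig <- matrix(complex_sigma(scene$carrier, f), nx, ny)
  d <- scene$droplet_diameter_um
  if (d > 0) {
    xc <- scene$droplet_center_um
    if (is.null(xc)) xc <- geometry$domain_length_um / 2
    h <- geometry$domain_height_um
    s_med <- if (isTRUE(scene$homogenize)) {
      droplet_effective_sigma(scene, f)
    } else {
      complex_sigma(scene$medium, f)
    }
    if (d >= h) { # pancake: full height, axial extent = diameter
      inside <- abs(xs - xc) <= d / 2
      sig[inside, ] <- s_med
    } else {
      for (j in seq_len(ny)) {
        inside <- (xs - xc)^2 + (ys[j] - h / 2)^2 <= (d / 2)^2
        sig[inside, j] <- s_med
      }
    }
    if (length(scene$cells) > 0 && !isTRUE(scene$homogenize)) {
      x0 <- xc - d / 2
      paint_disk <- function(cx, cy, r, s_cell) {
        r2 <- r^2
        for (j in seq_len(ny)) {
          dy2 <- (ys[j] - cy)^2
          if (dy2 > r2) next
          inside <- (xs - cx)^2 + dy2 <= r2
          sig[inside, j] <<- s_cell
        }
      }
      if (scene$cell_layout == "aggregate") {
        # clump: row of touching/overlapping disks about the mean position
        k <- length(scene$cells)
        r <- scene$cells[[1]]$radius_um
        cx <- x0 + mean(scene$cell_fracs) * d
        cy <- min(scene$wall_clearance_um + r, h / 2)
        offs <- if (k == 1) 0 else seq(-(r - 1), r - 1, length.out = k)
        s_cell <- 2i * pi * f * EPS0 *
          cell_complex_permittivity(scene$cells[[1]], f, scene$medium)
        for (o in offs) paint_disk(cx + o, cy, r, s_cell)
      } else {
        for (ic in seq_along(scene$cells)) {
          cell <- scene$cells[[ic]]
          s_cell <- 2i * pi * f * EPS0 *
            cell_complex_permittivity(cell, f, scene$medium)
          paint_disk(x0 + scene$cell_fracs[ic] * d, h / 2,
                     cell$radius_um, s_cell)
        }
      }
    }
  }
  sig
}

#' Solve the quasi-static field in the sensing region
#'
#' Solves \eqn{\nabla\cdot(\sigma^*(x,y)\nabla\phi) = 0} with
#' \eqn{\sigma^* = \sigma + j\omega\varepsilon_0\varepsilon_r} assigned per
#' region, Dirichlet potentials on the two electrodes and zero normal
#' current elsewhere, using a conservative finite-volume 5-point scheme on
#' a regular grid (complex system solved as its equivalent real block
#' form). The discrete scheme conserves current exactly, so the electrode
#' currents balance to solver precision.
#'
#' @param geometry An [electrode_geometry()].
#' @param scene A [droplet_scene()].
#' @param f Frequency in Hz.
#' @param grid_step_um Grid spacing; must divide the domain and electrode
#'   coordinates (default 0.5 um).
#' @param swap_electrodes If `TRUE` the right electrode is excited and the
#'   left grounded (reciprocity checks).
#' @param potentials Optional length-2 numeric `c(V_left, V_right)`
#'   overriding the excitation (e.g. equal potentials for null checks).
#' @return List with complex electrode currents `I_left`, `I_right` in
#'   amperes (scaled by `geometry$depth_um`), per-unit-depth values
#'   `I_left_per_m`, `I_right_per_m`, the relative conservation error
#'   `conservation`, and the node potential matrix `phi` (nx x ny).
#' @export
solve_field <- function(geometry, scene, f, grid_step_um = 0.5,
                        swap_electrodes = FALSE, potentials = NULL) {
  h <- grid_step_um
  L <- geometry$domain_length_um; H <- geometry$domain_height_um
  if (abs(L / h - round(L / h)) > 1e-9 || abs(H / h - round(H / h)) > 1e-9)
    stop("grid_step_um must divide the domain dimensions")
  nx <- round(L / h) + 1L; ny <- round(H / h) + 1L
  xs <- seq(0, L, length.out = nx); ys <- seq(0, H, length.out = ny)
  sig <- rasterize_sigma(geometry, scene, f, xs, ys)
  if (max(Mod(sig)) == 0) stop("all-insulating domain: singular system")

  idx <- matrix(seq_len(nx * ny), nx, ny)
  on_left <- xs >= geometry$left_um[1] - 1e-9 &
    xs <= geometry$left_um[2] + 1e-9
  on_right <- xs >= geometry$right_um[1] - 1e-9 &
    xs <= geometry$right_um[2] + 1e-9
  dir_left <- idx[on_left, 1]
  dir_right <- idx[on_right, 1]
  v_left <- if (swap_electrodes) 0 else geometry$excitation_v
  v_right <- if (swap_electrodes) geometry$excitation_v else 0
  if (!is.null(potentials)) {
    stopifnot(length(potentials) == 2)
    v_left <- potentials[1]; v_right <- potentials[2]
  }

  # conductances of horizontal faces (between x-neighbours) and vertical
  # faces; transverse face widths halve on the domain boundary rows/cols
  wy <- rep(1, ny); wy[c(1, ny)] <- 0.5
  wx <- rep(1, nx); wx[c(1, nx)] <- 0.5
  sig_hx <- (sig[-nx, ] + sig[-1, ]) / 2           # (nx-1) x ny
  Ghx <- sweep(sig_hx, 2, wy, `*`)                 # sigma* * (dy_face/h)
  sig_vy <- (sig[, -ny] + sig[, -1]) / 2           # nx x (ny-1)
  Gvy <- sweep(sig_vy, 1, wx, `*`)

  # assemble edge list
  i_h <- as.vector(idx[-nx, ]); j_h <- as.vector(idx[-1, ])
  g_h <- as.vector(Ghx)
  i_v <- as.vector(idx[, -ny]); j_v <- as.vector(idx[, -1])
  g_v <- as.vector(Gvy)
  ei <- c(i_h, i_v); ej <- c(j_h, j_v); g <- c(g_h, g_v)

  n <- nx * ny
  dirichlet <- c(dir_left, dir_right)
  phi_d <- rep(0, n); phi_d[dir_left] <- v_left; phi_d[dir_right] <- v_right
  is_dir <- rep(FALSE, n); is_dir[dirichlet] <- TRUE

  # Laplacian (complex, symmetric): A = D - W over free nodes
  free <- which(!is_dir)
  map <- integer(n); map[free] <- seq_along(free)

  keep_ff <- !is_dir[ei] & !is_dir[ej]
  keep_fd <- xor(is_dir[ei], is_dir[ej])
  # degree contributions at free nodes from all incident edges
  deg_i <- c(ei[!is_dir[ei]], ej[!is_dir[ej]])
  deg_g <- c(g[!is_dir[ei]], g[!is_dir[ej]])
  # rhs from dirichlet neighbours
  fd_free <- ifelse(is_dir[ei], ej, ei)[keep_fd]
  fd_dir <- ifelse(is_dir[ei], ei, ej)[keep_fd]
  fd_g <- g[keep_fd]

  nf <- length(free)
  b <- complex(nf)
  bt <- tapply(fd_g * phi_d[fd_dir], map[fd_free], sum)
  b[as.integer(names(bt))] <- as.complex(bt)

  dt <- tapply(deg_g, map[deg_i], sum)
  dvec <- complex(nf)
  dvec[as.integer(names(dt))] <- as.complex(dt)

  ii <- map[ei[keep_ff]]; jj <- map[ej[keep_ff]]; gg <- g[keep_ff]
  # real block system [[Re, -Im], [Im, Re]] [xr; xi] = [br; bi]
  tri_i <- c(ii, jj, seq_len(nf))
  tri_j <- c(jj, ii, seq_len(nf))
  tri_x <- c(-gg, -gg, dvec[seq_len(nf)])
  Ar <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = Re(tri_x),
                             dims = c(nf, nf))
  Ai <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = Im(tri_x),
                             dims = c(nf, nf))
  Ablk <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  rhs <- c(Re(b), Im(b))
  sol <- tryCatch(Matrix::solve(Ablk, rhs),
                  error = function(e) stop("field solve failed: ",
                                           conditionMessage(e)))
  sol <- as.numeric(sol)
  phi <- phi_d
  phi[free] <- complex(real = sol[seq_len(nf)],
                       imaginary = sol[nf + seq_len(nf)])

  # electrode current: net conductive+displacement current entering the
  # domain through each electrode's incident faces (per unit depth, * 1/h
  # cancels the um face width so units are S/m * V = A/m)
  elec_current <- function(nodes) {
    sel_i <- ei %in% nodes & !(ej %in% nodes)
    sel_j <- ej %in% nodes & !(ei %in% nodes)
    sum(g[sel_i] * (phi[ei[sel_i]] - phi[ej[sel_i]])) +
      sum(g[sel_j] * (phi[ej[sel_j]] - phi[ei[sel_j]]))
  }
  I_left <- elec_current(dir_left)
  I_right <- elec_current(dir_right)
  mmax <- max(Mod(I_left), Mod(I_right))
  cons <- if (mmax == 0) 0 else Mod(I_left + I_right) / mmax
  depth_m <- geometry$depth_um * 1e-6
  list(I_left = I_left * depth_m, I_right = I_right * depth_m,
       I_left_per_m = I_left, I_right_per_m = I_right,
       conservation = cons,
       phi = matrix(phi, nx, ny), xs = xs, ys = ys, sigma = sig)
}

#' Electrode current magnitude for a scene
#'
#' @inheritParams solve_field
#' @return Complex current through the excited electrode (amperes).
#' @export
electrode_current <- function(geometry, scene, f, grid_step_um = 0.5) {
  solve_field(geometry, scene, f, grid_step_um)$I_left
}

#' Probe-frequency spectrum of droplet contrast
#'
#' Solves the field for an empty droplet and a k-cell droplet over a list
#' of frequencies and reports the contrast
#' \eqn{|I_{cells}|/|I_{empty}|} along with the differential magnitude
#' \eqn{|I_{cells} - I_{empty}|}.
#'
#' @param geometry An [electrode_geometry()].
#' @param scene_empty,scene_cells The two scenes to compare (same
#'   geometry).
#' @param f_list Frequencies in Hz.
#' @param grid_step_um Grid spacing.
#' @return A data.frame with columns `frequency_hz`, `abs_I_empty`,
#'   `abs_I_cells`, `contrast`, `abs_dI`.
#' @export
frequency_spectrum <- function(geometry, scene_empty, scene_cells, f_list,
                               grid_step_um = 0.5) {
  rows <- lapply(f_list, function(f) {
    Ie <- electrode_current(geometry, scene_empty, f, grid_step_um)
    Ic <- electrode_current(geometry, scene_cells, f, grid_step_um)
    data.frame(frequency_hz = f, abs_I_empty = Mod(Ie),
               abs_I_cells = Mod(Ic), contrast = Mod(Ic) / Mod(Ie),
               abs_dI = Mod(Ic - Ie))
  })
  do.call(rbind, rows)
}

#' Medium-conductivity spectrum of droplet contrast
#'
#' As [frequency_spectrum()] but sweeping the droplet medium conductivity
#' at a fixed probe frequency.
#'
#' @param geometry An [electrode_geometry()].
#' @param sigma_list Medium conductivities (S/m) to sweep.
#' @param f Probe frequency in Hz.
#' @param k Number of encapsulated cells in the cell scene.
#' @param eps_r Medium relative permittivity (default 80).
#' @param cell Cell model.
#' @param grid_step_um Grid spacing.
#' @return A data.frame with columns `sigma_medium`, `abs_I_empty`,
#'   `abs_I_cells`, `contrast`, `abs_dI`.
#' @export
conductivity_spectrum <- function(geometry, sigma_list, f, k = 1,
                                  eps_r = 80, cell = shell_cell(),
                                  grid_step_um = 0.5) {
  rows <- lapply(sigma_list, function(s) {
    med <- dielectric_medium(s, eps_r)
    Ie <- electrode_current(geometry, scene_k_cells(0, medium = med), f,
                            grid_step_um)
    Ic <- electrode_current(geometry, scene_k_cells(k, medium = med,
                                                    cell = cell), f,
                            grid_step_um)
    data.frame(sigma_medium = s, abs_I_empty = Mod(Ie),
               abs_I_cells = Mod(Ic), contrast = Mod(Ic) / Mod(Ie),
               abs_dI = Mod(Ic - Ie))
  })
  do.call(rbind, rows)
}

#' Differential amplitude versus encapsulated cell count
#'
#' Computes \eqn{|\Delta I(k)| = |I_k - I_{empty}|} for `k` in `k_list` at
#' the probe frequency. The physically expected ordering (more cells, more
#' conductive detection volume, larger amplitude, saturating beyond two
#' cells) is what downstream amplitude tables rely on.
#'
#' @param geometry An [electrode_geometry()].
#' @param k_list Cell counts (default 0:3).
#' @param f Probe frequency (default 40 MHz).
#' @param medium Droplet medium.
#' @param cell Cell model.
#' @param grid_step_um Grid spacing.
#' @return A data.frame with columns `k`, `abs_I`, `abs_dI`.
#' @export
multi_cell_amplitude <- function(geometry, k_list = 0:3, f = 40e6,
                                 medium = medium_low_conductivity(),
                                 cell = shell_cell(), grid_step_um = 0.5) {
  I0 <- electrode_current(geometry, scene_k_cells(0, medium = medium), f,
                          grid_step_um)
  rows <- lapply(k_list, function(k) {
    Ik <- if (k == 0) I0 else {
      electrode_current(geometry, scene_k_cells(k, medium = medium,
                                                cell = cell), f,
                        grid_step_um)
    }
    data.frame(k = k, abs_I = Mod(Ik), abs_dI = Mod(Ik - I0))
  })
  do.call(rbind, rows)
}
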