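test_that("single-shell model collapses to homogeneous limits", {
  # membrane identical to cytoplasm -> homogeneous sphere
  cell <- shell_cell(sigma_mem = 0.5, eps_mem_r = 60,
                     sigma_cyto = 0.5, eps_cyto_r = 60)
  e <- cell_complex_permittivity(cell, 1e6)
  e_cyto <- complex_eps_r(list(sigma = 0.5, eps_r = 60), 1e6)
  expect_equal(e, e_cyto, tolerance = 1e-9)
  # high frequency shorts the membrane: cytoplasm-dominated value
  cell2 <- shell_cell()
  e_hi <- cell_complex_permittivity(cell2, 1e12)
  e_cyto2 <- complex_eps_r(list(sigma = 0.5, eps_r = 60), 1e12)
  expect_lt(Mod(e_hi - e_cyto2) / Mod(e_cyto2), 0.01)
  # at 40 MHz the apparent conductivity is already cytoplasm-like
  e_40 <- cell_complex_permittivity(cell2, 40e6)
  sig_app <- -Im(e_40) * 2 * pi * 40e6 * 8.8541878128e-12
  expect_gt(sig_app, 0.4)
  # permeabilized cell requires the medium and adopts its conductivity
  dead <- shell_cell(viable = FALSE)
  expect_error(cell_complex_permittivity(dead, 40e6), "medium")
  e_dead <- cell_complex_permittivity(dead, 40e6, medium_low_conductivity())
  sig_dead <- -Im(e_dead) * 2 * pi * 40e6 * 8.8541878128e-12
  expect_lt(sig_dead, 0.01)
})

test_that("Maxwell-Garnett mixing is exact at zero fraction and dilute-linear", {
  e_h <- complex(real = 80, imaginary = -2)
  e_i <- complex(real = 60, imaginary = -40)
  expect_equal(maxwell_garnett(e_h, e_i, 0), e_h)
  d1 <- maxwell_garnett(e_h, e_i, 0.04) - e_h
  d2 <- maxwell_garnett(e_h, e_i, 0.08) - e_h
  expect_lt(Mod(d2 - 2 * d1) / Mod(d2), 0.05)
})

test_that("effective droplet conductivity responds to cells as expected", {
  sc0 <- scene_k_cells(0)
  f <- 40e6
  expect_equal(droplet_effective_sigma(sc0, f),
               complex_sigma(medium_low_conductivity(), f))
  sc1 <- scene_k_cells(1)
  expect_gt(Mod(droplet_effective_sigma(sc1, f)),
            Mod(complex_sigma(medium_low_conductivity(), f)))
  # two identical cells: dilute inclusion term doubles (within MG curvature)
  sc2 <- scene_k_cells(2)
  t1 <- droplet_effective_sigma(sc1, f) - complex_sigma(sc1$medium, f)
  t2 <- droplet_effective_sigma(sc2, f) - complex_sigma(sc2$medium, f)
  expect_lt(Mod(t2 - 2 * t1) / Mod(t2), 0.25)
  # dilute assumption violated -> warning
  tiny <- droplet_scene(22, cells = list(shell_cell()), cell_fracs = 0.5)
  expect_warning(droplet_effective_sigma(tiny, f), "dilute")
})

test_that("field solver conserves current and honours trivial cases", {
  geo <- electrode_geometry()
  for (sc in list(scene_k_cells(0), scene_k_cells(2),
                  droplet_scene(0))) {
    res <- solve_field(geo, sc, 40e6, grid_step_um = 1)
    expect_lt(res$conservation, 1e-6)
  }
  # equal electrode potentials in a uniform medium -> no current
  un <- droplet_scene(0, carrier = dielectric_medium(1.6, 80))
  null <- solve_field(geo, un, 1e6, grid_step_um = 1, potentials = c(5, 5))
  expect_lt(Mod(null$I_left), 1e-12)
  # reciprocity: swapping excitation mirrors the currents
  a <- solve_field(geo, scene_k_cells(1), 40e6, grid_step_um = 1)
  b <- solve_field(geo, scene_k_cells(1), 40e6, grid_step_um = 1,
                   swap_electrodes = TRUE)
  expect_lt(Mod(a$I_left + b$I_left) / Mod(a$I_left), 1e-9)
})

test_that("solver converges on grid refinement", {
  geo <- electrode_geometry()
  sc <- scene_k_cells(1)
  I_def <- Mod(solve_field(geo, sc, 40e6, grid_step_um = 0.5)$I_left)
  I_half <- Mod(solve_field(geo, sc, 40e6, grid_step_um = 0.25)$I_left)
  expect_lt(abs(I_half - I_def) / I_def, 0.02)
})

test_that("uniform-medium current matches fine grid and conformal mapping", {
  geo <- electrode_geometry()
  un <- droplet_scene(0, carrier = dielectric_medium(1.6, 80))
  f0 <- 1e4 # conduction-dominated
  I_def <- Mod(solve_field(geo, un, f0, grid_step_um = 0.5)$I_left)
  I_fine <- Mod(solve_field(geo, un, f0, grid_step_um = 0.25)$I_left)
  expect_lt(abs(I_def - I_fine) / I_fine, 0.01)
  # conformal-mapping closed form for coplanar strips on a half-plane:
  # G = (sigma/2) K(k')/K(k), k = gap/(gap + 2 width); approximate the
  # half-plane with a tall domain
  tall <- electrode_geometry(domain_length_um = 400, domain_height_um = 200)
  I_tall <- Mod(solve_field(tall, un, f0, grid_step_um = 2)$I_left_per_m)
  k <- 20 / (20 + 2 * 20)
  G <- 1.6 / 2 * ellipK(sqrt(1 - k^2)) / ellipK(k)
  expect_lt(abs(I_tall - G * 5) / (G * 5), 0.25)
})

test_that("cell contrast ordering holds in low-conductivity medium at 40 MHz", {
  geo <- electrode_geometry()
  f <- 40e6
  # explicit inclusions
  amp <- multi_cell_amplitude(geo, 0:3, f, grid_step_um = 1)
  expect_equal(amp$abs_dI[1], 0)
  expect_true(all(diff(amp$abs_dI) > 0))
  # saturation: the two-to-three step is the smaller one
  expect_lt(amp$abs_dI[4] - amp$abs_dI[3], amp$abs_dI[3] - amp$abs_dI[2])
  expect_gt(amp$abs_dI[3] / amp$abs_dI[2], 1)
  # homogenized route agrees on the ordering
  I0 <- electrode_current(geo, scene_k_cells(0), f, 1)
  Ih <- vapply(1:3, function(k) {
    Mod(electrode_current(geo, scene_k_cells(k, homogenize = TRUE), f, 1) - I0)
  }, 0)
  expect_true(all(diff(c(0, Ih)) > 0))
})

test_that("differential amplitude rises steeply with probe frequency at low sigma", {
  geo <- electrode_geometry()
  sp <- frequency_spectrum(geo, scene_k_cells(0), scene_k_cells(1),
                           c(1e5, 1e6, 1e7, 4e7), grid_step_um = 1)
  expect_true(all(diff(sp$abs_dI) > 0))
  expect_gt(sp$abs_dI[4] / sp$abs_dI[2], 10)
})

test_that("cells in PBS are nearly invisible above 1 MHz", {
  geo <- electrode_geometry()
  pbs <- medium_pbs()
  sp <- frequency_spectrum(geo, scene_k_cells(0, medium = pbs),
                           scene_k_cells(1, medium = pbs, homogenize = TRUE),
                           c(2e6, 1e7, 4e7), grid_step_um = 1)
  expect_true(all(abs(sp$contrast - 1) < 0.1))
})

test_that("contrast falls monotonically with medium conductivity at 40 MHz", {
  geo <- electrode_geometry()
  sg <- c(8e-5, 1e-3, 1e-2, 0.1, 0.5, 1.6)
  con <- vapply(sg, function(s) {
    med <- dielectric_medium(s, 80)
    Ie <- electrode_current(geo, scene_k_cells(0, medium = med), 40e6, 1)
    Ic <- electrode_current(geo, scene_k_cells(1, medium = med,
                                               homogenize = TRUE), 40e6, 1)
    Mod(Ic) / Mod(Ie)
  }, 0)
  expect_true(all(diff(con) < 0))
  # index matching: cytoplasm-like medium sees almost no cell
  expect_lt(abs(con[5] - 1), 0.02)
})

test_that("larger cytoplasm-medium contrast gives larger amplitude", {
  geo <- electrode_geometry()
  dI <- vapply(c(0.1, 0.25, 0.5, 1.0), function(s_cyto) {
    cell <- shell_cell(sigma_cyto = s_cyto)
    Ie <- electrode_current(geo, scene_k_cells(0), 40e6, 1)
    Ic <- electrode_current(geo, scene_k_cells(1, cell = cell,
                                               homogenize = TRUE), 40e6, 1)
    Mod(Ic - Ie)
  }, 0)
  expect_true(all(diff(dI) > 0))
})

test_that("permeabilized cells read like empty droplets", {
  geo <- electrode_geometry()
  f <- 40e6
  I0 <- electrode_current(geo, scene_k_cells(0), f, 1)
  Iv <- electrode_current(geo, scene_k_cells(1), f, 1)
  Ip <- electrode_current(geo, scene_k_cells(1, cell = shell_cell(
    viable = FALSE)), f, 1)
  expect_lt(Mod(Ip - I0), 0.25 * Mod(Iv - I0))
})

test_that("droplet amplitude is insensitive to size once electrodes are covered", {
  geo <- electrode_geometry()
  f <- 40e6
  Ioil <- electrode_current(geo, droplet_scene(0), f, 1)
  span <- 2 * 20 + 20 # both electrodes plus gap
  empt <- vapply(c(60, 70, 80), function(d) {
    Mod(electrode_current(geo, droplet_scene(d), f, 1) - Ioil)
  }, 0)
  expect_gte(min(c(60, 70, 80)), span)
  expect_lt(diff(range(empt)) / max(empt), 0.10)
  cellamp <- vapply(c(60, 70, 80), function(d) {
    sc <- droplet_scene(d, cells = list(shell_cell()))
    Mod(electrode_current(geo, sc, f, 1) -
        electrode_current(geo, droplet_scene(d), f, 1))
  }, 0)
  expect_lt(diff(range(cellamp)) / max(cellamp), 0.10)
})

test_that("solver rejects impossible grids and degenerate systems", {
  geo <- electrode_geometry()
  expect_error(solve_field(geo, scene_k_cells(0), 40e6, grid_step_um = 7),
               "divide")
})
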