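test_that("zero pressure gives the undeformed, stress-free state", {
  m <- build_mesh(ring_slice(), 0.3)
  sol <- solve_static(m, wall_only(), solve_config(0, "kPa"))
  expect_true(sol$converged)
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(max(abs(sol$element_fields[, c("s11", "s22", "s12", "szz")])), 0)
})

test_that("ring inflation matches the 1D radial-equilibrium oracle within 2%", {
  sol <- ring_solution_100mmHg()
  expect_true(sol$converged)
  oracle <- ring_ode_oracle(material_params("vessel"), mmHg_to_kPa(100))
  hoop <- fem_hoop_at(sol, 2.25)
  expect_equal(hoop, oracle$sigma_theta, tolerance = 0.02)
  expect_equal(sol$lumen_area, oracle$lumen_area, tolerance = 0.01)
})

test_that("small-load response matches the Lame thick-cylinder closed form", {
  m <- build_mesh(ring_slice(), 0.15)
  p <- 0.1
  sol <- solve_static(m, wall_only(), solve_config(p, "kPa", load_steps = 1))
  ri <- 1.5; ro <- 3; rq <- 2.25
  C1 <- p * ri^2 / (ro^2 - ri^2); C2 <- p * ri^2 * ro^2 / (ro^2 - ri^2)
  lame <- C1 + C2 / rq^2
  expect_equal(fem_hoop_at(sol, rq), lame, tolerance = 0.05)
})

test_that("rigid-body reactions vanish for the self-equilibrated pressure load", {
  sol <- ring_solution_100mmHg()
  expect_lt(sol$reaction_norm, 1e-8)
  expect_lt(sol$residual_norm, sol$config$newton_tol)
})

test_that("displacements are linear in pressure at small loads", {
  m <- build_mesh(ring_slice(), 0.25)
  s1 <- solve_static(m, wall_only(), solve_config(0.05, "kPa", load_steps = 1))
  s2 <- solve_static(m, wall_only(), solve_config(0.10, "kPa", load_steps = 1))
  r <- max(abs(s2$u)) / max(abs(s1$u))
  expect_equal(r, 2, tolerance = 0.05)
})

test_that("lumen area increases monotonically with pressure", {
  m <- build_mesh(ring_slice(), 0.3)
  areas <- vapply(c(20, 60, 100), function(p) {
    solve_static(m, wall_only(), solve_config(p, "mmHg"))$lumen_area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_gt(areas[1], pi * 1.5^2)
})

test_that("a soft lipid core raises peak lumen stress versus all-wall tissue", {
  sl <- generate_slice(slice_spec(cap_thickness = 0.1, seed = 6))
  cfg <- solve_config(110, "mmHg")
  with_lipid <- solve_static(build_mesh(sl, 0.2), plaque_materials(), cfg)
  all_wall <- solve_static(build_mesh(sl, 0.2),
                           list(wall = material_params("vessel"),
                                lipid = material_params("vessel")), cfg)
  pw <- max(sample_lumen(with_lipid)$PWS_kPa)
  pa <- max(sample_lumen(all_wall)$PWS_kPa)
  expect_gt(pw, pa)
})

test_that("thin-layer solve with unit axial stretch reproduces plane strain", {
  sl <- ring_slice()
  cfg2d <- solve_config(80, "mmHg")
  cfgtl <- solve_config(80, "mmHg", axial_stretch = 1, variant = "thin_layer")
  s2d <- solve_static(build_mesh(sl, 0.25), wall_only(), cfg2d)
  stl <- thin_layer_solve(sl, wall_only(), cfgtl, h = 0.25)
  expect_equal(stl$u, s2d$u, tolerance = 0.01)
  expect_equal(mean(sample_lumen(stl)$PWS_kPa),
               mean(sample_lumen(s2d)$PWS_kPa), tolerance = 0.01)
})

test_that("the 10% axial stretch produces axial stress and changes hoop stress", {
  sl <- ring_slice()
  m <- build_mesh(sl, 0.25)
  s2d <- solve_static(m, wall_only(), solve_config(80, "mmHg"))
  stl <- solve_static(m, wall_only(),
                      solve_config(80, "mmHg", axial_stretch = 1 / 0.9,
                                   variant = "thin_layer"))
  expect_gt(mean(stl$element_fields[, "szz"]), 1)  # tension, kPa
  h2d <- fem_hoop_at(s2d, 2.25); htl <- fem_hoop_at(stl, 2.25)
  expect_gt(abs(htl - h2d), 1e-3)
})

test_that("lumen sampling is uniform on the ring and equivariant to rotation", {
  sol <- ring_solution_100mmHg()
  prof <- sample_lumen(sol, 100)
  expect_equal(nrow(prof), 100)
  cv <- stats::sd(prof$PWS_kPa) / mean(prof$PWS_kPa)
  expect_lt(cv, 0.02)

  sl <- generate_slice(slice_spec(seed = 12))
  cfg <- solve_config(90, "mmHg")
  p0 <- sample_lumen(solve_static(build_mesh(sl, 0.2), plaque_materials(), cfg))
  p90 <- sample_lumen(solve_static(build_mesh(rotate_slice(sl, pi / 2), 0.2),
                                   plaque_materials(), cfg))
  # cyclic shift by n/4 (+/- 1 index); agreement to discretization level
  # (rotation re-orients the angular grid relative to the plaque)
  errs <- vapply(24:26, function(s) {
    mean(abs(p90$PWS_kPa[((seq_len(100) - 1 + s) %% 100) + 1] - p0$PWS_kPa))
  }, numeric(1))
  expect_lt(min(errs) / mean(p0$PWS_kPa), 0.10)
  # and the unshifted profiles must NOT match (the field really rotated)
  err0 <- mean(abs(p90$PWS_kPa - p0$PWS_kPa))
  expect_gt(err0, min(errs))
})

test_that("sampling a prescribed constant field returns its principal values", {
  m <- build_mesh(ring_slice(), 0.3)
  ef <- matrix(0, nrow(m$tri), 10,
               dimnames = list(NULL, c("s11", "s22", "s12", "szz",
                                       "E11", "E22", "E12", "Ezz", "J", "W")))
  ef[, "s11"] <- 2; ef[, "s22"] <- 1; ef[, "s12"] <- 0; ef[, "szz"] <- 0.5
  ef[, "E11"] <- 0.03; ef[, "E22"] <- 0.01
  sol <- structure(list(mesh = m, u = matrix(0, nrow(m$nodes), 2),
                        converged = TRUE, residual_norm = 0,
                        reaction_norm = 0, element_fields = ef,
                        lumen_area = pi * 1.5^2,
                        config = solve_config(0, "kPa"), materials = NULL),
                   class = "field_solution")
  prof <- sample_lumen(sol, 4)
  expect_equal(prof$PWS_kPa, rep(2, 4), tolerance = 1e-9)
  expect_equal(prof$PWSn, rep(0.03, 4), tolerance = 1e-9)
})

test_that("sampling refuses a non-converged solution", {
  sol <- ring_solution_100mmHg()
  bad <- sol; bad$converged <- FALSE
  expect_error(sample_lumen(bad), "non-converged")
})

test_that("mesh independence terminates on the ring and records its sequence", {
  mc <- fixture("ring_mesh_conv", {
    mesh_convergence(ring_slice(), wall_only(), solve_config(100, "mmHg"),
                     start_h = 0.25, max_refine = 6)
  })
  expect_lte(nrow(mc$table), 7)   # start + at most 6 refinements
  expect_true(all(diff(mc$table$n_elements) >= 0))
  expect_lt(mc$table$rel_change[nrow(mc$table)], 0.01)
  oracle <- ring_ode_oracle(material_params("vessel"), mmHg_to_kPa(100),
                            R_query = 1.5)
  # lumen-point PWS against the oracle's inner-wall hoop stress
  expect_equal(mean(mc$profile$PWS_kPa), oracle$sigma_theta, tolerance = 0.05)
})

test_that("an already-fine mesh stops after a single refinement check", {
  mc <- mesh_convergence(ring_slice(), wall_only(),
                         solve_config(60, "mmHg"), start_h = 0.15,
                         max_refine = 3)
  expect_equal(nrow(mc$table), 2)
})
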