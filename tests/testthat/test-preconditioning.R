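test_that("zero imaging pressure needs no shrink", {
  sl <- generate_slice(slice_spec(seed = 2))
  sr <- find_circ_shrink(sl, plaque_materials(), 0, h = 0.3)
  expect_equal(sr$circ_shrink_ratio, 1)
  expect_equal(sr$shrunk_slice$contours, sl$contours)
})

test_that("re-pressurizing the shrunk ring recovers the imaged lumen area", {
  sl <- ring_slice()
  sr <- fixture("ring_shrink", {
    find_circ_shrink(sl, wall_only(), 100, h = 0.2)
  })
  expect_lt(sr$circ_shrink_ratio, 1)
  expect_lt(abs(sr$achieved_area_error), 0.005)
  # end-to-end: fresh solve of the shrunk geometry at imaging pressure
  sol <- solve_static(sr$shrunk_mesh, wall_only(),
                      solve_config(100, "mmHg"))
  expect_equal(sol$lumen_area, sr$target_area, tolerance = 0.005)
  expect_equal(sr$target_area, pi * 1.5^2, tolerance = 0.01)
})

test_that("stiffer tissue needs less circumferential shrink", {
  sl <- ring_slice()
  sr1 <- fixture("ring_shrink", find_circ_shrink(sl, wall_only(), 100, h = 0.2))
  sr10 <- find_circ_shrink(sl, list(wall = scale_stiffness(material_params("vessel"), 10)),
                           100, h = 0.2)
  expect_gt(sr10$circ_shrink_ratio, sr1$circ_shrink_ratio)
  expect_lte(sr10$circ_shrink_ratio, 1)
})

test_that("shrunk wall cross-sectional area conserves tissue volume", {
  sl <- generate_slice(slice_spec(seed = 4, noise_amplitude = 0))
  A_wall <- abs(polygon_area(sl$contours$outer)) -
    abs(polygon_area(sl$contours$lumen))
  sr <- find_circ_shrink(sl, plaque_materials(), 80, h = 0.3,
                         axial_stretch = 1 / 0.9)
  A_wall_shrunk <- abs(polygon_area(sr$shrunk_slice$contours$outer)) -
    abs(polygon_area(sr$shrunk_slice$contours$lumen))
  expect_equal(A_wall_shrunk, A_wall / 0.9, tolerance = 0.01)
  expect_equal(sr$axial_shrink, 0.10)
})

test_that("axial shrink contracts length by 10% and dilates cross-sections", {
  sl <- generate_slice(slice_spec(seed = 2))
  slices <- lapply(1:2, function(i) {
    s <- sl; s$slice_id <- i; s$axial_position <- (i - 1) * 70.58; s
  })
  v <- vessel_spec(slices, pressure_range = c(70, 125), slice_spacing = 70.58)
  sh <- apply_axial_shrink(v)
  expect_equal(sh$vessel$slices[[2]]$axial_position, 63.522)
  expect_equal(sh$axial_stretch, 1 / 0.9)
  # per-slice wall area scales by 1/0.9 (volume conservation)
  A0 <- abs(polygon_area(v$slices[[1]]$contours$outer)) -
    abs(polygon_area(v$slices[[1]]$contours$lumen))
  A1 <- abs(polygon_area(sh$vessel$slices[[1]]$contours$outer)) -
    abs(polygon_area(sh$vessel$slices[[1]]$contours$lumen))
  expect_equal(A1 * 0.9, A0, tolerance = 1e-10)
  # shrink followed by the solver stretch recovers the in vivo length
  expect_equal(sh$vessel$slices[[2]]$axial_position * sh$axial_stretch, 70.58)
})

test_that("skipping the shrink step overestimates lumen wall stress", {
  sl <- generate_slice(slice_spec(seed = 3))
  mats <- plaque_materials()
  sr <- find_circ_shrink(sl, mats, 70, h = 0.25, tol = 0.001)
  cfg <- solve_config(125, "mmHg")
  pws_shrunk <- mean(sample_lumen(solve_static(sr$shrunk_mesh, mats, cfg))$PWS_kPa)
  pws_direct <- mean(sample_lumen(solve_static(build_mesh(sl, 0.25), mats, cfg))$PWS_kPa)
  expect_gt(pws_direct, pws_shrunk)
})
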