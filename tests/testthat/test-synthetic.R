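test_that("a slice without lipid has only lumen and outer contours", {
  sl <- generate_slice(slice_spec(lipid_arc = 0, seed = 2))
  expect_setequal(names(sl$contours), c("lumen", "outer"))
})

test_that("fibrous-cap thickness is honored by construction", {
  sl <- generate_slice(slice_spec(cap_thickness = 0.05, lipid_thickness = 0.3,
                                  seed = 4))
  d <- polygon_min_distance(sl$contours$lumen, sl$contours$lipid)
  expect_equal(d, 0.05, tolerance = 0.01)
})

test_that("identical specs and seeds generate bit-identical contours", {
  a <- generate_slice(slice_spec(seed = 77))
  b <- generate_slice(slice_spec(seed = 77))
  expect_identical(a$contours, b$contours)
  cc <- generate_slice(slice_spec(seed = 78))
  expect_false(identical(a$contours, cc$contours))
})

test_that("infeasible slice specifications raise explicit errors", {
  expect_error(slice_spec(lipid_thickness = 0.7, cap_thickness = 0.4,
                          wall_thickness = 1.0), "infeasible")
  expect_error(slice_spec(cap_thickness = 0), "cap_thickness")
  expect_error(slice_spec(calc_present = TRUE, calc_arc = 250,
                          lipid_arc = 120), "overlap")
})

test_that("generated contours stay simple, CCW and nested over a property sweep", {
  withr::with_seed(123, {
    n_bad <- 0
    for (i in 1:1000) {
      sp <- slice_spec(
        lumen_radius = stats::runif(1, 1.0, 2.0),
        lumen_eccentricity = stats::runif(1, 0, 0.6),
        wall_thickness = stats::runif(1, 0.8, 1.5),
        lipid_arc = sample(c(0, stats::runif(1, 40, 160)), 1),
        lipid_thickness = stats::runif(1, 0.2, 0.45),
        cap_thickness = stats::runif(1, 0.06, 0.3),
        calc_present = stats::runif(1) < 0.3,
        noise_amplitude = stats::runif(1, 0, 0.05),
        n_points = 64, seed = i)
      sl <- try(generate_slice(sp), silent = TRUE)
      if (inherits(sl, "try-error")) { n_bad <- n_bad + 1; next }
      for (nm in names(sl$contours)) {
        p <- sl$contours[[nm]]
        expect_gt(polygon_area(p), 0)          # CCW
        expect_true(polygon_is_simple(p))
      }
      # nesting: lumen strictly inside outer, inclusions inside the annulus
      expect_true(all(points_in_polygon(sl$contours$lumen, sl$contours$outer)))
      if (!is.null(sl$contours$lipid)) {
        expect_true(all(points_in_polygon(sl$contours$lipid, sl$contours$outer)))
        expect_false(any(points_in_polygon(sl$contours$lipid, sl$contours$lumen)))
      }
    }
    expect_lt(n_bad, 50)  # only genuinely infeasible draws may error
  })
})

test_that("stenosis follows its defining formula", {
  square <- function(s) rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  mk <- function(s, id) structure(list(slice_id = id, axial_position = id * 0.5,
                                       contours = list(lumen = square(s),
                                                       outer = square(4))),
                                  class = "slice_contours")
  v <- vessel_spec(list(mk(2, 1), mk(sqrt(2), 2)), pressure_range = c(70, 125))
  expect_equal(stenosis(v), (1 - 2 / 4) * 100)
  v0 <- vessel_spec(list(mk(2, 1), mk(2, 2)), pressure_range = c(70, 125))
  expect_equal(stenosis(v0), 0)
})

test_that("plaque burden follows its defining formula and validates nesting", {
  sq <- function(s) rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  mk <- function(al, ao) structure(list(slice_id = 1L, axial_position = 0,
                                        contours = list(lumen = sq(sqrt(al)),
                                                        outer = sq(sqrt(ao)))),
                                   class = "slice_contours")
  expect_equal(plaque_burden(mk(3, 10)), 70)
  expect_equal(plaque_burden(mk(1e-8, 10)), 100, tolerance = 1e-6)
  expect_error(plaque_burden(mk(10, 3)), "nesting")
})

test_that("morphology is invariant under uniform coordinate scaling", {
  v <- generate_cohort(1, base_seed = 5)[[1]]
  v2 <- v
  v2$slices <- lapply(v$slices, function(s) {
    s$contours <- lapply(s$contours, function(p) p * 3.7)
    s
  })
  expect_equal(stenosis(v2), stenosis(v), tolerance = 1e-12)
  expect_equal(plaque_burden(v2$slices[[1]]), plaque_burden(v$slices[[1]]),
               tolerance = 1e-12)
})

test_that("cohort generation is deterministic with the contracted shape", {
  a <- generate_cohort(7, base_seed = 42)
  expect_length(a, 7)
  for (v in a) expect_gte(length(v$slices), 2)
  b <- generate_cohort(7, base_seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(7, base_seed = 43)))
})

test_that("zero variability collapses the cohort to identical slices", {
  v <- generate_cohort(1, base_seed = 9, variability = 0)[[1]]
  ref <- v$slices[[1]]$contours
  for (s in v$slices[-1]) expect_equal(s$contours, ref, tolerance = 1e-12)
  zs <- vapply(v$slices, function(s) s$axial_position, numeric(1))
  expect_equal(zs, (seq_along(zs) - 1) * 0.5)
})

test_that("contour CSV round-trips", {
  v <- generate_cohort(1, base_seed = 3)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(v, path)
  back <- read_contours(path)
  expect_length(back, length(v$slices))
  expect_equal(back[[2]]$contours$lumen, v$slices[[2]]$contours$lumen,
               tolerance = 1e-9)
  expect_equal(back[[2]]$axial_position, v$slices[[2]]$axial_position)
})
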