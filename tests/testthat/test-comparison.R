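test_that("pointwise statistics match their defining formulas", {
  d0 <- pointwise_delta(c(1, 2, 3), c(1, 2, 3))
  expect_equal(d0$mean_delta, 0)
  expect_equal(d0$relative_error, 0)

  d <- pointwise_delta(c(1, 2, 3), c(2, 3, 4))
  expect_identical(d$delta, c(1, 1, 1))
  expect_equal(d$mean_delta, 1)
  expect_equal(d$mean_base, 2)
  expect_equal(d$relative_error, 50)

  # swapping p and q keeps the mean difference but changes the base
  ds <- pointwise_delta(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ds$mean_delta, d$mean_delta)
  expect_false(isTRUE(all.equal(ds$relative_error, d$relative_error)))
})

test_that("pointwise statistics match a brute-force recomputation", {
  withr::with_seed(17, {
    for (i in 1:20) {
      p <- stats::runif(100, 10, 200)
      q <- stats::runif(100, 10, 200)
      d <- pointwise_delta(p, q)
      expect_equal(d$delta, abs(p - q), tolerance = 1e-12)
      expect_equal(d$mean_delta, sum(abs(p - q)) / 100, tolerance = 1e-12)
      expect_equal(d$mean_base, sum(p) / 100, tolerance = 1e-12)
      expect_equal(d$relative_error,
                   (sum(abs(p - q)) / 100) / (sum(p) / 100) * 100,
                   tolerance = 1e-12)
    }
  })
})

test_that("misaligned or mismatched profiles are rejected", {
  expect_error(pointwise_delta(1:3, 1:4), "different numbers")
  a <- tibble::tibble(point_index = 1:3, PWS_kPa = c(1, 2, 3))
  b <- tibble::tibble(point_index = c(2, 3, 4), PWS_kPa = c(1, 2, 3))
  expect_error(pointwise_delta(a, b, "PWS"), "misaligned")
})

test_that("model variant presets encode the feature matrix", {
  m1 <- model_variant("M1")
  expect_true(m1$circ_shrink); expect_false(m1$axial_shrink)
  expect_equal(m1$kinematics, "plane_strain_2d"); expect_equal(m1$flow, "none")
  m2 <- model_variant("M2")
  expect_false(m2$circ_shrink)
  m5 <- model_variant("M5")
  expect_true(m5$circ_shrink && m5$axial_shrink)
  expect_equal(m5$kinematics, "thin_layer"); expect_equal(m5$flow, "none")
  fsi <- model_variant("FSI")
  expect_equal(fsi$flow, "coupled")
  m7 <- model_variant("M7")
  expect_equal(m7$flow, "flow_only")
  expect_error(model_variant("M99"), "unknown variant")
})

test_that("run_variant honors flags, stamps provenance and is deterministic", {
  v <- generate_cohort(1, base_seed = 31,
                       variability = cohort_variability(n_slices = 2,
                                                        n_points = 64))[[1]]
  study <- study_config(h = 0.3, load_steps = 3)
  out <- run_variant(v, "M2", study)
  expect_equal(nrow(out), 2 * 100)
  expect_true(all(is.na(out$FSS_dyncm2)))        # no flow stage
  expect_true(all(is.finite(out$PWS_kPa)))
  out2 <- run_variant(v, "M2", study)
  expect_identical(out$PWS_kPa, out2$PWS_kPa)    # deterministic

  fo <- run_variant(v, "M7", study)
  expect_true(all(is.na(fo$PWS_kPa)))
  expect_true(all(is.finite(fo$FSS_dyncm2)))
  expect_equal(attr(fo, "provenance")$surrogate, "fully-developed")
})

test_that("self-comparison of a variant yields zero errors", {
  profs <- list(
    A = tibble::tibble(patient_id = "P1",
                       slice_id = rep(1:2, each = 3), variant = "A",
                       point_index = rep(1:3, 2), arc_s = 0, x = 0, y = 0,
                       PWS_kPa = c(1, 2, 3, 4, 5, 6),
                       PWSn = 0.01 * c(1, 2, 3, 4, 5, 6),
                       FSS_dyncm2 = NA_real_))
  profs$B <- profs$A
  cohortv <- generate_cohort(1, base_seed = 1)  # only for the interface
  rep <- cohort_report(cohortv, pairs = list(c("A", "B")),
                       profiles = profs)
  expect_true(all(rep$cohort$relative_error == 0))
  expect_true(all(rep$per_patient$relative_error == 0))
})

test_that("aggregation pools points rather than averaging means", {
  # two slices with different point counts of weight: hand-set values
  pa <- tibble::tibble(patient_id = "P1",
                       slice_id = rep(1:2, each = 2), variant = "A",
                       point_index = rep(1:2, 2), arc_s = 0, x = 0, y = 0,
                       PWS_kPa = c(10, 10, 100, 100),
                       PWSn = c(0.1, 0.1, 0.2, 0.2), FSS_dyncm2 = NA_real_)
  pb <- pa
  pb$PWS_kPa <- c(11, 11, 150, 150)   # deltas 1 and 50
  pb$PWSn <- pa$PWSn
  rep <- cohort_report(generate_cohort(1, base_seed = 1),
                       pairs = list(c("A", "B")),
                       profiles = list(A = pa, B = pb))
  pooled <- rep$cohort[rep$cohort$quantity == "PWS", ]
  expect_equal(pooled$mean_delta, mean(c(1, 1, 50, 50)))
  expect_equal(pooled$mean_base, mean(c(10, 10, 100, 100)))
  expect_equal(pooled$relative_error, 25.5 / 55 * 100)
  # patient level equals the pooled per-point computation, not mean of slices
  pp <- rep$per_patient[rep$per_patient$quantity == "PWS", ]
  expect_equal(pp$mean_delta, 25.5)
  # and differs from the mean of slice-level relative errors
  slice_rel <- rep$per_slice$relative_error[rep$per_slice$quantity == "PWS"]
  expect_false(isTRUE(all.equal(mean(slice_rel), pp$relative_error)))
})

test_that("per-patient extremes are flagged like the published tables", {
  rep <- cohort_study()
  pp <- rep$per_patient[rep$per_patient$pair == "M1:M2" &
                          rep$per_patient$quantity == "PWS", ]
  expect_equal(sum(pp$is_max_error), 1L)
  expect_equal(sum(pp$is_min_error), 1L)
  expect_equal(pp$relative_error[pp$is_max_error], max(pp$relative_error))
})

test_that("study configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cohort:",
    "  n_patients: 2",
    "  base_seed: 7",
    "solver:",
    "  h: 0.22",
    "  load_steps: 5",
    "  pressure_phase: min",
    "preconditioning:",
    "  shrink_tol: 0.002",
    "flow:",
    "  viscosity: 0.035",
    "  flow_rate: 1.5",
    "materials:",
    "  lipid: lipid",
    "comparison:",
    "  pairs: ['M1:M2', 'FSI:M5']"
  ), path)
  sc <- read_study_config(path)
  expect_equal(sc$study$h, 0.22)
  expect_equal(sc$study$pressure_phase, "min")
  expect_equal(sc$study$flow$viscosity, 0.035)
  expect_equal(sc$study$shrink_tol, 0.002)
  expect_equal(sc$pairs, list(c("M1", "M2"), c("FSI", "M5")))
  expect_equal(sc$cohort_args$n_patients, 2)
})

test_that("exports write readable VTK and CSV artifacts", {
  sol <- ring_solution_100mmHg()
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(sol, vtk)
  head <- readLines(vtk, n = 5)
  expect_equal(head[1], "# vtk DataFile Version 3.0")
  expect_match(head[5], sprintf("POINTS %d double", nrow(sol$mesh$nodes)))
  expect_true(any(grepl("VECTORS displacement", readLines(vtk))))

  prof <- sample_lumen(sol)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 100)
  expect_true(all(c("point_index", "arc_s", "x", "y", "PWS_kPa", "PWSn",
                    "FSS_dyncm2") %in% names(back)))
  expect_equal(back$PWS_kPa, prof$PWS_kPa, tolerance = 1e-6)

  flow <- solve_axial_flow(circle_poly(1.5, 128), flow_config())
  vtk2 <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(flow, vtk2)
  expect_true(any(grepl("axial_velocity", readLines(vtk2))))
})

test_that("tidy and glance methods return well-formed tibbles", {
  sol <- ring_solution_100mmHg()
  g <- glance(sol)
  expect_s3_class(g, "tbl_df")
  expect_true(g$converged)
  td <- tidy(sol)
  expect_equal(nrow(td), nrow(sol$mesh$tri))
  expect_true(all(c("region", "pws_kPa", "s11") %in% names(td)))

  d <- tidy(pointwise_delta(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(d$relative_error, 50)
})
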