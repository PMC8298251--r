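test_that("kinematics at identity and for isochoric planar stretch", {
  k <- kinematics(diag(2), 1, c(1, 0))
  expect_equal(c(k$I1, k$I2, k$I4, k$J), c(3, 3, 1, 1))
  expect_equal(k$green_strain, matrix(0, 3, 3))

  lam <- 1.3
  k2 <- kinematics(diag(c(lam, 1 / lam)), 1, c(1, 0))
  expect_equal(k2$I4, lam^2)
  expect_equal(k2$J, 1)
  expect_error(kinematics(diag(c(1, -1))), "positive determinant")
})

test_that("invariants agree with an eigen-decomposition oracle", {
  withr::with_seed(11, {
    for (i in 1:20) {
      F <- diag(2) + matrix(stats::rnorm(4, 0, 0.2), 2, 2)
      if (det(F) <= 0) next
      lz <- stats::runif(1, 0.9, 1.2)
      k <- kinematics(F, lz, c(0, 1))
      ev <- eigen(k$C, symmetric = TRUE, only.values = TRUE)$values
      expect_equal(k$I1, sum(ev), tolerance = 1e-12)
      expect_equal(k$I2, ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3],
                   tolerance = 1e-12)
      expect_equal(k$J, sqrt(prod(ev)), tolerance = 1e-12)
    }
  })
})

test_that("printed parameter presets are stored verbatim", {
  v <- material_params("vessel")
  expect_identical(c(v$c1, v$c2, v$D1, v$D2, v$K1, v$K2),
                   c(-1312.9, 114.7, 629.7, 2.0, 35.9, 23.5))
  l <- material_params("lipid")
  expect_identical(c(l$c1, l$c2, l$D1, l$D2), c(0.5, 0, 0.5, 1.5))
  cc <- material_params("calcification")
  expect_identical(c(cc$c1, cc$c2, cc$D1, cc$D2), c(92.0, 0, 36.0, 2.0))
  expect_true(v$anisotropic); expect_false(l$anisotropic)
})

test_that("reference state has zero energy and zero stress for all presets", {
  for (p in c("vessel", "lipid", "calcification")) {
    mat <- material_params(p)
    kin <- kinematics(diag(2), 1, c(0, 1))
    expect_equal(strain_energy(kin, mat), 0)
    expect_equal(max(abs(cauchy_stress(kin, mat)$cauchy)), 0, tolerance = 1e-12)
  }
})

test_that("lipid energy matches the direct scalar evaluation at I1 = I2 = 4", {
  # plane-strain C = diag(a, b, 1) with a + b = 3, ab = 1 gives I1 = I2 = 4, J = 1
  a <- (3 + sqrt(5)) / 2; b <- (3 - sqrt(5)) / 2
  kin <- kinematics(diag(sqrt(c(a, b))), 1, NULL)
  expect_equal(kin$I1, 4, tolerance = 1e-12)
  expect_equal(kin$I2, 4, tolerance = 1e-12)
  expect_equal(kin$J, 1, tolerance = 1e-12)
  W <- strain_energy(kin, material_params("lipid"))
  expect_equal(W, 0.5 * 1 + 0.5 * (exp(1.5) - 1), tolerance = 1e-9)
})

test_that("analytic stress matches central finite differences of W", {
  mats <- lapply(c("vessel", "lipid", "calcification"), material_params)
  withr::with_seed(3, {
    for (mat in mats) {
      for (i in 1:20) {
        F <- diag(2) + matrix(stats::rnorm(4, 0, 0.03), 2, 2)
        if (det(F) <= 0) next
        n_c <- c(0, 1)
        kin <- kinematics(F, 1, n_c)
        P_an <- kin$J * cauchy_stress(kin, mat)$cauchy[1:2, 1:2] %*% t(solve(F))
        P_fd <- matrix(0, 2, 2); h <- 1e-6
        for (r in 1:2) for (cc in 1:2) {
          Fp <- F; Fp[r, cc] <- Fp[r, cc] + h
          Fm <- F; Fm[r, cc] <- Fm[r, cc] - h
          P_fd[r, cc] <- (strain_energy(kinematics(Fp, 1, n_c), mat) -
                            strain_energy(kinematics(Fm, 1, n_c), mat)) / (2 * h)
        }
        expect_lt(max(abs(P_an - P_fd)) / max(max(abs(P_fd)), 1e-8), 1e-5)
      }
    }
  })
})

test_that("energy is objective and non-negative near identity", {
  mat <- material_params("vessel")
  withr::with_seed(5, {
    for (i in 1:20) {
      F <- diag(2) + matrix(stats::rnorm(4, 0, 0.05), 2, 2)
      if (det(F) <= 0) next
      a <- stats::runif(1, 0, 2 * pi)
      Q <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      w1 <- strain_energy(kinematics(F, 1, c(0, 1)), mat)
      w2 <- strain_energy(kinematics(Q %*% F, 1, c(0, 1)), mat)
      expect_equal(w1, w2, tolerance = 1e-10 * max(1, abs(w1)))
      expect_gte(w1, -1e-10)
    }
  })
})

test_that("equibiaxial stretch of an isotropic material gives equal normal stresses", {
  kin <- kinematics(diag(c(1.05, 1.05)), 1, NULL)
  s <- cauchy_stress(kin, material_params("calcification"))$cauchy
  expect_equal(s[1, 1], s[2, 2], tolerance = 1e-10)
  expect_equal(s[1, 2], 0, tolerance = 1e-10)
})

test_that("extreme isochoric stretch raises an explicit range error", {
  mat <- material_params("lipid")
  expect_error(strain_energy(kinematics(diag(c(60, 1 / 60)), 1, NULL), mat),
               "overflow")
  expect_error(cauchy_stress(kinematics(diag(c(60, 1 / 60)), 1, NULL), mat),
               "overflow")
})

test_that("principal_max matches the closed-form 2x2 eigenvalue", {
  expect_equal(principal_max(diag(c(3, 1))), 3)
  expect_equal(principal_max(matrix(c(0, 2, 2, 0), 2, 2)), 2)
  expect_error(principal_max(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  withr::with_seed(9, {
    for (i in 1:50) {
      a <- stats::rnorm(1); b <- stats::rnorm(1); cc <- stats::rnorm(1)
      m <- matrix(c(a, b, b, cc), 2, 2)
      closed <- (a + cc) / 2 + sqrt(((a - cc) / 2)^2 + b^2)
      expect_equal(principal_max(m), closed, tolerance = 1e-12)
    }
  })
})

test_that("stiffness scaling multiplies stress proportionally", {
  mat <- material_params("vessel")
  m10 <- scale_stiffness(mat, 10)
  kin <- kinematics(diag(c(1.05, 0.97)), 1, c(0, 1))
  s1 <- cauchy_stress(kin, mat)$cauchy
  s10 <- cauchy_stress(kin, m10)$cauchy
  expect_equal(s10, 10 * s1, tolerance = 1e-10)
})
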