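# Kinematics and stress evaluation for the modified Mooney-Rivlin laws.
# Deformation is in-plane 2x2 plus a prescribed axial stretch lambda_z; all
# invariants are the full 3D ones with the axial stretch folded in, so the
# plane-strain (lambda_z = 1) and thin-layer (lambda_z = 1/0.9) variants share
# one code path.

#' Kinematic state from an in-plane deformation gradient
#'
#' Builds the right Cauchy-Green tensor, its invariants, the squared fiber
#' stretch and the Green-Lagrange strain for a 2D in-plane deformation
#' gradient combined with a prescribed axial stretch.
#'
#' @param F 2x2 in-plane deformation gradient (dimensionless).
#' @param lambda_z prescribed axial stretch (1 for plane strain).
#' @param n_c in-plane unit fiber (circumferential) direction; may be `NULL`
#'   for isotropic materials, in which case `I4` is reported as 1.
#' @return Object of class `kinematic_state`: list with `F`, `C` (3x3),
#'   `I1`, `I2`, `I4`, `J`, `green_strain` (3x3), `lambda_z`, `n_c`.
#' @examples
#' k <- kinematics(diag(2))
#' c(k$I1, k$I2, k$I4, k$J)  # 3 3 1 1
#' @export
kinematics <- function(F, lambda_z = 1, n_c = NULL) {
  F <- matrix(as.numeric(F), 2, 2)
  detF2 <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  if (!is.finite(detF2) || detF2 <= 0)
    stop("deformation gradient must have positive determinant")
  stopifnot(lambda_z > 0)
  C2 <- crossprod(F)                      # F^T F, in-plane block
  C <- rbind(cbind(C2, c(0, 0)), c(0, 0, lambda_z^2))
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  if (!is.null(n_c)) {
    n_c <- as.numeric(n_c)
    if (abs(sqrt(sum(n_c^2)) - 1) > 1e-8) stop("n_c must be a unit vector")
    I4 <- as.numeric(n_c %*% C2 %*% n_c)
  } else {
    I4 <- 1
  }
  J <- detF2 * lambda_z
  E <- (C - diag(3)) / 2
  structure(list(F = F, C = C, I1 = I1, I2 = I2, I4 = I4, J = J,
                 green_strain = E, lambda_z = lambda_z, n_c = n_c),
            class = "kinematic_state")
}

# Derivatives of W with respect to the isochoric invariants
# I1b = J^(-2/3) I1, I2b = J^(-4/3) I2 (the standard nearly-incompressible
# split: the deviatoric terms see the reduced invariants, the volumetric
# penalty sees J, so the reference state is stress-free for any parameter
# set). Fiber term uses the full I4 and is tension-only.
.w_derivs <- function(kin, mat) {
  g1 <- kin$J^(-2 / 3); g2 <- kin$J^(-4 / 3)
  I1b <- g1 * kin$I1
  e1 <- mat$D2 * (I1b - 3)
  if (e1 > 700) stop("strain-energy exponential overflow: I1b - 3 = ",
                     format(I1b - 3), " is outside the usable range")
  W1 <- mat$c1 + mat$D1 * mat$D2 * exp(e1)
  W2 <- mat$c2
  fiber_on <- isTRUE(mat$anisotropic) && kin$I4 > 1
  if (fiber_on) {
    e4 <- mat$K2 * (kin$I4 - 1)^2
    if (e4 > 700) stop("fiber-term exponential overflow at I4 = ",
                       format(kin$I4))
    W4 <- 2 * mat$K1 * (kin$I4 - 1) * exp(e4)
  } else W4 <- 0
  WJ <- mat$kappa_vol * (kin$J - 1)
  list(W1 = W1, W2 = W2, W4 = W4, WJ = WJ, g1 = g1, g2 = g2,
       fiber_on = fiber_on)
}

#' Strain-energy density
#'
#' Evaluates the modified Mooney-Rivlin energy (isotropic polynomial +
#' exponential terms, a tension-only exponential fiber term for anisotropic
#' materials, and a quadratic volumetric penalty). Normalized so that
#' `W = 0` in the reference state.
#'
#' @param kin a [kinematics()] state.
#' @param mat a [material_params()] object.
#' @return Energy density in kPa.
#' @examples
#' strain_energy(kinematics(diag(2)), material_params("lipid"))  # 0
#' @export
strain_energy <- function(kin, mat) {
  stopifnot(inherits(kin, "kinematic_state"), inherits(mat, "material_params"))
  I1b <- kin$J^(-2 / 3) * kin$I1
  I2b <- kin$J^(-4 / 3) * kin$I2
  e1 <- mat$D2 * (I1b - 3)
  if (e1 > 700) stop("strain-energy exponential overflow: I1b - 3 = ",
                     format(I1b - 3), " is outside the usable range")
  W <- mat$c1 * (I1b - 3) + mat$c2 * (I2b - 3) +
    mat$D1 * (exp(e1) - 1) +
    (mat$kappa_vol / 2) * (kin$J - 1)^2
  if (isTRUE(mat$anisotropic) && kin$I4 > 1) {
    e4 <- mat$K2 * (kin$I4 - 1)^2
    if (e4 > 700) stop("fiber-term exponential overflow at I4 = ",
                       format(kin$I4))
    W <- W + (mat$K1 / mat$K2) * (exp(e4) - 1)
  }
  W
}

#' Cauchy stress
#'
#' Analytic Cauchy stress \eqn{\sigma = J^{-1} F S F^T} from the second
#' Piola-Kirchhoff stress \eqn{S = 2\,\partial W/\partial C}. Returns the full
#' 3x3 stress (the axial component is carried by the prescribed stretch).
#'
#' @inheritParams strain_energy
#' @return Object of class `stress_state`: list with `cauchy` (3x3, kPa),
#'   `principal_values` (sorted descending) and `principal_dirs` (columns).
#' @examples
#' s <- cauchy_stress(kinematics(diag(2)), material_params("vessel"))
#' max(abs(s$cauchy))  # 0
#' @export
cauchy_stress <- function(kin, mat) {
  stopifnot(inherits(kin, "kinematic_state"), inherits(mat, "material_params"))
  d <- .w_derivs(kin, mat)
  C2 <- kin$C[1:2, 1:2]
  I2x2 <- diag(2)
  C2inv <- solve(C2)
  C33 <- kin$lambda_z^2
  A2 <- I2x2 - (kin$I1 / 3) * C2inv
  B2 <- kin$I1 * I2x2 - C2 - (2 * kin$I2 / 3) * C2inv
  S2 <- 2 * d$W1 * d$g1 * A2 + 2 * d$W2 * d$g2 * B2 +
    d$WJ * kin$J * C2inv
  if (d$fiber_on) S2 <- S2 + 2 * d$W4 * tcrossprod(kin$n_c)
  A33 <- 1 - kin$I1 / (3 * C33)
  B33 <- kin$I1 - C33 - 2 * kin$I2 / (3 * C33)
  S33 <- 2 * d$W1 * d$g1 * A33 + 2 * d$W2 * d$g2 * B33 +
    d$WJ * kin$J / C33
  sig2 <- (kin$F %*% S2 %*% t(kin$F)) / kin$J
  sig2 <- (sig2 + t(sig2)) / 2
  szz <- C33 * S33 / kin$J
  sig <- rbind(cbind(sig2, c(0, 0)), c(0, 0, szz))
  eg <- eigen(sig, symmetric = TRUE)
  structure(list(cauchy = sig,
                 principal_values = eg$values,
                 principal_dirs = eg$vectors),
            class = "stress_state")
}

#' Maximum principal value of a symmetric tensor
#'
#' Largest (signed) eigenvalue. Applied to Cauchy stress this is the plaque
#' wall stress (PWS); applied to Green-Lagrange strain it is the plaque wall
#' strain (PWSn).
#'
#' @param m symmetric 2x2 or 3x3 matrix.
#' @return Scalar.
#' @examples
#' principal_max(diag(c(3, 1)))            # 3
#' principal_max(matrix(c(0, 2, 2, 0), 2)) # 2
#' @export
principal_max <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("input must be square")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("input tensor must be symmetric")
  max(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
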