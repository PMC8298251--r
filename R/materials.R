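#' Material parameter sets for the modified Mooney-Rivlin law
#'
#' Builds the parameter list for the hyperelastic strain-energy density used
#' for vessel wall and plaque components:
#' \deqn{W = c_1(\bar I_1-3) + c_2(\bar I_2-3) + D_1[e^{D_2(\bar I_1-3)}-1]
#'       + (K_1/K_2)\{e^{K_2(I_4-1)^2}-1\} + \tfrac{\kappa}{2}(J-1)^2}
#' where \eqn{\bar I_1 = J^{-2/3} I_1} and \eqn{\bar I_2 = J^{-4/3} I_2} are
#' the isochoric (reduced) invariants of the right Cauchy-Green tensor - the
#' standard nearly-incompressible split, which makes the reference state
#' stress-free for every parameter set (with the plain invariants the
#' published vessel set, whose \eqn{c_1 < 0}, carries a spurious hydrostatic
#' reference stress \eqn{2(c_1+2c_2+D_1 D_2)I}). The \eqn{I_4} fiber term is
#' present only for anisotropic materials (vessel/fibrous-cap tissue, fibers
#' circumferential) and is active only in fiber tension (\eqn{I_4 > 1}). The
#' quadratic volumetric penalty enforces near-incompressibility.
#'
#' Named presets carry the published coronary parameter values:
#' \describe{
#'   \item{vessel}{c1 = -1312.9, c2 = 114.7, D1 = 629.7, D2 = 2.0 kPa-scale,
#'     K1 = 35.9 kPa, K2 = 23.5 (anisotropic).}
#'   \item{lipid}{c1 = 0.5, c2 = 0, D1 = 0.5, D2 = 1.5 (isotropic).}
#'   \item{calcification}{c1 = 92.0, c2 = 0, D1 = 36.0, D2 = 2.0 (isotropic).}
#' }
#'
#' @param preset `"vessel"`, `"lipid"`, `"calcification"`, or `"custom"`.
#' @param c1,c2,D1 kPa; `D2`, `K2` dimensionless; `K1` kPa (0 disables the
#'   fiber term).
#' @param kappa_vol volumetric penalty modulus, kPa. The default (`NULL`)
#'   scales the penalty to the material, `max(3000, 500 mu)` with `mu` the
#'   small-strain shear modulus, corresponding to a Poisson ratio of about
#'   0.499. This matters for the vessel preset: its large negative `c1`
#'   makes the energy non-convex in the volumetric direction, and a penalty
#'   that is too soft relative to `mu` admits a spurious contracted energy
#'   well below the reference state. The scaled penalty removes the well
#'   (verified by `check_stability`).
#' @param check_stability verify at load time that the small-strain response
#'   is stable and that no negative-energy well exists along sampled
#'   in-plane deformation paths near identity.
#' @return An object of class `material_params`.
#' @examples
#' material_params("vessel")
#' material_params("custom", c1 = 10, c2 = 2, D1 = 1, D2 = 1)
#' @export
material_params <- function(preset = c("vessel", "lipid", "calcification", "custom"),
                            c1 = NULL, c2 = NULL, D1 = NULL, D2 = NULL,
                            K1 = NULL, K2 = NULL, kappa_vol = NULL,
                            check_stability = TRUE) {
  preset <- match.arg(preset)
  base <- switch(preset,
    vessel        = list(c1 = -1312.9, c2 = 114.7, D1 = 629.7, D2 = 2.0,
                         K1 = 35.9, K2 = 23.5, anisotropic = TRUE),
    lipid         = list(c1 = 0.5, c2 = 0, D1 = 0.5, D2 = 1.5,
                         K1 = 0, K2 = 1, anisotropic = FALSE),
    calcification = list(c1 = 92.0, c2 = 0, D1 = 36.0, D2 = 2.0,
                         K1 = 0, K2 = 1, anisotropic = FALSE),
    custom        = list(c1 = 0, c2 = 0, D1 = 0, D2 = 1,
                         K1 = 0, K2 = 1, anisotropic = FALSE)
  )
  for (nm in c("c1", "c2", "D1", "D2", "K1", "K2")) {
    v <- get(nm)
    if (!is.null(v)) base[[nm]] <- v
  }
  if (!is.null(K1) && K1 > 0) base$anisotropic <- TRUE
  if (base$K1 == 0) base$anisotropic <- FALSE
  mu <- 2 * (base$c1 + base$D1 * base$D2 + base$c2)
  if (is.null(kappa_vol)) kappa_vol <- max(3000, 500 * mu)
  stopifnot(kappa_vol > 0, base$D2 >= 0, base$K2 > 0)
  mat <- structure(c(base, list(kappa_vol = kappa_vol, preset = preset)),
                   class = "material_params")
  if (check_stability) {
    if (mu <= 0)
      stop("material is unstable at identity: small-strain shear modulus <= 0")
    # no energy well below the reference state along in-plane paths
    lam <- seq(0.9, 1.1, by = 0.004)
    w_eb <- vapply(lam, function(l)
      strain_energy(kinematics(diag(c(l, l))), mat), numeric(1))
    w_ux <- vapply(lam, function(l)
      strain_energy(kinematics(diag(c(l, 1))), mat), numeric(1))
    if (min(w_eb, w_ux) < -1e-8)
      stop("material is non-convex near identity (negative-energy well); ",
           "increase kappa_vol")
  }
  mat
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf(
    "<material_params> preset=%s  c1=%.1f c2=%.1f D1=%.1f D2=%.2f K1=%.1f K2=%.2f kPa  kappa_vol=%.0f  %s\n",
    x$preset, x$c1, x$c2, x$D1, x$D2, x$K1, x$K2, x$kappa_vol,
    if (x$anisotropic) "anisotropic" else "isotropic"))
  invisible(x)
}

#' Small-strain moduli from the tangent of W at identity
#'
#' Shear modulus of the isotropic part, \eqn{\mu = 2(W_1 + W_2)} evaluated at
#' \eqn{I_1 = I_2 = 3}, and the bulk-like modulus of the volumetric penalty.
#' Used for load-time stability checks and small-load benchmarks.
#'
#' @param mat a [material_params()] object.
#' @return List with `mu` (kPa) and `kappa` (kPa).
#' @export
small_strain_moduli <- function(mat) {
  W1 <- mat$c1 + mat$D1 * mat$D2   # dW/dI1 at I1 = 3
  W2 <- mat$c2
  list(mu = 2 * (W1 + W2), kappa = mat$kappa_vol)
}

#' Scale the stiffness of a material parameter set
#'
#' Multiplies every stress-like parameter (c1, c2, D1, K1, kappa_vol) by a
#' common factor; the dimensionless exponents D2, K2 are untouched. Used for
#' rigid-limit and stiffness-sensitivity studies.
#'
#' @param mat a [material_params()] object.
#' @param factor positive scalar.
#' @return A new `material_params` object.
#' @export
scale_stiffness <- function(mat, factor) {
  stopifnot(factor > 0)
  mat$c1 <- mat$c1 * factor; mat$c2 <- mat$c2 * factor
  mat$D1 <- mat$D1 * factor; mat$K1 <- mat$K1 * factor
  mat$kappa_vol <- mat$kappa_vol * factor
  mat$preset <- "custom"
  mat
}
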