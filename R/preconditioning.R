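# Recovery of the no-load geometry from the imaged (pressurized) geometry.
# The imaged contours are circumferentially shrunk by a scalar ratio k
# (lumen scaled by k about its centroid, outer contour rescaled so wall
# cross-sectional area is conserved through the axial shrink-stretch), and k
# is found by root-finding so that re-pressurizing the shrunk geometry at
# the imaging pressure recovers the in vivo lumen area. Each function
# evaluation is a full nonlinear FEM solve.

# Radial remap of mesh nodes / contour vertices for a shrink ratio k.
# Points between the lumen (scale k) and outer boundary (scale k_out) move
# linearly in their radial wall fraction, so inclusions stay nested and mesh
# topology is unchanged across k.
.shrink_map <- function(pts, center, rho_l, rho_o, k, k_out) {
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  # unclamped linear remap in the wall fraction: points marginally outside
  # [rho_l, rho_o] (e.g. midside nodes of boundary chords) extrapolate
  # smoothly instead of being snapped onto the boundary curve
  f <- (r - rho_l) / (rho_o - rho_l)
  r_new <- (1 - f) * k * rho_l + f * k_out * rho_o
  scl <- ifelse(r > 1e-12, r_new / r, 1)
  cbind(center[1] + dx * scl, center[2] + dy * scl)
}

#' Find the circumferential shrink ratio
#'
#' Root-finds the scalar shrink ratio `k` in the bracket such that the
#' shrunk geometry, when pressurized at the imaging pressure (and axially
#' stretched for thin-layer models), recovers the target in vivo lumen area
#' within `tol`. The outer contour is rescaled at every trial so that the
#' no-load wall cross-sectional area equals the in vivo wall area times the
#' axial stretch (volume conservation through the axial shrink-stretch).
#'
#' @param slice the in vivo `slice_contours` (as imaged).
#' @param materials named region materials list.
#' @param imaging_pressure pressure at which the geometry was imaged.
#' @param pressure_unit `"mmHg"` or `"kPa"`.
#' @param tol relative lumen-area tolerance (default 0.5 percent).
#' @param h mesh size, mm.
#' @param axial_stretch 1 for 2D models, 1/0.9 for thin-layer models.
#' @param bracket search interval for `k`.
#' @param target_lumen_area in vivo lumen area to recover, mm^2; defaults
#'   to the area of `slice`'s lumen contour.
#' @param newton_tol relative Newton residual tolerance of the inner FEM
#'   solves; relax for strongly stiffness-scaled materials, whose residual
#'   cannot cancel below the floating-point floor.
#' @param max_iter root-find iteration cap.
#' @return Object of class `shrink_result`: `circ_shrink_ratio`,
#'   `axial_shrink` (0.10 when an axial stretch is applied, else 0),
#'   `shrunk_slice`, `shrunk_mesh`, `iterations`, `achieved_area_error`
#'   (relative), `solution` (the FEM solution at the accepted `k`),
#'   `target_area`.
#' @export
find_circ_shrink <- function(slice, materials, imaging_pressure,
                             pressure_unit = c("mmHg", "kPa"), tol = 0.005,
                             h = 0.25, axial_stretch = 1,
                             bracket = c(0.7, 1.1),
                             target_lumen_area = NULL, newton_tol = 1e-8,
                             max_iter = 30L) {
  pressure_unit <- match.arg(pressure_unit)
  p_kPa <- if (pressure_unit == "mmHg") mmHg_to_kPa(imaging_pressure)
           else imaging_pressure
  stopifnot(p_kPa >= 0, tol > 0, inherits(slice, "slice_contours"))
  L <- slice$contours$lumen; O <- slice$contours$outer
  A_lum <- abs(polygon_area(L)); A_out <- abs(polygon_area(O))
  A_wall <- A_out - A_lum
  center <- polygon_centroid(L)

  mesh0 <- build_mesh(slice, h)
  # the in vivo target is measured in the same discrete metric the solver
  # reports (the meshed lumen loop), so the root is not biased by the
  # mesh-vs-contour area representation gap
  target <- target_lumen_area %||%
    abs(polygon_area(mesh0$nodes[mesh0$lumen_loop, , drop = FALSE]))
  th_n <- atan2(mesh0$nodes[, 2] - center[2], mesh0$nodes[, 1] - center[1])
  rho_l_n <- radial_profile(L, center, th_n)
  rho_o_n <- radial_profile(O, center, th_n)

  variant <- if (axial_stretch == 1) "plane_strain_2d" else "thin_layer"
  cfg <- solve_config(p_kPa, "kPa", axial_stretch = axial_stretch,
                      variant = variant, newton_tol = newton_tol)

  # wall area of the no-load state: in vivo wall area * axial stretch
  k_out_of <- function(k) {
    sqrt((A_wall * axial_stretch + k^2 * A_lum) / A_out)
  }
  make_shrunk <- function(k) {
    m <- mesh0
    m$nodes <- .shrink_map(mesh0$nodes, center, rho_l_n, rho_o_n,
                           k, k_out_of(k))
    m
  }
  warm <- NULL
  area_err <- function(k) {
    sol <- tryCatch(solve_static(make_shrunk(k), materials, cfg, init = warm),
                    error = function(e) NULL)
    if (is.null(sol)) return(list(fail = TRUE, err = NA_real_, sol = NULL))
    warm <<- sol
    list(fail = FALSE, err = (sol$lumen_area - target) / target, sol = sol)
  }

  if (p_kPa == 0 && axial_stretch == 1) {
    sol <- solve_static(mesh0, materials, cfg)
    return(.shrink_result(1, axial_stretch, slice, mesh0, 0L, 0, sol, target,
                          center, rho_l_n, rho_o_n))
  }

  # Secant iteration from the unshrunk geometry, clamped to the bracket.
  # The pressurized area is smooth and monotone increasing in k, and the
  # root sits near 1, so the search never needs to visit the far end of the
  # bracket. A failed solve at small k counts as "too shrunk" (step back).
  k1 <- min(1, bracket[2])
  e1 <- area_err(k1); it <- 1L
  if (e1$fail) stop("FEM solve failed at k = 1; geometry or materials invalid")
  if (abs(e1$err) < tol)
    return(.finish_shrink(k1, e1, it, slice, make_shrunk, axial_stretch,
                          target, center, rho_l_n, rho_o_n, k_out_of))
  k_neg <- NULL; f_neg <- NULL   # bracketing points by sign of err
  k_pos <- NULL; f_pos <- NULL
  if (e1$err > 0) { k_pos <- k1; f_pos <- e1$err } else { k_neg <- k1; f_neg <- e1$err }
  k2 <- k1 - sign(e1$err) * 0.04
  while (it < max_iter) {
    k2 <- min(max(k2, bracket[1]), bracket[2])
    e2 <- area_err(k2); it <- it + 1L
    if (e2$fail) {
      # solver failure: retreat halfway toward the last successful k
      if (k2 >= bracket[2] - 1e-9 || abs(k2 - k1) < 1e-4)
        stop(sprintf("shrink search: FEM solve failed near k = %.3f", k2))
      k2 <- (k1 + k2) / 2
      next
    }
    if (abs(e2$err) < tol)
      return(.finish_shrink(k2, e2, it, slice, make_shrunk, axial_stretch,
                            target, center, rho_l_n, rho_o_n, k_out_of))
    if (e2$err > 0) { k_pos <- k2; f_pos <- e2$err } else { k_neg <- k2; f_neg <- e2$err }
    if (!is.null(k_pos) && !is.null(k_neg)) {
      # regula falsi inside the established sign bracket
      k_new <- (k_neg * f_pos - k_pos * f_neg) / (f_pos - f_neg)
      lo <- min(k_pos, k_neg); hi <- max(k_pos, k_neg)
      if (!is.finite(k_new) || k_new <= lo || k_new >= hi)
        k_new <- (lo + hi) / 2
    } else {
      # same-sign secant step, clamped
      d_err <- (e2$err - e1$err) / (k2 - k1)
      k_new <- if (is.finite(d_err) && abs(d_err) > 1e-9)
        k2 - e2$err / d_err else k2 - sign(e2$err) * 0.04
      k_new <- min(max(k_new, k2 - 0.1), k2 + 0.1)
      if (k_new <= bracket[1] || k_new >= bracket[2])
        stop(sprintf(
          "bracket failure: shrink ratio outside [%.2f, %.2f] (err at k = %.3f is %+.2f%%)",
          bracket[1], bracket[2], k2, 100 * e2$err))
    }
    k1 <- k2; e1 <- e2
    k2 <- k_new
  }
  stop(sprintf("shrink search did not reach %.2f%% area tolerance in %d iterations",
               100 * tol, max_iter))
}

.finish_shrink <- function(k, e, it, slice, make_shrunk, axial_stretch,
                           target, center, rho_l_n, rho_o_n, k_out_of) {
  k_out <- k_out_of(k)
  shrunk_slice <- slice
  for (nm in names(slice$contours)) {
    poly <- slice$contours[[nm]]
    rho_l_v <- radial_profile(slice$contours$lumen, center,
                              atan2(poly[, 2] - center[2], poly[, 1] - center[1]))
    rho_o_v <- radial_profile(slice$contours$outer, center,
                              atan2(poly[, 2] - center[2], poly[, 1] - center[1]))
    shrunk_slice$contours[[nm]] <- .shrink_map(poly, center, rho_l_v, rho_o_v,
                                               k, k_out)
  }
  .shrink_result(k, axial_stretch, shrunk_slice, make_shrunk(k), it,
                 e$err, e$sol, target, center, rho_l_n, rho_o_n)
}

.shrink_result <- function(k, axial_stretch, shrunk_slice, shrunk_mesh, it,
                           err, sol, target, center, rho_l_n, rho_o_n) {
  structure(list(circ_shrink_ratio = k,
                 axial_shrink = if (axial_stretch > 1) 0.10 else 0,
                 axial_stretch = axial_stretch,
                 shrunk_slice = shrunk_slice, shrunk_mesh = shrunk_mesh,
                 iterations = it, achieved_area_error = err,
                 solution = sol, target_area = target),
            class = "shrink_result")
}

#' @export
print.shrink_result <- function(x, ...) {
  cat(sprintf(
    "<shrink_result> k = %.4f (axial shrink %.0f%%), %d FEM evaluations, area error %.3f%%\n",
    x$circ_shrink_ratio, 100 * x$axial_shrink, x$iterations,
    100 * x$achieved_area_error))
  invisible(x)
}

#' @export
glance.shrink_result <- function(x, ...) {
  tibble::tibble(circ_shrink_ratio = x$circ_shrink_ratio,
                 axial_shrink = x$axial_shrink,
                 axial_stretch = x$axial_stretch,
                 iterations = x$iterations,
                 achieved_area_error = x$achieved_area_error,
                 target_area_mm2 = x$target_area)
}

#' Apply the 10 percent axial shrink to a vessel
#'
#' Axial coordinates contract by the factor 0.9 and every cross-section
#' dilates in-plane by `1/sqrt(0.9)` about its lumen centroid, so per-slice
#' areas scale by 1/0.9 and tissue volume is conserved. The solver later
#' applies the axial stretch 1/0.9 to recover the in vivo length.
#'
#' @param vessel a [vessel_spec()].
#' @param shrink axial shrink fraction (default 0.10).
#' @return List with `vessel` (the shrunk [vessel_spec()]) and
#'   `axial_stretch` (`1/(1-shrink)`) to pass to the solver.
#' @export
apply_axial_shrink <- function(vessel, shrink = 0.10) {
  stopifnot(inherits(vessel, "vessel_spec"), shrink > 0, shrink < 1)
  ratio <- 1 - shrink
  scale <- 1 / sqrt(ratio)
  slices <- lapply(vessel$slices, function(s) {
    ctr <- polygon_centroid(s$contours$lumen)
    s$contours <- lapply(s$contours, function(p) {
      cbind(ctr[1] + (p[, 1] - ctr[1]) * scale,
            ctr[2] + (p[, 2] - ctr[2]) * scale)
    })
    s$axial_position <- s$axial_position * ratio
    s
  })
  out <- vessel
  out$slices <- slices
  out$slice_spacing <- vessel$slice_spacing * ratio
  list(vessel = out, axial_stretch = 1 / ratio)
}
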