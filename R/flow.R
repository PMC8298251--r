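# Desk-scale surrogate for the lumen flow computation: steady, fully
# developed laminar axial flow of a Newtonian fluid on the lumen
# cross-section. The axial velocity w solves -mu * laplacian(w) = G with
# w = 0 on the wall; wall shear stress is mu |dw/dn|. Every FSS output of
# the package carries the stamp "surrogate: fully-developed".

#' Flow configuration
#'
#' @param viscosity dynamic viscosity, Poise (dyn s/cm^2); 0.04 is typical
#'   whole blood.
#' @param flow_rate driving volumetric flow rate, mL/s. Exactly one of
#'   `flow_rate` and `pressure_gradient` must be given; a fixed flow rate is
#'   the default drive so FSS comparisons across model variants isolate
#'   geometry.
#' @param pressure_gradient axial pressure gradient, dyn/cm^3.
#' @param mesh_h flow-mesh element size, mm.
#' @return Object of class `flow_config`.
#' @export
flow_config <- function(viscosity = 0.04, flow_rate = 1.0,
                        pressure_gradient = NULL, mesh_h = 0.08) {
  if (!is.null(pressure_gradient)) flow_rate <- NULL
  if (is.null(flow_rate) == is.null(pressure_gradient))
    stop("specify exactly one of flow_rate and pressure_gradient")
  stopifnot(viscosity > 0, mesh_h > 0)
  structure(list(viscosity = viscosity, flow_rate = flow_rate,
                 pressure_gradient = pressure_gradient, mesh_h = mesh_h),
            class = "flow_config")
}

#' Solve fully developed axial flow on a lumen cross-section
#'
#' Linear-triangle FEM solve of the Poisson problem for the axial velocity,
#' with wall shear recovered by the consistent boundary-flux method (the
#' nodal residual of the interior equation divided by the tributary boundary
#' length), which converges much faster than differentiating the velocity
#' field directly.
#'
#' @param lumen n x 2 CCW polygon of the lumen boundary, mm.
#' @param config a [flow_config()].
#' @return Object of class `flow_solution`: list with `velocity` (per node,
#'   cm/s), `nodes` (cm), `tri`, `boundary` (node indices, CCW),
#'   `boundary_theta` (angle of each boundary node about the section
#'   center), `wall_shear` (dyn/cm^2 per boundary node), `Q` (mL/s),
#'   `G` (dyn/cm^3), `center` (mm), and a `surrogate` stamp.
#' @examples
#' th <- 2 * pi * (0:63) / 64
#' fs <- solve_axial_flow(cbind(1.5 * cos(th), 1.5 * sin(th)), flow_config())
#' mean(fs$wall_shear)   # ~ 4 mu Q / (pi R^3) with R in cm
#' @export
solve_axial_flow <- function(lumen, config = flow_config()) {
  stopifnot(inherits(config, "flow_config"))
  lumen <- as.matrix(lumen)
  if (abs(polygon_area(lumen)) < 1e-9) stop("zero-area lumen")
  if (polygon_area(lumen) < 0) lumen <- lumen[rev(seq_len(nrow(lumen))), ]
  dm <- build_disc_mesh(lumen, config$mesh_h)
  nodes <- dm$nodes * 0.1   # mm -> cm
  tri <- dm$tri
  mu <- config$viscosity
  nn <- nrow(nodes)

  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  A <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  if (any(A <= 0)) stop("flow mesh contains inverted elements")
  bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / (2 * A)
  by <- cbind(x3 - x2, x1 - x3, x2 - x1) / (2 * A)

  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    vv[[k]] <- mu * A * (bx[, a] * bx[, b] + by[, a] * by[, b])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(nn, nn))
  f1 <- numeric(nn)   # load vector for G = 1
  for (a in 1:3) {
    tmp <- tapply(A / 3, tri[, a], sum)
    f1[as.integer(names(tmp))] <- f1[as.integer(names(tmp))] + tmp
  }

  bnd <- dm$boundary
  interior <- setdiff(seq_len(nn), bnd)
  w <- numeric(nn)
  w[interior] <- as.numeric(Matrix::solve(K[interior, interior],
                                          f1[interior]))
  Q1 <- sum(A * (w[tri[, 1]] + w[tri[, 2]] + w[tri[, 3]]) / 3)
  if (!is.null(config$flow_rate)) {
    G <- config$flow_rate / Q1
  } else {
    G <- config$pressure_gradient
  }
  w <- w * G
  Q <- Q1 * G

  # consistent boundary flux: residual of the interior equation at wall nodes
  r <- as.numeric(K %*% w - G * f1)
  bxy <- nodes[bnd, , drop = FALSE]
  nb <- length(bnd)
  nxt <- c(seq_len(nb - 1) + 1, 1)
  seg <- sqrt(rowSums((bxy[nxt, ] - bxy)^2))
  tributary <- (seg + c(seg[nb], seg[-nb])) / 2
  fss <- abs(r[bnd]) / tributary
  if (any(w[interior] <= 0))
    warning("non-positive axial velocity in the interior; check lumen shape")

  ctr <- dm$center
  th <- atan2(dm$nodes[bnd, 2] - ctr[2], dm$nodes[bnd, 1] - ctr[1])
  structure(list(velocity = w, nodes = nodes, tri = tri, boundary = bnd,
                 boundary_theta = th, wall_shear = fss, Q = Q, G = G,
                 viscosity = mu, center = ctr, lumen_mm = lumen,
                 surrogate = "fully-developed"),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  s <- fss_summary(x)
  cat(sprintf(
    "<flow_solution> (surrogate: %s) Q = %.3f mL/s, G = %.1f dyn/cm^3, FSS max/min/ave = %.1f/%.1f/%.1f dyn/cm^2\n",
    x$surrogate, x$Q, x$G, s$max_fss, s$min_fss, s$ave_fss))
  invisible(x)
}

#' Sample the wall-shear profile at lumen points
#'
#' Interpolates the wall shear stress at `n` points uniformly spaced in
#' boundary arc length starting from the +x reference ray, or at caller-
#' supplied angular positions (used to align FSS with the structural PWS
#' sample points).
#'
#' @param flow a [solve_axial_flow()] result.
#' @param n number of points when `theta` is not given.
#' @param theta optional vector of angles (radians, about the section
#'   center) at which to interpolate.
#' @return Numeric vector of FSS values, dyn/cm^2.
#' @export
flow_fss_profile <- function(flow, n = 100L, theta = NULL) {
  stopifnot(inherits(flow, "flow_solution"))
  if (is.null(theta)) {
    # boundary nodes are CCW with node 1 on the +x ray: uniform arc sampling
    bxy <- flow$nodes[flow$boundary, , drop = FALSE]
    L <- polygon_arclength(bxy)
    L <- L[length(L)]
    s <- L * (seq_len(n) - 1) / n
    return(polygon_interp(bxy, flow$wall_shear, s))
  }
  th <- flow$boundary_theta
  ord <- order(th)
  ths <- th[ord]; fs <- flow$wall_shear[ord]
  thp <- c(ths[length(ths)] - 2 * pi, ths, ths[1] + 2 * pi)
  fsp <- c(fs[length(fs)], fs, fs[1])
  stats::approx(thp, fsp, xout = wrap_angle(theta))$y
}

#' Max, min and average wall shear stress
#'
#' Extrema and arithmetic mean of the FSS distribution, the three summary
#' statistics reported per slice (Max-FSS, Min-FSS, Ave-FSS).
#'
#' @param flow a `flow_solution`, a `lumen_profile` with a filled
#'   `FSS_dyncm2` column, or a bare numeric vector of FSS values.
#' @param n number of profile points when summarizing a `flow_solution`.
#' @return Tibble with `max_fss`, `min_fss`, `ave_fss` (dyn/cm^2).
#' @export
fss_summary <- function(flow, n = 100L) {
  v <- if (inherits(flow, "flow_solution")) {
    flow_fss_profile(flow, n = n)
  } else if (is.data.frame(flow)) {
    flow$FSS_dyncm2
  } else {
    as.numeric(flow)
  }
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite FSS values to summarize")
  tibble::tibble(max_fss = max(v), min_fss = min(v), ave_fss = mean(v))
}

#' Coupled structure-then-flow surrogate for one slice
#'
#' Sequential fluid-structure surrogate: the preconditioned (shrunk) wall is
#' pressurized with the lumen pressure reduced by the slice's fully
#' developed-flow dynamic pressure (\eqn{\rho \bar v^2/2} with
#' \eqn{\bar v = Q/A}, \eqn{\rho = 1} g/cm^3), then the flow problem is
#' solved on the deformed lumen and the wall shear is written into the
#' structural lumen profile at the same material sample points.
#'
#' @param slice the in vivo `slice_contours` (used for reference areas).
#' @param materials named region materials list.
#' @param pressure lumen pressure for the structural solve.
#' @param shrink a [find_circ_shrink()] result for this slice.
#' @param flow_cfg a [flow_config()].
#' @param n lumen sample points.
#' @param pressure_unit `"mmHg"` or `"kPa"`.
#' @param newton_tol relative Newton residual tolerance of the structural
#'   solve.
#' @return A `lumen_profile` tibble with `PWS_kPa`, `PWSn` and
#'   `FSS_dyncm2` filled; attributes carry the dynamic-pressure correction
#'   (kPa) and the surrogate stamp.
#' @export
coupled_fss <- function(slice, materials, pressure, shrink, flow_cfg = flow_config(),
                        n = 100L, pressure_unit = c("mmHg", "kPa"),
                        newton_tol = 1e-8) {
  pressure_unit <- match.arg(pressure_unit)
  p_kPa <- if (pressure_unit == "mmHg") mmHg_to_kPa(pressure) else pressure
  stopifnot(inherits(shrink, "shrink_result"))
  q_dyn_kPa <- 0
  if (!is.null(flow_cfg$flow_rate)) {
    A_cm2 <- shrink$target_area * 0.01          # mm^2 -> cm^2
    vbar <- flow_cfg$flow_rate / A_cm2          # cm/s
    q_dyn_kPa <- 0.5 * 1.0 * vbar^2 * 1e-4      # dyn/cm^2 -> kPa, rho = 1
  }
  variant <- if (shrink$axial_stretch == 1) "plane_strain_2d" else "thin_layer"
  cfg <- solve_config(max(p_kPa - q_dyn_kPa, 0), "kPa",
                      axial_stretch = shrink$axial_stretch, variant = variant,
                      newton_tol = newton_tol)
  sol <- solve_static(shrink$shrunk_mesh, materials, cfg,
                      init = shrink$solution)
  prof <- sample_lumen(sol, n, align = "material")
  def <- sol$mesh$nodes + sol$u
  lum_poly <- def[sol$mesh$lumen_loop, , drop = FALSE]
  flow <- solve_axial_flow(lum_poly, flow_cfg)
  ctr <- polygon_centroid(lum_poly)
  theta <- atan2(prof$y - ctr[2], prof$x - ctr[1])
  prof$FSS_dyncm2 <- flow_fss_profile(flow, theta = theta)
  attr(prof, "q_dyn_kPa") <- q_dyn_kPa
  attr(prof, "surrogate") <- "fully-developed"
  attr(prof, "lumen_area_deformed") <- sol$lumen_area
  prof
}
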