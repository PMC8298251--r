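# Seeded generator of VH-IVUS-like segmented cross-sections. Real inputs are
# segmented contour polygons (lumen, outer wall, lipid-rich necrotic core,
# calcification); this module emulates them so every downstream solver stage
# can be exercised without patient data.

#' Specification of one synthetic plaque cross-section
#'
#' Parameters of an idealized diseased coronary cross-section: an eccentric
#' elliptical lumen inside an outer wall, optionally a lipid-rich necrotic
#' core separated from the lumen by a fibrous cap of prescribed thickness,
#' and optionally a calcification band. Smooth band-limited radial noise
#' emulates segmentation irregularity while keeping contours simple.
#'
#' @param lumen_radius mean lumen radius, mm.
#' @param lumen_eccentricity 0 (concentric circle) to just under 1; controls
#'   both the lumen center offset and the elliptical aspect.
#' @param wall_thickness wall thickness measured along rays from the slice
#'   center, mm.
#' @param lipid_arc angular extent of the lipid core, degrees in [0, 360);
#'   0 means no lipid.
#' @param lipid_thickness radial thickness of the lipid core, mm.
#' @param cap_thickness fibrous-cap thickness (lumen-to-lipid distance), mm.
#' @param calc_present logical; include a calcification band.
#' @param calc_arc angular extent of the calcification, degrees.
#' @param noise_amplitude peak radial perturbation, mm.
#' @param n_points vertices per contour polygon (64-256).
#' @param seed integer seed; identical specs with identical seeds generate
#'   bit-identical contours.
#' @return Object of class `slice_spec`.
#' @export
slice_spec <- function(lumen_radius = 1.5, lumen_eccentricity = 0.3,
                       wall_thickness = 1.0, lipid_arc = 100,
                       lipid_thickness = 0.4, cap_thickness = 0.15,
                       calc_present = FALSE, calc_arc = 40,
                       noise_amplitude = 0.02, n_points = 128, seed = 1L) {
  stopifnot(lumen_radius > 0, wall_thickness > 0,
            lumen_eccentricity >= 0, lumen_eccentricity < 1,
            lipid_arc >= 0, lipid_arc < 360, calc_arc > 0, calc_arc < 360,
            noise_amplitude >= 0, n_points >= 64, n_points <= 256)
  if (lipid_arc > 0) {
    if (cap_thickness <= 0) stop("cap_thickness must be > 0 when lipid is present")
    if (lipid_thickness <= 0) stop("lipid_thickness must be > 0 when lipid is present")
    if (lipid_thickness + cap_thickness >= wall_thickness)
      stop("infeasible slice: lipid_thickness + cap_thickness (",
           lipid_thickness + cap_thickness, " mm) >= wall_thickness (",
           wall_thickness, " mm)")
  }
  if (calc_present && lipid_arc > 0 && (calc_arc + lipid_arc) / 2 > 170)
    stop("infeasible slice: calcification and lipid arcs overlap")
  structure(list(lumen_radius = lumen_radius,
                 lumen_eccentricity = lumen_eccentricity,
                 wall_thickness = wall_thickness, lipid_arc = lipid_arc,
                 lipid_thickness = lipid_thickness,
                 cap_thickness = cap_thickness, calc_present = calc_present,
                 calc_arc = calc_arc, noise_amplitude = noise_amplitude,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "slice_spec")
}

# Band-limited periodic perturbation (modes 2..5), scaled to peak `amp`.
.smooth_noise <- function(theta, amp) {
  if (amp <= 0) return(rep(0, length(theta)))
  k <- 2:5
  a <- stats::runif(length(k), -1, 1)
  ph <- stats::runif(length(k), 0, 2 * pi)
  f <- rep(0, length(theta))
  for (i in seq_along(k)) f <- f + a[i] * cos(k[i] * theta + ph[i])
  if (max(abs(f)) < 1e-12) return(rep(0, length(theta)))
  f / max(abs(f)) * amp
}

#' Generate one synthetic segmented cross-section
#'
#' Deterministically builds the closed CCW contour polygons (lumen, outer
#' wall, optional lipid core and calcification) described by a
#' [slice_spec()]. The lipid core's inner boundary is the lumen contour
#' offset outward along its normals by exactly `cap_thickness`, so the
#' minimum lumen-to-lipid polygon distance equals the cap thickness up to
#' discretization.
#'
#' @param spec a [slice_spec()].
#' @param slice_id integer identifier stored in the result.
#' @param axial_position axial position of the slice along the vessel, mm.
#' @return Object of class `slice_contours`: list with `slice_id`,
#'   `axial_position` and `contours`, a named list of n x 2 CCW vertex
#'   matrices (`lumen`, `outer`, and optionally `lipid`, `calc`).
#' @examples
#' sl <- generate_slice(slice_spec(seed = 7))
#' names(sl$contours)
#' @export
generate_slice <- function(spec, slice_id = 1L, axial_position = 0) {
  stopifnot(inherits(spec, "slice_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_points
    th <- 2 * pi * (seq_len(n) - 1) / n
    ecc <- spec$lumen_eccentricity
    r <- spec$lumen_radius
    d <- 0.4 * ecc * r                       # lumen center offset toward +x
    a <- r * (1 + 0.25 * ecc)                # ellipse semi-axes, area-preserving
    b <- r * (1 - 0.25 * ecc)
    rho_n <- .smooth_noise(th, spec$noise_amplitude)
    lum <- cbind(d + (a + rho_n) * cos(th), (b + rho_n) * sin(th))
    # outer wall: constant ray thickness beyond the lumen, about the origin
    rho_l <- radial_profile(lum, c(0, 0), th)
    wall_n <- .smooth_noise(th, spec$noise_amplitude)
    rho_o <- rho_l + spec$wall_thickness + wall_n
    outer <- cbind(rho_o * cos(th), rho_o * sin(th))
    contours <- list(lumen = lum, outer = outer)

    if (spec$lipid_arc > 0) {
      # normal offset of the lumen contour; arc centered on the thick side (-x)
      nrm <- .lumen_normals(lum)
      half <- spec$lipid_arc * pi / 360
      ang <- atan2(lum[, 2], lum[, 1])       # angle about slice center
      keep <- which(abs(wrap_angle(ang - pi)) <= half)
      keep <- keep[order(wrap_angle(ang[keep] - pi))]
      inner <- lum[keep, , drop = FALSE] + spec$cap_thickness * nrm[keep, , drop = FALSE]
      outer_l <- lum[keep, , drop = FALSE] +
        (spec$cap_thickness + spec$lipid_thickness) * nrm[keep, , drop = FALSE]
      lipid <- rbind(inner, outer_l[rev(seq_len(nrow(outer_l))), , drop = FALSE])
      if (polygon_area(lipid) < 0) lipid <- lipid[rev(seq_len(nrow(lipid))), ]
      contours$lipid <- lipid
    }
    if (isTRUE(spec$calc_present)) {
      halfc <- spec$calc_arc * pi / 360
      thc <- seq(-halfc, halfc, length.out = max(8, ceiling(n * halfc / pi)))
      rl <- radial_profile(lum, c(0, 0), thc)
      ro <- radial_profile(outer, c(0, 0), thc)
      r1 <- rl + 0.35 * (ro - rl); r2 <- rl + 0.65 * (ro - rl)
      calc <- rbind(cbind(r1 * cos(thc), r1 * sin(thc)),
                    cbind(rev(r2 * cos(thc)), rev(r2 * sin(thc))))
      if (polygon_area(calc) < 0) calc <- calc[rev(seq_len(nrow(calc))), ]
      contours$calc <- calc
    }
    structure(list(slice_id = as.integer(slice_id),
                   axial_position = axial_position,
                   contours = contours, spec = spec),
              class = "slice_contours")
  })
}

# Outward vertex normals of the (CCW) lumen polygon.
.lumen_normals <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, ])
  prv <- rbind(poly[nrow(poly), ], poly[-nrow(poly), , drop = FALSE])
  tv <- nxt - prv
  tv <- tv / sqrt(rowSums(tv^2))
  cbind(tv[, 2], -tv[, 1])   # rotate tangent -90 deg: outward for CCW loop
}

#' @export
print.slice_contours <- function(x, ...) {
  cat(sprintf("<slice_contours> id=%d z=%.2f mm regions: %s\n",
              x$slice_id, x$axial_position,
              paste(names(x$contours), collapse = ", ")))
  invisible(x)
}

#' Tidy a slice's contours into a long tibble
#'
#' @param x a `slice_contours` object.
#' @param ... unused.
#' @return Tibble with columns `slice_id`, `region`, `point_index`, `x_mm`,
#'   `y_mm`, `axial_mm`.
#' @export
tidy.slice_contours <- function(x, ...) {
  purrr::map_dfr(names(x$contours), function(rg) {
    m <- x$contours[[rg]]
    tibble::tibble(slice_id = x$slice_id, region = rg,
                   point_index = seq_len(nrow(m)),
                   x_mm = m[, 1], y_mm = m[, 2], axial_mm = x$axial_position)
  })
}

#' Construct a vessel from slices
#'
#' @param slices list of [generate_slice()] results, ordered proximal to
#'   distal (the first slice is the inlet).
#' @param patient_id label.
#' @param slice_spacing axial spacing, mm.
#' @param pressure_range length-2 numeric, (P_min, P_max) in mmHg.
#' @param imaging_pressure pressure at which the geometry was imaged, mmHg;
#'   defaults to P_min (diastole).
#' @return Object of class `vessel_spec`.
#' @export
vessel_spec <- function(slices, patient_id = "P1", slice_spacing = 0.5,
                        pressure_range = c(70, 125),
                        imaging_pressure = pressure_range[1]) {
  stopifnot(length(slices) >= 2, pressure_range[1] < pressure_range[2],
            imaging_pressure >= pressure_range[1],
            imaging_pressure <= pressure_range[2])
  structure(list(patient_id = patient_id, slices = slices,
                 slice_spacing = slice_spacing,
                 pressure_range = as.numeric(pressure_range),
                 imaging_pressure = as.numeric(imaging_pressure)),
            class = "vessel_spec")
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat(sprintf("<vessel_spec> %s: %d slices, spacing %.2f mm, BP %g-%g mmHg (imaged at %g)\n",
              x$patient_id, length(x$slices), x$slice_spacing,
              x$pressure_range[1], x$pressure_range[2], x$imaging_pressure))
  invisible(x)
}

#' Cohort variability configuration
#'
#' Ranges from which per-patient and per-slice parameters are drawn by
#' [generate_cohort()]. Defaults emulate the morphology spread of a small
#' coronary cohort: blood pressure 60-97 / 110-145 mmHg, plaque burden
#' roughly 58-82 percent and stenosis roughly 35-66 percent.
#'
#' @param n_slices slices per vessel.
#' @param lumen_radius,wall_thickness,eccentricity,lipid_arc,lipid_thickness,cap_thickness
#'   length-2 ranges for uniform draws.
#' @param severity range of fractional mid-vessel lumen radius reduction
#'   (drives stenosis).
#' @param calc_prob probability a patient has a calcification band.
#' @param noise_amplitude radial noise, mm.
#' @param p_min,p_max ranges for diastolic and systolic pressure, mmHg.
#' @param n_points contour vertices.
#' @return List of class `cohort_variability`.
#' @export
cohort_variability <- function(n_slices = 3,
                               lumen_radius = c(1.3, 1.7),
                               wall_thickness = c(0.9, 1.2),
                               eccentricity = c(0.15, 0.45),
                               lipid_arc = c(60, 140),
                               lipid_thickness = c(0.3, 0.5),
                               cap_thickness = c(0.10, 0.25),
                               severity = c(0.20, 0.45),
                               calc_prob = 0.3,
                               noise_amplitude = 0.02,
                               p_min = c(60, 97), p_max = c(110, 145),
                               n_points = 96) {
  structure(list(n_slices = n_slices, lumen_radius = lumen_radius,
                 wall_thickness = wall_thickness, eccentricity = eccentricity,
                 lipid_arc = lipid_arc, lipid_thickness = lipid_thickness,
                 cap_thickness = cap_thickness, severity = severity,
                 calc_prob = calc_prob, noise_amplitude = noise_amplitude,
                 p_min = p_min, p_max = p_max, n_points = n_points),
            class = "cohort_variability")
}

#' Generate a synthetic multi-patient cohort
#'
#' Draws per-patient morphology and pressure ranges from the variability
#' configuration and stacks slices into vessels. Fully deterministic given
#' `base_seed`. Passing `variability = 0` collapses every range to its
#' midpoint with zero severity and zero noise, producing vessels whose
#' slices are identical up to axial position.
#'
#' @param n_patients number of vessels to generate.
#' @param base_seed integer seed.
#' @param variability a [cohort_variability()] or the scalar 0.
#' @return List of [vessel_spec()] objects, named `P1`, `P2`, ...
#' @examples
#' cohort <- generate_cohort(2, base_seed = 42)
#' length(cohort)
#' @export
generate_cohort <- function(n_patients, base_seed = 42L,
                            variability = cohort_variability()) {
  stopifnot(n_patients >= 1)
  if (identical(variability, 0)) {
    v <- cohort_variability()
    mid <- function(r) rep(mean(r), 2)
    v$lumen_radius <- mid(v$lumen_radius); v$wall_thickness <- mid(v$wall_thickness)
    v$eccentricity <- mid(v$eccentricity); v$lipid_arc <- mid(v$lipid_arc)
    v$lipid_thickness <- mid(v$lipid_thickness); v$cap_thickness <- mid(v$cap_thickness)
    v$severity <- c(0, 0); v$calc_prob <- 0; v$noise_amplitude <- 0
    v$p_min <- mid(v$p_min); v$p_max <- mid(v$p_max)
    variability <- v
  }
  stopifnot(inherits(variability, "cohort_variability"))
  v <- variability
  lapply(seq_len(n_patients), function(ip) {
    pseed <- as.integer((base_seed * 1000L + ip * 7L) %% .Machine$integer.max)
    with_local_seed(pseed, {
      runi <- function(r) stats::runif(1, r[1], r[2])
      r0 <- runi(v$lumen_radius)
      wt <- runi(v$wall_thickness)
      ec <- runi(v$eccentricity)
      la <- runi(v$lipid_arc)
      lt <- runi(v$lipid_thickness)
      ct <- runi(v$cap_thickness)
      # keep the core feasible inside the wall
      if (lt + ct >= 0.9 * wt) lt <- 0.9 * wt - ct - 0.05
      sev <- runi(v$severity)
      calc <- stats::runif(1) < v$calc_prob
      pmin <- round(runi(v$p_min))
      pmax <- round(runi(v$p_max))
      ns <- v$n_slices
      # lumen narrows toward mid-vessel: inlet widest, center tightest
      prof <- if (ns == 1) 0 else sin(pi * (seq_len(ns) - 1) / (ns - 1))
      radii <- r0 * (1 - sev * prof)
      slices <- lapply(seq_len(ns), function(is) {
        sp <- slice_spec(lumen_radius = radii[is], lumen_eccentricity = ec,
                         wall_thickness = wt, lipid_arc = la,
                         lipid_thickness = lt, cap_thickness = ct,
                         calc_present = calc, noise_amplitude = v$noise_amplitude,
                         n_points = v$n_points,
                         seed = pseed + is * 101L)
        generate_slice(sp, slice_id = is, axial_position = (is - 1) * 0.5)
      })
      vessel_spec(slices, patient_id = paste0("P", ip),
                  slice_spacing = 0.5, pressure_range = c(pmin, pmax),
                  imaging_pressure = pmin)
    })
  }) |> stats::setNames(paste0("P", seq_len(n_patients)))
}

#' Stenosis severity of a vessel
#'
#' `(1 - min lumen area / inlet lumen area) * 100`, the inlet being the
#' first slice; areas by the shoelace formula.
#'
#' @param vessel a [vessel_spec()].
#' @return Percent stenosis.
#' @export
stenosis <- function(vessel) {
  stopifnot(inherits(vessel, "vessel_spec"))
  areas <- vapply(vessel$slices, function(s) abs(polygon_area(s$contours$lumen)),
                  numeric(1))
  if (any(areas < 1e-9)) stop("degenerate (zero-area) lumen contour")
  (1 - min(areas) / areas[1]) * 100
}

#' Plaque burden of one slice
#'
#' `(wall area - lumen area) / wall area * 100`, the wall area being the
#' area enclosed by the outer contour.
#'
#' @param slice a `slice_contours` object.
#' @return Percent plaque burden.
#' @export
plaque_burden <- function(slice) {
  stopifnot(inherits(slice, "slice_contours"))
  a_out <- abs(polygon_area(slice$contours$outer))
  a_lum <- abs(polygon_area(slice$contours$lumen))
  if (a_lum > a_out) stop("invalid nesting: lumen area exceeds outer area")
  if (a_out < 1e-9) stop("degenerate outer contour")
  (a_out - a_lum) / a_out * 100
}

#' Morphology table for a vessel
#'
#' @param vessel a [vessel_spec()].
#' @return Tibble with one row per slice (`slice_id`, `lumen_area`,
#'   `wall_area`, `plaque_burden_pct`) plus vessel-level `stenosis_pct`
#'   repeated on every row.
#' @export
vessel_morphology <- function(vessel) {
  st <- stenosis(vessel)
  purrr::map_dfr(vessel$slices, function(s) {
    tibble::tibble(patient_id = vessel$patient_id, slice_id = s$slice_id,
                   lumen_area = abs(polygon_area(s$contours$lumen)),
                   wall_area = abs(polygon_area(s$contours$outer)),
                   plaque_burden_pct = plaque_burden(s),
                   stenosis_pct = st)
  })
}

#' Write / read vessel contours as CSV
#'
#' One file per vessel with columns `slice_id`, `region`, `point_index`,
#' `x_mm`, `y_mm`, `axial_mm`; points counterclockwise, header mandatory.
#'
#' @param vessel a [vessel_spec()].
#' @param path CSV file path.
#' @return `write_contours` returns `path` invisibly; `read_contours`
#'   returns a list of `slice_contours` (pressure metadata must be supplied
#'   separately when rebuilding a [vessel_spec()]).
#' @export
write_contours <- function(vessel, path) {
  df <- purrr::map_dfr(vessel$slices, tidy.slice_contours)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice_id", "region", "point_index", "x_mm", "y_mm", "axial_mm")
  if (!all(need %in% names(df))) stop("contour CSV must have columns: ",
                                      paste(need, collapse = ", "))
  df$region[df$region == "calcification"] <- "calc"
  lapply(split(df, df$slice_id), function(d) {
    contours <- lapply(split(d, d$region), function(r) {
      r <- r[order(r$point_index), ]
      m <- cbind(r$x_mm, r$y_mm)
      if (polygon_area(m) < 0) m <- m[rev(seq_len(nrow(m))), ]
      m
    })
    ord <- intersect(c("lumen", "outer", "lipid", "calc"), names(contours))
    structure(list(slice_id = d$slice_id[1], axial_position = d$axial_mm[1],
                   contours = contours[ord]),
              class = "slice_contours")
  }) |> unname()
}
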