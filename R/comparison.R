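# Model-variant orchestration and the pointwise comparison statistics:
# Delta_i = |p_i - q_i|, MeanDelta = sum(Delta_i)/n, MeanBase = sum(p_i)/n,
# RelativeError = MeanDelta / MeanBase * 100, with model p as the base.
# Aggregation at slice, patient and cohort level is pooled over points (one
# summation with n = total points), never a mean of means.

#' Model variant definition
#'
#' The feature matrix of the compared models: circumferential shrink
#' preconditioning, 10 percent axial shrink-stretch, in-plane kinematics,
#' and the flow stage.
#'
#' Named presets:
#' \describe{
#'   \item{M1}{2D plane strain with circumferential shrink, no flow.}
#'   \item{M2}{2D plane strain without shrink, no flow.}
#'   \item{M5}{thin-layer structure-only: circumferential + axial shrink.}
#'   \item{FSI}{thin-layer coupled structure-then-flow surrogate.}
#'   \item{M7}{flow-only on the imaged lumen (no wall mechanics).}
#' }
#'
#' @param name preset name, or any label when the flags are given explicitly.
#' @param circ_shrink,axial_shrink logicals.
#' @param kinematics `"plane_strain_2d"`, `"thin_layer"`, or `NA` for
#'   flow-only models.
#' @param flow `"none"`, `"flow_only"`, or `"coupled"`.
#' @return Object of class `model_variant`.
#' @export
model_variant <- function(name, circ_shrink = NULL, axial_shrink = NULL,
                          kinematics = NULL, flow = NULL) {
  presets <- list(
    M1  = list(circ_shrink = TRUE,  axial_shrink = FALSE,
               kinematics = "plane_strain_2d", flow = "none"),
    M2  = list(circ_shrink = FALSE, axial_shrink = FALSE,
               kinematics = "plane_strain_2d", flow = "none"),
    M5  = list(circ_shrink = TRUE,  axial_shrink = TRUE,
               kinematics = "thin_layer", flow = "none"),
    FSI = list(circ_shrink = TRUE,  axial_shrink = TRUE,
               kinematics = "thin_layer", flow = "coupled"),
    M7  = list(circ_shrink = FALSE, axial_shrink = FALSE,
               kinematics = NA_character_, flow = "flow_only"))
  v <- presets[[name]] %||% list(circ_shrink = circ_shrink,
                                 axial_shrink = axial_shrink,
                                 kinematics = kinematics, flow = flow)
  for (nm in c("circ_shrink", "axial_shrink", "kinematics", "flow")) {
    ov <- get(nm)
    if (!is.null(ov)) v[[nm]] <- ov
  }
  if (is.null(v$flow)) stop("unknown variant '", name,
                            "' and no explicit flags given")
  stopifnot(v$flow %in% c("none", "flow_only", "coupled"))
  if (v$flow != "flow_only")
    stopifnot(v$kinematics %in% c("plane_strain_2d", "thin_layer"))
  structure(c(list(name = name), v), class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("<model_variant> %s: shrink=%s axial=%s kinematics=%s flow=%s\n",
              x$name, x$circ_shrink, x$axial_shrink, x$kinematics, x$flow))
  invisible(x)
}

#' Study configuration
#'
#' Bundles the settings shared by every stage of a cohort run.
#'
#' @param materials named region-to-[material_params()] list.
#' @param h structural mesh size, mm.
#' @param n_points lumen sample points per slice.
#' @param flow a [flow_config()].
#' @param shrink_tol relative lumen-area tolerance of the shrink search.
#' @param pressure_phase `"max"` (systolic) or `"min"` (diastolic): which
#'   end of each patient's pressure range the solves use.
#' @param load_steps incremental load steps for the structural solves.
#' @return Object of class `study_config`.
#' @export
study_config <- function(materials = list(wall = material_params("vessel"),
                                          lipid = material_params("lipid"),
                                          calc = material_params("calcification")),
                         h = 0.18, n_points = 100L, flow = flow_config(),
                         shrink_tol = 0.001,
                         pressure_phase = c("max", "min"),
                         load_steps = 6L) {
  pressure_phase <- match.arg(pressure_phase)
  structure(list(materials = materials, h = h,
                 n_points = as.integer(n_points), flow = flow,
                 shrink_tol = shrink_tol, pressure_phase = pressure_phase,
                 load_steps = as.integer(load_steps)),
            class = "study_config")
}

# 100 material sample points on a polygon, CCW from the +x ray through its
# centroid (used for flow-only variants where no FEM mesh exists).
.lumen_points <- function(poly, n) {
  ctr <- polygon_centroid(poly)
  ang <- wrap_angle(atan2(poly[, 2] - ctr[2], poly[, 1] - ctr[1]))
  arc <- polygon_arclength(poly)
  L <- arc[length(arc)]
  angc <- c(ang, ang[1]); s0 <- 0
  for (k in seq_len(length(angc) - 1)) {
    a1 <- angc[k]; a2 <- angc[k + 1]
    if (a1 <= 0 && a2 > 0 && (a2 - a1) < pi) {
      s0 <- arc[k] + (0 - a1) / (a2 - a1) * (arc[k + 1] - arc[k])
      break
    }
  }
  s <- (s0 + L * (seq_len(n) - 1) / n) %% L
  pos <- polygon_interp(poly, poly, s)
  list(s = s, pos = pos, center = ctr)
}

#' Run one model variant over a vessel
#'
#' Per-slice pipeline honoring the variant's feature flags: axial shrink,
#' circumferential shrink search, structural solve at the selected pressure
#' phase, lumen sampling, and the flow stage. Deterministic given the vessel
#' and configuration.
#'
#' @param vessel a [vessel_spec()].
#' @param variant a [model_variant()] or preset name.
#' @param study a [study_config()].
#' @param shrink_cache optional environment memoizing [find_circ_shrink()]
#'   results across variants that share a preconditioning configuration
#'   (used by [cohort_report()] so M5 and the coupled surrogate reuse one
#'   search per slice).
#' @return Tibble with one row per lumen point per slice: `patient_id`,
#'   `slice_id`, `variant`, `point_index`, `arc_s`, `x`, `y`, `PWS_kPa`,
#'   `PWSn`, `FSS_dyncm2` (NA where the variant does not compute a field).
#'   Attribute `provenance` records pressures, shrink ratios and stamps.
#' @export
run_variant <- function(vessel, variant, study = study_config(),
                        shrink_cache = NULL) {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(inherits(vessel, "vessel_spec"), inherits(variant, "model_variant"),
            inherits(study, "study_config"))
  p_mmHg <- if (study$pressure_phase == "max") vessel$pressure_range[2]
            else vessel$pressure_range[1]
  prov <- list(variant = variant, pressure_mmHg = p_mmHg,
               imaging_pressure_mmHg = vessel$imaging_pressure,
               surrogate = if (variant$flow != "none") "fully-developed" else NA,
               slices = list())

  vshr <- if (isTRUE(variant$axial_shrink)) apply_axial_shrink(vessel)
          else list(vessel = vessel, axial_stretch = 1)
  lz <- vshr$axial_stretch

  rows <- vector("list", length(vessel$slices))
  for (i in seq_along(vessel$slices)) {
    sl0 <- vessel$slices[[i]]          # in vivo (imaged) slice

    if (variant$flow == "flow_only") {
      lp <- .lumen_points(sl0$contours$lumen, study$n_points)
      flow <- solve_axial_flow(sl0$contours$lumen, study$flow)
      theta <- atan2(lp$pos[, 2] - lp$center[2], lp$pos[, 1] - lp$center[1])
      prof <- tibble::tibble(point_index = seq_len(study$n_points),
                             arc_s = as.numeric(lp$s),
                             x = lp$pos[, 1], y = lp$pos[, 2],
                             PWS_kPa = NA_real_, PWSn = NA_real_,
                             FSS_dyncm2 = flow_fss_profile(flow, theta = theta))
      prov$slices[[i]] <- list(slice_id = sl0$slice_id, Q = flow$Q, G = flow$G)
    } else {
      target <- abs(polygon_area(sl0$contours$lumen))
      if (isTRUE(variant$circ_shrink)) {
        # find_circ_shrink takes the imaged slice; the axial-stretch wall-area
        # scaling is part of its volume-conservation bookkeeping
        key <- sprintf("%s_%d_%.6f", vessel$patient_id, sl0$slice_id, lz)
        if (!is.null(shrink_cache) && exists(key, envir = shrink_cache)) {
          sr <- get(key, envir = shrink_cache)
        } else {
          sr <- find_circ_shrink(sl0, study$materials, vessel$imaging_pressure,
                                 tol = study$shrink_tol, h = study$h,
                                 axial_stretch = lz)
          if (!is.null(shrink_cache)) assign(key, sr, envir = shrink_cache)
        }
      } else {
        sr <- .shrink_result(1, lz, sl0, build_mesh(sl0, study$h), 0L,
                             NA_real_, NULL, target,
                             polygon_centroid(sl0$contours$lumen), NULL, NULL)
      }
      if (variant$flow == "coupled") {
        prof <- coupled_fss(sl0, study$materials, p_mmHg, sr,
                            flow_cfg = study$flow, n = study$n_points)
      } else {
        cfg <- solve_config(p_mmHg, "mmHg", axial_stretch = lz,
                            load_steps = study$load_steps,
                            variant = if (lz == 1) "plane_strain_2d" else "thin_layer")
        sol <- solve_static(sr$shrunk_mesh, study$materials, cfg,
                            init = sr$solution)
        prof <- sample_lumen(sol, study$n_points, align = "material")
      }
      prov$slices[[i]] <- list(slice_id = sl0$slice_id,
                               circ_shrink_ratio = sr$circ_shrink_ratio,
                               shrink_iterations = sr$iterations,
                               area_error = sr$achieved_area_error)
    }
    rows[[i]] <- dplyr::mutate(tibble::as_tibble(prof),
                               patient_id = vessel$patient_id,
                               slice_id = sl0$slice_id,
                               variant = variant$name, .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "provenance") <- prov
  out
}

#' Pointwise comparison statistics between two lumen profiles
#'
#' For aligned per-point values of models p and q:
#' `delta_i = |p_i - q_i|`, `mean_delta = sum(delta)/n`,
#' `mean_base = sum(p)/n`, `relative_error = mean_delta/mean_base * 100`.
#' Model p is the base of the relative error.
#'
#' @param profile_p,profile_q `lumen_profile` tibbles for the same slice
#'   (aligned points), or bare numeric vectors.
#' @param quantity `"PWS"`, `"PWSn"` or `"FSS"` (ignored for vectors).
#' @return Object of class `delta_stats`: list with `delta`, `mean_delta`,
#'   `mean_base`, `relative_error`, `n`, `quantity`.
#' @examples
#' pointwise_delta(c(1, 2, 3), c(2, 3, 4))$relative_error  # 50
#' @export
pointwise_delta <- function(profile_p, profile_q, quantity = "PWS") {
  col <- switch(quantity, PWS = "PWS_kPa", PWSn = "PWSn", FSS = "FSS_dyncm2",
                quantity)
  p <- if (is.data.frame(profile_p)) profile_p[[col]] else as.numeric(profile_p)
  q <- if (is.data.frame(profile_q)) profile_q[[col]] else as.numeric(profile_q)
  if (length(p) != length(q))
    stop("profiles have different numbers of points (", length(p), " vs ",
         length(q), ")")
  if (is.data.frame(profile_p) && is.data.frame(profile_q) &&
      !is.null(profile_p$point_index) && !is.null(profile_q$point_index) &&
      any(profile_p$point_index != profile_q$point_index))
    stop("profiles are misaligned: point indices differ")
  delta <- abs(p - q)
  mean_delta <- mean(delta)
  mean_base <- mean(p)
  structure(list(delta = delta, mean_delta = mean_delta,
                 mean_base = mean_base,
                 relative_error = mean_delta / mean_base * 100,
                 n = length(p), quantity = quantity),
            class = "delta_stats")
}

#' @export
print.delta_stats <- function(x, ...) {
  cat(sprintf("<delta_stats> %s over %d points: MeanDelta = %.4g, MeanBase = %.4g, RelErr = %.2f%%\n",
              x$quantity, x$n, x$mean_delta, x$mean_base, x$relative_error))
  invisible(x)
}

#' @export
tidy.delta_stats <- function(x, ...) {
  tibble::tibble(quantity = x$quantity, n = x$n, mean_delta = x$mean_delta,
                 mean_base = x$mean_base, relative_error = x$relative_error)
}

# pooled delta stats over a set of aligned rows (already joined p/q values)
.pooled_stats <- function(vp, vq) {
  keep <- is.finite(vp) & is.finite(vq)
  vp <- vp[keep]; vq <- vq[keep]
  tibble::tibble(n = length(vp), mean_delta = mean(abs(vp - vq)),
                 mean_base = mean(vp),
                 relative_error = mean(abs(vp - vq)) / mean(vp) * 100)
}

#' Cohort-level model comparison report
#'
#' Runs every model variant needed by `pairs` on every vessel and computes
#' the pointwise comparison statistics at slice, patient and cohort level.
#' For pairs involving the flow-only model the compared quantities are the
#' per-slice FSS summaries (Max-, Min-, Ave-FSS, the per-slice values acting
#' as the pooled samples); otherwise PWS and PWSn are compared pointwise
#' over the 100 lumen points. The first variant of each pair is the base of
#' the relative error.
#'
#' @param cohort list of [vessel_spec()] objects (e.g. [generate_cohort()]).
#' @param pairs list of length-2 character vectors `c(base, other)`.
#' @param study a [study_config()].
#' @param profiles optional precomputed named list of variant profile
#'   tibbles (from [run_variant()], row-bound over vessels); computed when
#'   missing.
#' @return Object of class `cohort_report`: list with tibbles `per_slice`,
#'   `per_patient`, `cohort`, the raw `profiles`, and `provenance`.
#' @export
cohort_report <- function(cohort,
                          pairs = list(c("M1", "M2"), c("FSI", "M1"),
                                       c("FSI", "M5"), c("FSI", "M7")),
                          study = study_config(), profiles = NULL) {
  if (inherits(cohort, "vessel_spec")) cohort <- list(cohort)
  if (!length(cohort)) stop("empty cohort")
  variants <- unique(unlist(pairs))
  if (is.null(profiles)) {
    shrink_cache <- new.env(parent = emptyenv())
    profiles <- lapply(stats::setNames(variants, variants), function(v) {
      dplyr::bind_rows(lapply(cohort, run_variant, variant = v, study = study,
                              shrink_cache = shrink_cache))
    })
  }
  stopifnot(all(variants %in% names(profiles)))

  per_slice <- list(); per_patient <- list(); cohort_rows <- list()
  for (pr in pairs) {
    base <- pr[1]; other <- pr[2]
    pb <- profiles[[base]]; po <- profiles[[other]]
    joined <- dplyr::inner_join(
      pb, po, by = c("patient_id", "slice_id", "point_index"),
      suffix = c("_p", "_q"))
    flow_pair <- all(is.na(pb$PWS_kPa)) || all(is.na(po$PWS_kPa))
    if (flow_pair) {
      # per-slice FSS summaries become the compared samples
      summ <- function(df) {
        dplyr::summarise(dplyr::group_by(df, patient_id, slice_id),
                         `Max-FSS` = max(FSS_dyncm2),
                         `Min-FSS` = min(FSS_dyncm2),
                         `Ave-FSS` = mean(FSS_dyncm2), .groups = "drop")
      }
      sj <- dplyr::inner_join(summ(pb), summ(po),
                              by = c("patient_id", "slice_id"),
                              suffix = c("_p", "_q"))
      for (qt in c("Max-FSS", "Min-FSS", "Ave-FSS")) {
        vp <- sj[[paste0(qt, "_p")]]; vq <- sj[[paste0(qt, "_q")]]
        per_slice[[length(per_slice) + 1]] <- dplyr::mutate(
          dplyr::bind_cols(sj[c("patient_id", "slice_id")],
                           tibble::tibble(mean_delta = abs(vp - vq),
                                          mean_base = vp,
                                          relative_error = abs(vp - vq) / vp * 100,
                                          n = 1L)),
          pair = paste0(base, ":", other), quantity = qt, .before = 1)
        pp <- dplyr::group_modify(
          dplyr::group_by(sj, patient_id),
          ~ .pooled_stats(.x[[paste0(qt, "_p")]], .x[[paste0(qt, "_q")]]))
        per_patient[[length(per_patient) + 1]] <- dplyr::mutate(
          dplyr::ungroup(pp),
          pair = paste0(base, ":", other), quantity = qt, .before = 1)
        cohort_rows[[length(cohort_rows) + 1]] <- dplyr::mutate(
          .pooled_stats(vp, vq),
          pair = paste0(base, ":", other), quantity = qt, .before = 1)
      }
    } else {
      for (qt in c("PWS", "PWSn")) {
        col <- if (qt == "PWS") "PWS_kPa" else "PWSn"
        vp <- joined[[paste0(col, "_p")]]; vq <- joined[[paste0(col, "_q")]]
        ps <- dplyr::group_modify(
          dplyr::group_by(joined, patient_id, slice_id),
          ~ .pooled_stats(.x[[paste0(col, "_p")]], .x[[paste0(col, "_q")]]))
        per_slice[[length(per_slice) + 1]] <- dplyr::mutate(
          dplyr::ungroup(ps),
          pair = paste0(base, ":", other), quantity = qt, .before = 1)
        pp <- dplyr::group_modify(
          dplyr::group_by(joined, patient_id),
          ~ .pooled_stats(.x[[paste0(col, "_p")]], .x[[paste0(col, "_q")]]))
        per_patient[[length(per_patient) + 1]] <- dplyr::mutate(
          dplyr::ungroup(pp),
          pair = paste0(base, ":", other), quantity = qt, .before = 1)
        cohort_rows[[length(cohort_rows) + 1]] <- dplyr::mutate(
          .pooled_stats(vp, vq),
          pair = paste0(base, ":", other), quantity = qt, .before = 1)
      }
    }
  }
  per_patient <- dplyr::bind_rows(per_patient)
  # flag extreme per-patient errors per pair/quantity (table bold convention)
  per_patient <- dplyr::mutate(
    dplyr::group_by(per_patient, pair, quantity),
    is_max_error = relative_error == max(relative_error),
    is_min_error = relative_error == min(relative_error))
  per_patient <- dplyr::ungroup(per_patient)
  structure(list(per_slice = dplyr::bind_rows(per_slice),
                 per_patient = per_patient,
                 cohort = dplyr::bind_rows(cohort_rows),
                 profiles = profiles,
                 provenance = list(
                   pairs = pairs,
                   pressure_phase = study$pressure_phase,
                   h_mm = study$h, n_points = study$n_points,
                   flow = unclass(study$flow),
                   surrogate = "fully-developed",
                   materials = lapply(study$materials, unclass))),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> cohort-level relative errors (base listed first):\n")
  d <- dplyr::mutate(x$cohort, relative_error = sprintf("%.2f%%", relative_error))
  print(as.data.frame(d[, c("pair", "quantity", "n", "mean_base",
                            "mean_delta", "relative_error")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.cohort_report <- function(x, level = c("cohort", "patient", "slice"), ...) {
  level <- match.arg(level)
  switch(level, cohort = x$cohort, patient = x$per_patient,
         slice = x$per_slice)
}

#' @export
glance.cohort_report <- function(x, ...) {
  tibble::tibble(n_pairs = length(x$provenance$pairs),
                 n_patients = length(unique(x$per_patient$patient_id)),
                 n_slices = length(unique(paste(x$per_slice$patient_id,
                                                x$per_slice$slice_id))),
                 pressure_phase = x$provenance$pressure_phase)
}
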