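# Component-fitted meshing of segmented cross-sections. Contours from IVUS
# segmentation are star-shaped about the lumen centroid, so the wall annulus
# is meshed on a structured polar grid whose radial lines pass through every
# region interface: inclusion boundaries are grid surfaces, the angular grid
# snaps to inclusion arc ends, and each cell lies in exactly one region.
# Quads are split into quadratic (6-node) triangles.

# Both ray-polygon intersections (inner and outer crossing) for a band-shaped
# inclusion; NA if the ray misses the polygon.
.ray_band <- function(poly, center, theta) {
  poly <- as.matrix(poly)
  ax <- poly[, 1] - center[1]; ay <- poly[, 2] - center[2]
  bx <- c(ax[-1], ax[1]);      by <- c(ay[-1], ay[1])
  ex <- bx - ax; ey <- by - ay
  dx <- cos(theta); dy <- sin(theta)
  den <- dx * ey - dy * ex
  ok <- abs(den) > 1e-14
  s <- (ax * dy - ay * dx) / den
  t <- if (abs(dx) > abs(dy)) (ax + s * ex) / dx else (ay + s * ey) / dy
  cand <- t[ok & s >= -1e-9 & s <= 1 + 1e-9 & t > 0]
  if (length(cand) < 2) return(c(NA_real_, NA_real_))
  c(min(cand), max(cand))
}

# Angular window [lo, hi] (may wrap) covered by an inclusion polygon, about
# `center`. Uses the circular mean as the window's anchor.
.angular_window <- function(poly, center) {
  phi <- atan2(poly[, 2] - center[2], poly[, 1] - center[1])
  mu <- atan2(mean(sin(phi)), mean(cos(phi)))
  off <- wrap_angle(phi - mu)
  c(mu + min(off), mu + max(off))
}

.in_window <- function(theta, win) {
  w <- wrap_angle(theta - (win[1] + win[2]) / 2)
  abs(w) <= (win[2] - win[1]) / 2 + 1e-9
}

#' Mesh a segmented slice into a component-fitted triangulation
#'
#' Builds a conforming mesh of 6-node quadratic triangles over the wall
#' annulus between the lumen and outer contours. Lipid and calcification
#' polygons are honored as mesh interfaces: their radial boundaries and
#' angular arc ends coincide with grid lines, so every element carries a
#' single region label (`wall`, `lipid` or `calc`) and meshed region areas
#' match the polygon areas closely.
#'
#' @param slice a `slice_contours` object (see [generate_slice()]).
#' @param h target element size, mm.
#' @return Object of class `mesh2d`: list with `nodes` (N x 2, mm), `tri`
#'   (E x 6 node indices; corners 1-3 CCW, midsides 4-6 opposite the usual
#'   order: 4 on edge 1-2, 5 on 2-3, 6 on 3-1), `region` (length E character),
#'   `lumen_loop` / `outer_loop` (ordered CCW node indices along the
#'   boundaries, corners and midsides interleaved), `lumen_edges` /
#'   `outer_edges` (B x 3: end, end, midside), `center`, `h`, `n_theta`.
#' @examples
#' m <- build_mesh(generate_slice(slice_spec(seed = 1)), h = 0.25)
#' table(m$region)
#' @export
build_mesh <- function(slice, h) {
  stopifnot(inherits(slice, "slice_contours"), h > 0)
  L <- slice$contours$lumen
  O <- slice$contours$outer
  if (is.null(L) || is.null(O)) stop("slice must contain lumen and outer contours")
  center <- polygon_centroid(L)
  if (!all(points_in_polygon(matrix(center, 1), L)))
    stop("lumen centroid falls outside the lumen; contour too irregular to mesh")

  per <- polygon_arclength(L); per <- per[length(per)]
  n_theta <- max(24L, min(512L, as.integer(round(per / h))))
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta

  incl <- slice$contours[intersect(c("lipid", "calc"), names(slice$contours))]
  wins <- lapply(incl, .angular_window, center = center)
  # snap grid angles to each inclusion's arc ends: one line at the angular
  # extreme and one where the band still has (near-)full thickness, so the
  # end-edge sliver is resolved by dedicated cells
  snap_targets <- c()
  for (nm in names(incl)) {
    w <- wins[[nm]]
    fine <- seq(w[1], w[2], length.out = 257)
    bands <- vapply(fine, function(t1) .ray_band(incl[[nm]], center, t1),
                    numeric(2))
    width <- bands[2, ] - bands[1, ]
    width[is.na(width)] <- 0
    full <- which(width >= 0.9 * max(width))
    snap_targets <- c(snap_targets, w[1], fine[min(full)],
                      fine[max(full)], w[2])
  }
  # drop only (near-)coincident snap targets, then snap each to the nearest
  # unused grid angle; arc-end lines may legitimately sit close together
  gap0 <- 2 * pi / n_theta
  kept <- c()
  for (ang in snap_targets) {
    if (!length(kept) || all(abs(wrap_angle(kept - ang)) > 0.02 * gap0))
      kept <- c(kept, ang)
  }
  used <- integer(0)
  for (ang in kept) {
    d <- abs(wrap_angle(theta - ang))
    d[used] <- Inf
    j <- which.min(d)
    theta[j] <- ang %% (2 * pi)
    used <- c(used, j)
  }
  snapped <- seq_along(theta) %in% used
  ordt <- order(theta); theta <- theta[ordt]; snapped <- snapped[ordt]
  # remove sliver gaps: plain grid lines crowding a snapped interface line
  # are dropped below a tenth of the nominal step; pairs of snapped lines
  # (legitimately close arc-end features) are merged only when degenerate
  repeat {
    gaps <- wrap_angle(c(theta[-1], theta[1] + 2 * pi) - theta) %% (2 * pi)
    jn_of <- function(j) if (j == length(theta)) 1L else j + 1L
    bad <- which(vapply(seq_along(theta), function(j) {
      thr <- if (snapped[j] && snapped[jn_of(j)]) 0.02 else 0.1
      gaps[j] < thr * gap0
    }, logical(1)))
    if (!length(bad)) break
    j <- bad[1]; jn <- jn_of(j)
    drop <- if (snapped[j] && !snapped[jn]) jn else j
    theta <- theta[-drop]; snapped <- snapped[-drop]
  }
  n_theta <- length(theta)

  rho_l <- radial_profile(L, center, theta)
  rho_o <- radial_profile(O, center, theta)
  thick <- rho_o - rho_l
  if (any(thick <= 0)) stop("outer contour does not enclose the lumen on every ray")

  # per-angle band fractions a(theta) < b(theta); inclusion boundaries inside
  # their windows, smooth filler elsewhere
  a <- rep(0.35, n_theta); b <- rep(0.65, n_theta)
  inwin <- rep(FALSE, n_theta)
  reg_of_angle <- rep("wall", n_theta)
  for (nm in names(incl)) {
    w <- wins[[nm]]
    sel <- which(.in_window(theta, w))
    got <- logical(length(sel))
    for (si in seq_along(sel)) {
      j <- sel[si]
      band <- .ray_band(incl[[nm]], center, theta[j])
      if (any(is.na(band))) next
      a[j] <- (band[1] - rho_l[j]) / thick[j]
      b[j] <- (band[2] - rho_l[j]) / thick[j]
      got[si] <- TRUE
    }
    # a ray exactly at the angular extreme can graze the polygon and miss;
    # borrow the nearest resolved band inside the window
    if (any(got) && any(!got)) {
      wc <- (w[1] + w[2]) / 2
      off <- wrap_angle(theta[sel] - wc)
      for (si in which(!got)) {
        near <- which(got)[which.min(abs(off[which(got)] - off[si]))]
        a[sel[si]] <- a[sel[near]]
        b[sel[si]] <- b[sel[near]]
      }
    }
    inwin[sel] <- inwin[sel] | any(got)
    reg_of_angle[sel] <- nm
  }
  a <- pmin(pmax(a, 0.02), 0.96); b <- pmin(pmax(b, a + 0.02), 0.98)
  # relax filler fractions toward window values to limit cell skew
  if (any(inwin) && any(!inwin)) {
    for (pass in 1:3) {
      prev <- c(n_theta, seq_len(n_theta - 1)); nxt <- c(seq_len(n_theta - 1) + 1, 1)
      free <- !inwin
      a[free] <- (a[prev][free] + 2 * a[free] + a[nxt][free]) / 4
      b[free] <- (b[prev][free] + 2 * b[free] + b[nxt][free]) / 4
    }
  }

  t1 <- mean((a * thick)); t2 <- mean(((b - a) * thick)); t3 <- mean(((1 - b) * thick))
  n1 <- max(1L, as.integer(round(t1 / h)))
  n2 <- max(1L, as.integer(round(t2 / h)))
  n3 <- max(1L, as.integer(round(t3 / h)))
  n_r <- n1 + n2 + n3

  # corner nodes: index (j, i), j angular (periodic), i radial 1..n_r+1
  frac <- function(j) {
    c(seq(0, a[j], length.out = n1 + 1),
      seq(a[j], b[j], length.out = n2 + 1)[-1],
      seq(b[j], 1, length.out = n3 + 1)[-1])
  }
  nid <- function(j, i) (j - 1L) * (n_r + 1L) + i
  nodes <- matrix(0, n_theta * (n_r + 1L), 2)
  for (j in seq_len(n_theta)) {
    r <- rho_l[j] + frac(j) * thick[j]
    nodes[nid(j, seq_len(n_r + 1L)), ] <- cbind(center[1] + r * cos(theta[j]),
                                                center[2] + r * sin(theta[j]))
  }

  # quads -> 2 CCW triangles; region from radial band + angular window
  ntri <- 2L * n_theta * n_r
  tri <- matrix(0L, ntri, 3)
  region <- character(ntri)
  k <- 0L
  for (j in seq_len(n_theta)) {
    jp <- if (j == n_theta) 1L else j + 1L
    th_mid <- theta[j] + wrap_angle(theta[jp] - theta[j]) / 2
    for (i in seq_len(n_r)) {
      A <- nid(j, i); B <- nid(jp, i); C <- nid(jp, i + 1L); D <- nid(j, i + 1L)
      rg <- "wall"
      if (i > n1 && i <= n1 + n2) {
        for (nm in names(incl)) {
          if (.in_window(th_mid, wins[[nm]])) { rg <- nm; break }
        }
      }
      tri[k + 1L, ] <- c(A, C, B); region[k + 1L] <- rg
      tri[k + 2L, ] <- c(A, D, C); region[k + 2L] <- rg
      k <- k + 2L
    }
  }

  # quadratic midside nodes on every unique undirected edge
  e_all <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  uk <- !duplicated(key)
  edge_ids <- match(key, key[uk])
  mids <- (nodes[e_all[uk, 1], , drop = FALSE] + nodes[e_all[uk, 2], , drop = FALSE]) / 2
  mid_node <- nrow(nodes) + seq_len(nrow(mids))
  nodes <- rbind(nodes, mids)
  tri6 <- cbind(tri, matrix(mid_node[edge_ids], ncol = 3))

  # boundary loops (corner + midside interleaved), CCW
  lum_corners <- nid(seq_len(n_theta), 1L)
  out_corners <- nid(seq_len(n_theta), n_r + 1L)
  loop_of <- function(corners) {
    nxt <- c(corners[-1], corners[1])
    ek <- paste(pmin(corners, nxt), pmax(corners, nxt))
    mid <- mid_node[match(ek, key[uk])]
    list(loop = as.integer(rbind(corners, mid)),
         edges = cbind(corners, nxt, mid))
  }
  lum <- loop_of(lum_corners)
  out <- loop_of(out_corners)

  structure(list(nodes = nodes, tri = tri6, region = region,
                 lumen_loop = lum$loop, outer_loop = out$loop,
                 lumen_edges = lum$edges, outer_edges = out$edges,
                 center = center, h = h, n_theta = n_theta, n_r = n_r),
            class = "mesh2d")
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("<mesh2d> %d nodes, %d quadratic triangles (h = %.3f mm): %s\n",
              nrow(x$nodes), nrow(x$tri), x$h,
              paste(sprintf("%s=%d", names(table(x$region)), table(x$region)),
                    collapse = ", ")))
  invisible(x)
}

#' Element areas and per-region area totals of a mesh
#'
#' Areas from the corner (straight-sided) triangle geometry.
#'
#' @param mesh a [build_mesh()] result.
#' @return Named numeric vector of region areas (mm^2).
#' @export
mesh_region_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  ar <- ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
  tapply(ar, mesh$region, sum)
}

# Linear (3-node) disc mesh of a star-shaped polygon interior, for the
# cross-sectional flow solve: a central fan plus structured rings.
build_disc_mesh <- function(poly, h) {
  poly <- as.matrix(poly)
  center <- polygon_centroid(poly)
  per <- polygon_arclength(poly); per <- per[length(per)]
  n_theta <- max(24L, min(512L, as.integer(round(per / h))))
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rho <- radial_profile(poly, center, theta)
  n_r <- max(3L, as.integer(round(mean(rho) / h)))
  # nodes: center (id 1), then rings i = 1..n_r at radius i/n_r * rho
  nid <- function(j, i) 1L + (i - 1L) * n_theta + j
  nodes <- matrix(0, 1L + n_r * n_theta, 2)
  nodes[1, ] <- center
  for (i in seq_len(n_r)) {
    r <- rho * i / n_r
    nodes[nid(seq_len(n_theta), i), ] <- cbind(center[1] + r * cos(theta),
                                               center[2] + r * sin(theta))
  }
  tris <- vector("list", n_r)
  jp <- c(seq_len(n_theta - 1L) + 1L, 1L)
  tris[[1]] <- cbind(1L, nid(seq_len(n_theta), 1L), nid(jp, 1L))
  for (i in seq_len(n_r - 1L)) {
    A <- nid(seq_len(n_theta), i); B <- nid(jp, i)
    C <- nid(jp, i + 1L); D <- nid(seq_len(n_theta), i + 1L)
    tris[[i + 1L]] <- rbind(cbind(A, C, B), cbind(A, D, C))
  }
  tri <- do.call(rbind, tris)
  boundary <- nid(seq_len(n_theta), n_r)
  list(nodes = nodes, tri = tri, boundary = boundary, center = center,
       n_theta = n_theta, n_r = n_r, h = h)
}
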