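# Internal helpers.

# Evaluate expr with a private RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards. Keeps generation deterministic without
# clobbering the user's stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Radial distance from `center` to a star-shaped polygon boundary along the
# directions `thetas` (radians, CCW from +x). Smallest positive ray-edge
# intersection per direction.
radial_profile <- function(poly, center, thetas) {
  poly <- as.matrix(poly)
  ax <- poly[, 1] - center[1]; ay <- poly[, 2] - center[2]
  bx <- c(ax[-1], ax[1]);      by <- c(ay[-1], ay[1])
  ex <- bx - ax; ey <- by - ay
  vapply(thetas, function(th) {
    dx <- cos(th); dy <- sin(th)
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-14
    # ray: t*d = a + s*e, 0 <= s <= 1, t > 0
    s <- (ax * dy - ay * dx) / den
    t <- if (abs(dx) > abs(dy)) (ax + s * ex) / dx else (ay + s * ey) / dy
    cand <- t[ok & s >= -1e-12 & s <= 1 + 1e-12 & t > 0]
    if (!length(cand)) stop("polygon is not star-shaped about the given center")
    min(cand)
  }, numeric(1))
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a <= -pi, a + 2 * pi, a)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
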