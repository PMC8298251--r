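# Shared fixtures and independent oracles. Expensive objects (nonlinear FEM
# solves, the synthetic cohort study) are computed once per run and cached.

.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# thick-walled circular benchmark section: inner radius 1.5 mm, outer 3 mm
ring_slice <- function() {
  generate_slice(slice_spec(lumen_radius = 1.5, lumen_eccentricity = 0,
                            wall_thickness = 1.5, lipid_arc = 0,
                            noise_amplitude = 0, n_points = 128, seed = 1))
}

wall_only <- function() list(wall = material_params("vessel"))

plaque_materials <- function() {
  list(wall = material_params("vessel"), lipid = material_params("lipid"),
       calc = material_params("calcification"))
}

ring_solution_100mmHg <- function() {
  fixture("ring_sol_100", {
    solve_static(build_mesh(ring_slice(), 0.12), wall_only(),
                 solve_config(100, "mmHg"))
  })
}

# ---- independent 1D radial-equilibrium oracle -------------------------------
# Incompressible plane-strain inflation of a thick-walled ring:
# r^2 = ri^2 + R^2 - Ri^2, lambda_theta = r/R, sigma_theta - sigma_r =
# lambda W'(lambda), dsigma_r/dr = (sigma_theta - sigma_r)/r. The energy is
# written out here independently of the package implementation.
ring_ode_oracle <- function(mat, p_kPa, Ri = 1.5, Ro = 3.0, R_query = 2.25) {
  W_of <- function(l) {
    I1 <- l^2 + l^-2 + 1
    w <- mat$c1 * (I1 - 3) + mat$c2 * (I1 - 3) +
      mat$D1 * (exp(mat$D2 * (I1 - 3)) - 1)
    fib <- ifelse(rep(isTRUE(mat$anisotropic), length(l)) & l^2 > 1,
                  (mat$K1 / mat$K2) * (exp(mat$K2 * (l^2 - 1)^2) - 1), 0)
    w + fib
  }
  W_p <- function(l) (W_of(l + 1e-6) - W_of(l - 1e-6)) / 2e-6
  simpson <- function(f, a, b, n = 2000) {
    x <- seq(a, b, length.out = n + 1); y <- f(x)
    h <- (b - a) / n
    h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) +
               2 * sum(y[seq(3, n - 1, 2)]))
  }
  igr <- function(r, ri) {
    R <- sqrt(r^2 - ri^2 + Ri^2); lt <- r / R
    lt * W_p(lt) / r
  }
  p_of <- function(ri) simpson(function(r) igr(r, ri), ri,
                               sqrt(Ro^2 - Ri^2 + ri^2))
  ri <- stats::uniroot(function(x) p_of(x) - p_kPa, c(Ri + 1e-4, Ri + 1.2),
                       tol = 1e-10)$root
  r_q <- sqrt(R_query^2 - Ri^2 + ri^2)
  s_r <- -p_kPa + simpson(function(r) igr(r, ri), ri, r_q)
  lt <- r_q / R_query
  list(ri = ri, lumen_area = pi * ri^2, sigma_r = s_r,
       sigma_theta = s_r + lt * W_p(lt), r_query = r_q)
}

# mean hoop Cauchy stress of elements near reference radius R0; the band is
# widened until it holds at least one radial ring of elements
fem_hoop_at <- function(sol, R0, halfwidth = 0.06) {
  m <- sol$mesh
  ce <- (m$nodes[m$tri[, 1], ] + m$nodes[m$tri[, 2], ] +
           m$nodes[m$tri[, 3], ]) / 3
  r0 <- sqrt(rowSums(ce^2))
  sel <- abs(r0 - R0) < halfwidth
  while (sum(sel) < 8 && halfwidth < 1) {
    halfwidth <- halfwidth * 1.5
    sel <- abs(r0 - R0) < halfwidth
  }
  ef <- sol$element_fields
  th <- atan2(ce[sel, 2], ce[sel, 1]); tx <- -sin(th); ty <- cos(th)
  mean(tx^2 * ef[sel, "s11"] + 2 * tx * ty * ef[sel, "s12"] +
         ty^2 * ef[sel, "s22"])
}

circle_poly <- function(R = 1.5, n = 256) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(R * cos(th), R * sin(th))
}

rotate_slice <- function(slice, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  slice$contours <- lapply(slice$contours, function(p) p %*% t(R))
  slice
}

# the synthetic cohort study shared by the directional acceptance checks
cohort_study <- function() {
  fixture("cohort_report", {
    cohort <- generate_cohort(7, base_seed = 42)
    cohort_report(cohort, study = study_config(load_steps = 4))
  })
}

cohort_relerr <- function(rep, pair, quantity) {
  ce <- rep$cohort
  ce$relative_error[ce$pair == pair & ce$quantity == quantity]
}
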