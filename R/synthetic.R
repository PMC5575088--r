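#' Analytic tube (vessel phantom) surface
#'
#' Open cylinder wall (no end caps) with its axis along +z, centred on the
#' physical origin, triangulated as an axial-by-circumferential quad lattice
#' split into triangles with outward-facing winding.
#'
#' @param radius Tube radius, mm (> 0).
#' @param length Tube length, mm (> 0).
#' @param axial_segments Number of vertex rings along the axis (>= 3).
#' @param circumferential_segments Vertices per ring (>= 3).
#' @return A [tri_surface()] with
#'   `axial_segments * circumferential_segments` vertices.
#' @export
make_tube_surface <- function(radius, length, axial_segments = 40,
                              circumferential_segments = 48) {
  if (!is.finite(radius) || radius <= 0) stop_af("`radius` must be > 0 (got %g)", radius)
  if (!is.finite(length) || length <= 0) stop_af("`length` must be > 0 (got %g)", length)
  if (axial_segments < 3 || circumferential_segments < 3)
    stop_af("segment counts must be >= 3")
  na <- as.integer(axial_segments); nc <- as.integer(circumferential_segments)
  z <- seq(-length / 2, length / 2, length.out = na)
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  verts <- cbind(radius * rep(cos(th), times = na),
                 radius * rep(sin(th), times = na),
                 rep(z, each = nc))
  vid <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  i <- rep(seq_len(na - 1L), each = nc)
  j <- rep(seq_len(nc), times = na - 1L)
  f1 <- cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j))
  f2 <- cbind(vid(i, j + 1L), vid(i + 1L, j + 1L), vid(i + 1L, j))
  tri_surface(verts, rbind(f1, f2))
}

#' Synthetic ground truth descriptor
#'
#' Carries the closed-form quantities a generated field is known to realise,
#' so downstream estimators can be tested against analytic truth.
#'
#' @param field_kind One of "poiseuille", "swirl", "eccentric_jet".
#' @param parameters Named list of generator parameters.
#' @param closed_form_sfd Secondary flow degree (dimensionless), or NULL.
#' @param closed_form_wss Wall shear stress, Pa, or NULL.
#' @param rotation_per_length Streamline rotation, degrees per mm, or NULL.
#' @export
synthetic_truth <- function(field_kind, parameters, closed_form_sfd = NULL,
                            closed_form_wss = NULL, rotation_per_length = NULL) {
  field_kind <- match.arg(field_kind, c("poiseuille", "swirl", "eccentric_jet"))
  structure(list(field_kind = field_kind, parameters = parameters,
                 closed_form_sfd = closed_form_sfd,
                 closed_form_wss = closed_form_wss,
                 rotation_per_length = rotation_per_length),
            class = "synthetic_truth")
}

# radial distance from the z axis, per voxel, plus lumen membership
lumen_geometry_ <- function(grid, radius) {
  ext <- grid_extent(grid)
  if (-radius < ext[1, 1] || radius > ext[2, 1] ||
      -radius < ext[1, 2] || radius > ext[2, 2])
    stop_af("lumen of radius %g mm is clipped by the grid extent", radius)
  ax <- grid_axes(grid)
  n <- grid$shape
  x2 <- matrix(ax[[1]]^2, n[1], n[2])
  y2 <- matrix(ax[[2]]^2, n[1], n[2], byrow = TRUE)
  r2_slice <- x2 + y2
  r2 <- array(r2_slice, dim = n)
  list(r2 = r2, lumen = r2 < radius^2)   # strict: voxel centre inside
}

#' Poiseuille (parabolic) pipe-flow phantom
#'
#' Fully developed laminar flow in a straight tube of radius `radius` along
#' +z: axial velocity `v_peak * (1 - r^2/R^2)` inside the lumen, zero
#' outside, no in-plane components. The truth carries the analytic wall
#' shear stress `2 * eta * v_peak / R` and a secondary flow degree of 0.
#'
#' @param grid A [grid_spec()]; the lumen must fit inside its extent.
#' @param radius Lumen radius, mm.
#' @param v_peak Centreline velocity, m/s.
#' @param eta Dynamic viscosity used for the truth WSS, Pa.s.
#' @return A list with `field` ([velocity_field()]) and `truth`
#'   ([synthetic_truth()]).
#' @export
make_poiseuille_field <- function(grid, radius, v_peak, eta = ETA_BLOOD) {
  lg <- lumen_geometry_(grid, radius)
  vz <- ifelse(lg$lumen, v_peak * (1 - lg$r2 / radius^2), 0)
  zero <- array(0, dim = grid$shape)
  field <- velocity_field(grid, zero, zero, array(vz, grid$shape), lumen = lg$lumen)
  truth <- synthetic_truth("poiseuille",
                           list(radius_mm = radius, v_peak = v_peak, eta = eta),
                           closed_form_sfd = 0,
                           closed_form_wss = 2 * eta * v_peak / (radius / 1000))
  list(field = field, truth = truth)
}

#' Plug flow with solid-body swirl phantom
#'
#' Uniform axial velocity `v_axial` plus solid-body rotation
#' `v_theta = omega * r` inside the lumen. The disk average of `|v_theta|`
#' is `(2/3) * omega * R`, so the truth secondary flow degree is
#' `2 * omega * R / (3 * v_axial)`; streamlines are helices turning at
#' `omega / v_axial` radians per metre of axial travel.
#'
#' @inheritParams make_poiseuille_field
#' @param v_axial Axial plug velocity, m/s (> 0).
#' @param omega Angular rate of the solid-body rotation, rad/s.
#' @export
make_swirl_field <- function(grid, radius, v_axial, omega) {
  if (v_axial <= 0) stop_af("`v_axial` must be > 0 (got %g)", v_axial)
  lg <- lumen_geometry_(grid, radius)
  ax <- grid_axes(grid)
  n <- grid$shape
  X <- array(rep(ax[[1]], times = n[2] * n[3]), n)
  Y <- array(rep(rep(ax[[2]], each = n[1]), times = n[3]), n)
  # v_theta = omega * r with r in metres: v = omega * (x,y)/1000 rotated 90deg
  vx <- ifelse(lg$lumen, -omega * Y / 1000, 0)
  vy <- ifelse(lg$lumen, omega * X / 1000, 0)
  vz <- ifelse(lg$lumen, v_axial, 0)
  field <- velocity_field(grid, vx, vy, vz, lumen = lg$lumen)
  R_m <- radius / 1000
  truth <- synthetic_truth("swirl",
                           list(radius_mm = radius, v_axial = v_axial, omega = omega),
                           closed_form_sfd = 2 * omega * R_m / (3 * v_axial),
                           rotation_per_length = (omega / v_axial) * (180 / pi) / 1000)
  list(field = field, truth = truth)
}

# area of the intersection of two disks: radii R and r, centre distance d
disk_overlap_area_ <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(pi * min(R, r)^2)
  r2 <- r^2; R2 <- R^2
  a1 <- r2 * acos((d^2 + r2 - R2) / (2 * d * r))
  a2 <- R2 * acos((d^2 + R2 - r2) / (2 * d * R))
  a3 <- 0.5 * sqrt(pmax(0, (-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R)))
  a1 + a2 - a3
}

#' Eccentric high-velocity jet phantom
#'
#' Through-plane velocity `v_jet` inside an off-centre circular sub-disk
#' (centre at `jet_offset_frac * R` along +x, radius `jet_radius_frac * R`,
#' clipped to the lumen) and `v_background` elsewhere in the lumen — the
#' synthetic realisation of systolic jets hugging the vessel wall. The truth
#' records the analytic jet area fraction (lens formula when the sub-disk
#' protrudes past the wall) and the jet centroid offset as a fraction of R.
#'
#' @inheritParams make_poiseuille_field
#' @param jet_offset_frac Jet-centre offset from the axis, fraction of R
#'   (0 <= frac < 1).
#' @param jet_radius_frac Jet radius, fraction of R (0 < frac <= 1).
#' @param v_jet,v_background Through-plane velocities, m/s.
#' @export
make_eccentric_jet_field <- function(grid, radius, jet_offset_frac, jet_radius_frac,
                                     v_jet, v_background = 0.2 * v_jet) {
  if (jet_offset_frac < 0 || jet_offset_frac >= 1)
    stop_af("`jet_offset_frac` must lie in [0, 1); the jet centre must be inside the lumen")
  if (jet_radius_frac <= 0 || jet_radius_frac > 1)
    stop_af("`jet_radius_frac` must lie in (0, 1]")
  if (v_jet <= v_background)
    stop_af("`v_jet` must exceed `v_background`")
  lg <- lumen_geometry_(grid, radius)
  ax <- grid_axes(grid)
  n <- grid$shape
  cx <- jet_offset_frac * radius
  x2j <- matrix((ax[[1]] - cx)^2, n[1], n[2])
  y2 <- matrix(ax[[2]]^2, n[1], n[2], byrow = TRUE)
  jet_slice <- (x2j + y2) < (jet_radius_frac * radius)^2
  jet <- array(jet_slice, n) & lg$lumen
  vz <- ifelse(lg$lumen, ifelse(jet, v_jet, v_background), 0)
  zero <- array(0, dim = grid$shape)
  field <- velocity_field(grid, zero, zero, vz, lumen = lg$lumen)
  a_jet <- disk_overlap_area_(radius, jet_radius_frac * radius, cx)
  a_f <- a_jet / (pi * radius^2)
  # jet centroid offset (fraction of R) by fine polar quadrature of the
  # clipped region — closed form exists but is unwieldy
  e <- if (cx == 0) 0 else {
    g <- seq(-radius, radius, length.out = 801)
    xx <- outer(g, rep(1, length(g))); yy <- t(xx)
    inl <- xx^2 + yy^2 < radius^2
    inj <- (xx - cx)^2 + yy^2 < (jet_radius_frac * radius)^2
    mean(xx[inl & inj]) / radius
  }
  truth <- synthetic_truth("eccentric_jet",
    list(radius_mm = radius, jet_offset_frac = jet_offset_frac,
         jet_radius_frac = jet_radius_frac, v_jet = v_jet,
         v_background = v_background,
         hv_area_fraction = a_f, hv_centroid_offset = e),
    closed_form_sfd = 0)
  list(field = field, truth = truth)
}

#' Add velocity-encoding measurement noise
#'
#' Perturbs every lumen voxel of every component with independent zero-mean
#' Gaussian noise of standard deviation `sigma` — a simplification of
#' phase-contrast velocity noise (additive Gaussian per component, no Rician
#' magnitude noise). Reproducible under a fixed seed; voxels outside the
#' lumen stay exactly zero when the field carries a lumen mask.
#'
#' @param field A [velocity_field()].
#' @param sigma Noise standard deviation, m/s (>= 0).
#' @param seed Integer seed (mandatory; generators hold no global state).
#' @export
add_velocity_noise <- function(field, sigma, seed) {
  if (sigma < 0) stop_af("`sigma` must be >= 0")
  if (sigma == 0) return(field)
  mask <- if (!is.null(field$lumen)) field$lumen else array(TRUE, field$grid$shape)
  nm <- sum(mask)
  withr::with_seed(as.integer(seed), {
    for (comp in c("vx", "vy", "vz"))
      field[[comp]][mask] <- field[[comp]][mask] + stats::rnorm(nm, 0, sigma)
  })
  field
}

#' Synthetic paired predicted/observed cohort
#'
#' Draws per-subject observed values uniformly on `x_range` and sets
#' `predicted = slope * observed + bias + N(0, noise_sd)` — the statistical
#' structure the paired validation protocol assumes (paired samples, a
#' near-unity linear relation, Gaussian scatter).
#'
#' @param n Number of subjects (>= 2).
#' @param slope Linear coefficient relating predicted to observed.
#' @param bias Additive offset, metric units.
#' @param noise_sd Gaussian noise SD, metric units (>= 0).
#' @param x_range Length-2 range of the observed values.
#' @param seed Integer seed.
#' @param metric_name,units Labels carried on the cohort.
#' @return A `paired_cohort` tibble with columns `subject_id`, `predicted`,
#'   `observed`.
#' @export
make_paired_cohort <- function(n, slope = 1, bias = 0, noise_sd = 0,
                               x_range = c(0, 1), seed = 1,
                               metric_name = "metric", units = "") {
  if (n < 2) stop_af("`n` must be >= 2")
  if (noise_sd < 0) stop_af("`noise_sd` must be >= 0")
  withr::with_seed(as.integer(seed), {
    x <- stats::runif(n, x_range[1], x_range[2])
    y <- slope * x + bias + stats::rnorm(n, 0, noise_sd)
  })
  paired_cohort(tibble(subject_id = paste0("S", seq_len(n)),
                       predicted = y, observed = x),
                metric_name = metric_name, units = units)
}
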