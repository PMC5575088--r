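#' Peak velocity magnitude over a lumen region
#'
#' Maximum of `sqrt(vx^2 + vy^2 + vz^2)` over the masked voxels — the
#' peak-systolic velocity across the valve when the mask covers the valve
#' region.
#'
#' @param field A [velocity_field()].
#' @param mask Logical array over the grid; defaults to the field's lumen
#'   mask when present.
#' @return Peak speed, m/s.
#' @export
peak_velocity <- function(field, mask = NULL) {
  if (is.null(mask)) mask <- field$lumen
  if (is.null(mask)) mask <- array(TRUE, field$grid$shape)
  if (!any(mask)) stop_af("peak_velocity: empty mask")
  sp <- speed_volume(field)
  max(sp[mask])
}

#' Secondary flow degree of a cross-section
#'
#' The ratio of the plane-averaged in-plane velocity magnitude to the
#' plane-averaged through-plane velocity magnitude. Magnitudes are averaged
#' (not vector components, which would cancel symmetric swirl to zero).
#' Purely axial flow gives 0; values above ~2.5 are beyond what is seen even
#' in severe aortic disease and are flagged as suspect by the pipeline.
#'
#' @param section A [cross_section()] carrying velocities.
#' @return Dimensionless SFD.
#' @export
secondary_flow_degree <- function(section) {
  sm <- section$samples
  keep <- sm$lumen
  if (!any(keep)) stop_af("secondary_flow_degree: empty lumen mask")
  if (!"v_through" %in% names(sm)) stop_af("section carries no velocities")
  v_th <- mean(abs(sm$v_through[keep]))
  if (v_th == 0) stop_af("secondary_flow_degree: zero mean through-plane velocity")
  v_in <- mean(sqrt(sm$v_in1[keep]^2 + sm$v_in2[keep]^2))
  v_in / v_th
}

#' Hagen-Poiseuille wall shear stress
#'
#' Idealised WSS of fully developed laminar pipe flow,
#' `eta * 4 * v_mean / r_mean`, with the dynamic viscosity of blood
#' (3.5e-3 Pa.s) as default. Insensitive to secondary flow by construction.
#'
#' @param v_mean Mean forward through-plane velocity, m/s (>= 0).
#' @param r_mean Mean lumen radius, m (> 0).
#' @param eta Dynamic viscosity, Pa.s.
#' @return WSS, Pa.
#' @export
wss_hagen_poiseuille <- function(v_mean, r_mean, eta = ETA_BLOOD) {
  if (r_mean <= 0) stop_af("`r_mean` must be > 0 (got %g)", r_mean)
  if (v_mean < 0) stop_af("`v_mean` must be >= 0 (got %g)", v_mean)
  eta * 4 * v_mean / r_mean
}

#' Surface-averaged wall shear stress from near-wall velocity gradients
#'
#' For every wall face, samples the velocity at the face centroid offset
#' inward by `probe_depth` and `2 * probe_depth`, takes the wall-tangential
#' speed at each, and forms the one-sided second-order wall gradient
#' `(4 v_t(d) - v_t(2d)) / (2d)` — the full three-point stencil with the
#' wall sample dropped, because no-slip holds on the wall mesh and voxels at
#' or beyond the wall carry no usable signal in measured data. Exact for a
#' parabolic profile under true no-slip. The face
#' WSS is `eta` times that gradient (clamped at zero); `wss_sa` is the
#' area-weighted mean. The inward direction is the face normal flipped
#' towards the mesh's principal axis, which is valid for tubular walls.
#'
#' @param field A [velocity_field()].
#' @param wall A [tri_surface()] lying inside the field's grid.
#' @param eta Dynamic viscosity, Pa.s.
#' @param probe_depth Inward probe distance, mm.
#' @return An object of class `wss_result`: `wss_sa` (Pa), `eta`,
#'   `wall_samples`, `n_excluded`, and `per_face` values (Pa) for mapping.
#' @export
wss_surface_averaged <- function(field, wall, eta = ETA_BLOOD, probe_depth = 1) {
  fg <- face_geometry(wall)
  nfc <- nrow(fg$centroids)
  # inward = towards the local principal-axis projection of the centroid
  ctr <- colMeans(wall$vertices)
  vc <- sweep(wall$vertices, 2, ctr)
  axis_dir <- svd(vc, nu = 0, nv = 1)$v[, 1]
  rel <- sweep(fg$centroids, 2, ctr)
  axial <- rel %*% axis_dir
  radial <- rel - axial %*% t(axis_dir)
  flip <- rowSums(fg$normals * radial) > 0
  n_in <- fg$normals
  n_in[flip, ] <- -n_in[flip, ]
  p1 <- fg$centroids + probe_depth * n_in
  p2 <- fg$centroids + 2 * probe_depth * n_in
  ok <- points_in_grid(field$grid, fg$centroids) &
    points_in_grid(field$grid, p1) & points_in_grid(field$grid, p2)
  if (mean(!ok) > 0.2)
    stop_af("wss_surface_averaged: %.0f%% of wall probes leave the grid",
            100 * mean(!ok))
  tangential_speed <- function(p, nin) {
    v <- interp_velocity(field, p)
    vn <- rowSums(v * nin)
    sqrt(pmax(0, rowSums(v^2) - vn^2))
  }
  vt1 <- tangential_speed(p1[ok, , drop = FALSE], n_in[ok, , drop = FALSE])
  vt2 <- tangential_speed(p2[ok, , drop = FALSE], n_in[ok, , drop = FALSE])
  grad <- (4 * vt1 - vt2) / (2 * probe_depth / 1000)   # 1/s, depth mm -> m
  per_face <- rep(NA_real_, nfc)
  per_face[ok] <- eta * pmax(0, grad)
  wss_sa <- sum(per_face[ok] * fg$areas[ok]) / sum(fg$areas[ok])
  structure(list(wss_sa = wss_sa, eta = eta,
                 wall_samples = sum(ok), n_excluded = sum(!ok),
                 probe_depth = probe_depth, per_face = per_face),
            class = "wss_result")
}

#' @export
print.wss_result <- function(x, ...) {
  cat(sprintf("<wss_result> WSS_SA = %.4g Pa over %d faces (%d excluded), eta = %g Pa.s\n",
              x$wss_sa, x$wall_samples, x$n_excluded, x$eta))
  invisible(x)
}

#' @export
tidy.wss_result <- function(x, ...) {
  tibble(wss_sa = x$wss_sa, eta = x$eta, wall_samples = x$wall_samples,
         n_excluded = x$n_excluded)
}

#' Streamline rotation angle about a centerline
#'
#' Seeds massless particles on a circle in the entry section and advects
#' them through the steady field with fixed-spatial-step 4th-order
#' Runge-Kutta integration of the normalised velocity direction. For each
#' streamline the signed azimuthal angle about the local centerline is
#' accumulated (unwrapped); the result is the median absolute total rotation
#' over the seeds that traverse the full segment. The median resists
#' occasional outlier streamlines.
#'
#' @param field A [velocity_field()].
#' @param cl A [centerline()] spanning the segment of interest.
#' @param seed_radius Radius of the seeding circle, mm (typically R/2).
#' @param n_seeds Number of seeds.
#' @param step Integration step, mm; default half the smallest voxel pitch.
#' @param max_steps Safety cap on integration steps.
#' @return Rotation in degrees. Errors if more than half the seeds leave the
#'   lumen before the end of the segment (with an exit census).
#' @export
rotation_angle <- function(field, cl, seed_radius, n_seeds = 12,
                           step = NULL, max_steps = 20000) {
  if (is.null(step)) step <- min(field$grid$spacing) / 2
  at0 <- centerline_at(cl, 0)
  basis <- plane_basis_(at0$tangent)
  s_end <- max(cl$arclength)
  th <- 2 * pi * (seq_len(n_seeds) - 1) / n_seeds
  totals <- rep(NA_real_, n_seeds)
  for (k in seq_len(n_seeds)) {
    p <- at0$point + seed_radius * (cos(th[k]) * basis$u + sin(th[k]) * basis$v)
    ang_prev <- NA_real_
    total <- 0
    completed <- FALSE
    dirfun <- function(x) {
      v <- interp_velocity(field, matrix(x, 1))
      sp <- sqrt(sum(v^2))
      if (sp < 1e-9) return(NULL)
      as.vector(v) / sp
    }
    for (it in seq_len(max_steps)) {
      # azimuth about the centerline at the current axial position
      s_here <- sum((p - at0$point) * at0$tangent)
      at <- centerline_at(cl, min(max(s_here, 0), s_end))
      b <- plane_basis_(at$tangent)
      relp <- p - at$point
      ang <- atan2(sum(relp * b$v), sum(relp * b$u))
      if (!is.na(ang_prev)) {
        d <- ang - ang_prev
        d <- (d + pi) %% (2 * pi) - pi
        total <- total + d
      }
      ang_prev <- ang
      if (s_here >= s_end - 1e-9) { completed <- TRUE; break }
      if (!points_in_grid(field$grid, matrix(p, 1))) break
      k1 <- dirfun(p); if (is.null(k1)) break
      k2 <- tryCatch(dirfun(p + step / 2 * k1), error = function(e) NULL)
      k3 <- if (!is.null(k2)) tryCatch(dirfun(p + step / 2 * k2), error = function(e) NULL) else NULL
      k4 <- if (!is.null(k3)) tryCatch(dirfun(p + step * k3), error = function(e) NULL) else NULL
      if (is.null(k2) || is.null(k3) || is.null(k4)) break
      p <- p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (completed) totals[k] <- abs(total) * 180 / pi
  }
  n_exit <- sum(is.na(totals))
  if (n_exit > n_seeds / 2)
    stop_af("rotation_angle: %d of %d seeds exited the lumen before the segment end",
            n_exit, n_seeds)
  stats::median(totals, na.rm = TRUE)
}

#' Grade a rotation angle into none / mild / marked
#'
#' Categorical grading of helical or vortical flow: `none` up to
#' `none_threshold` (default 90 degrees — a strictly zero threshold would
#' make `none` unattainable under measurement noise), `mild` for rotation
#' below one full turn, `marked` beyond 360 degrees.
#'
#' @param rotation_deg Non-negative rotation, degrees.
#' @param none_threshold Upper limit of the `none` grade, degrees.
#' @return Ordered factor with levels none < mild < marked.
#' @export
grade_rotation <- function(rotation_deg, none_threshold = 90) {
  if (any(rotation_deg < 0)) stop_af("`rotation_deg` must be >= 0")
  g <- ifelse(rotation_deg > 360, "marked",
              ifelse(rotation_deg > none_threshold, "mild", "none"))
  factor(g, levels = c("none", "mild", "marked"), ordered = TRUE)
}

#' Grade flow eccentricity of a cross-section
#'
#' The high-velocity (HV) region is the set of lumen samples with
#' through-plane velocity at or above `hv_threshold_frac` of the section
#' peak. Its lumen-area fraction `A_f` and centroid offset `e` (distance
#' between HV and lumen centroids, as a fraction of the equivalent radius)
#' quantify the qualitative thirds criterion: `marked` when the HV region is
#' small and rim-adjacent (`A_f < 1/3` and `e > 0.4`), `none` when it is
#' central (`e <= 0.2`), `mild` otherwise.
#'
#' @param section A [cross_section()] carrying velocities with positive mean
#'   forward flow.
#' @param hv_threshold_frac HV threshold as a fraction of the section peak
#'   (default 0.70).
#' @return A list: `grade` (ordered factor), `hv_area_fraction`,
#'   `hv_centroid_offset`.
#' @export
grade_eccentricity <- function(section, hv_threshold_frac = 0.70) {
  sm <- section$samples
  keep <- sm$lumen
  v <- sm$v_through[keep]
  if (mean(v) <= 0) stop_af("grade_eccentricity: non-positive mean forward flow")
  vmax <- max(v)
  hv <- v >= hv_threshold_frac * vmax
  if (!any(hv)) stop_af("grade_eccentricity: empty high-velocity region")
  a_f <- sum(hv) / sum(keep)
  la <- sm$a[keep]; lb <- sm$b[keep]
  lum_c <- c(mean(la), mean(lb))
  hv_c <- c(mean(la[hv]), mean(lb[hv]))
  e <- sqrt(sum((hv_c - lum_c)^2)) / section$r_mean
  grade <- if (a_f < 1 / 3 && e > 0.4) "marked" else if (e <= 0.2) "none" else "mild"
  list(grade = factor(grade, levels = c("none", "mild", "marked"), ordered = TRUE),
       hv_area_fraction = a_f, hv_centroid_offset = e)
}
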