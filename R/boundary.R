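#' Murray's-law outflow split
#'
#' Apportions a total flow rate among branch outlets by Murray's law,
#' `Q_i proportional to d_i^exponent` (exponent 3 by default). Fractions are
#' `d_i^3 / sum(d_j^3)` and absolute flows sum to `q_total` by construction,
#' so overall mass balance is honoured exactly.
#'
#' @param q_total Total outflow, mL/s (> 0).
#' @param diameters Named (or unnamed) vector of outlet diameters, mm,
#'   all > 0.
#' @param exponent Murray exponent (default 3).
#' @return An `outflow_split` tibble with columns `outlet_id`,
#'   `diameter_mm`, `fraction`, `q_ml_s`.
#' @export
murray_split <- function(q_total, diameters, exponent = 3) {
  if (!is.finite(q_total) || q_total <= 0) stop_af("`q_total` must be > 0")
  ids <- names(diameters)
  if (is.null(ids)) ids <- paste0("outlet", seq_along(diameters))
  bad <- which(!is.finite(diameters) | diameters <= 0)
  if (length(bad))
    stop_af("non-positive diameter for outlet '%s'", ids[bad[1]])
  w <- diameters^exponent
  frac <- w / sum(w)
  out <- tibble(outlet_id = ids, diameter_mm = as.numeric(diameters),
                fraction = as.numeric(frac), q_ml_s = as.numeric(frac * q_total))
  class(out) <- c("outflow_split", class(out))
  attr(out, "q_total") <- q_total
  attr(out, "exponent") <- exponent
  out
}

#' Map a measured velocity profile onto an inlet mesh
#'
#' Assigns each node of the inlet boundary mesh the trilinearly interpolated
#' three-component velocity from the field — the node-wise personalised
#' inlet profile used to drive downstream flow models. The volume flux is
#' the area-weighted sum of face-normal velocities (mm^2 x m/s = mL/s). The
#' inlet normal is taken to point into the domain; a negative flux raises a
#' warning (possible flipped normals), not an error.
#'
#' @param field A [velocity_field()].
#' @param inlet_mesh A [tri_surface()] section whose nodes lie inside the
#'   field grid.
#' @param flip_normals Flip the mesh face normals before computing flux.
#' @return An `inlet_profile` list: `node_positions` (mm),
#'   `node_velocities` (m/s), `flux` (mL/s).
#' @export
map_inlet_profile <- function(field, inlet_mesh, flip_normals = FALSE) {
  pts <- inlet_mesh$vertices
  inside <- points_in_grid(field$grid, pts)
  if (!all(inside))
    stop_af("map_inlet_profile: %d node(s) outside the field grid (first: node %d)",
            sum(!inside), which(!inside)[1])
  vel <- interp_velocity(field, pts)
  fg <- face_geometry(inlet_mesh)
  nrm <- if (flip_normals) -fg$normals else fg$normals
  f <- inlet_mesh$faces
  v_face <- (vel[f[, 1], , drop = FALSE] + vel[f[, 2], , drop = FALSE] +
             vel[f[, 3], , drop = FALSE]) / 3
  flux <- sum(fg$areas * rowSums(v_face * nrm))
  if (flux < 0)
    warn(sprintf("map_inlet_profile: negative flux (%.3g mL/s) - inlet normals may be flipped", flux))
  structure(list(node_positions = pts, node_velocities = vel, flux = flux),
            class = "inlet_profile")
}

#' @export
print.inlet_profile <- function(x, ...) {
  cat(sprintf("<inlet_profile> %d nodes, flux %.4g mL/s\n",
              nrow(x$node_positions), x$flux))
  invisible(x)
}

#' Triangulated disc mesh (inlet phantom)
#'
#' Fan/ring triangulation of a planar disc perpendicular to +z, used as a
#' synthetic inlet boundary mesh.
#'
#' @param radius Disc radius, mm.
#' @param n_rings Radial subdivisions.
#' @param n_theta Circumferential subdivisions.
#' @param z Axial position, mm.
#' @export
make_disc_mesh <- function(radius, n_rings = 8, n_theta = 24, z = 0) {
  verts <- matrix(c(0, 0, z), 1, 3)
  for (i in seq_len(n_rings)) {
    r <- radius * i / n_rings
    th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
    verts <- rbind(verts, cbind(r * cos(th), r * sin(th), z))
  }
  rid <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- NULL
  for (j in seq_len(n_theta))               # inner fan
    faces <- rbind(faces, c(1L, rid(1, j), rid(1, j + 1)))
  if (n_rings > 1) {
    for (i in seq_len(n_rings - 1)) for (j in seq_len(n_theta)) {
      faces <- rbind(faces,
                     c(rid(i, j), rid(i + 1, j), rid(i + 1, j + 1)),
                     c(rid(i, j), rid(i + 1, j + 1), rid(i, j + 1)))
    }
  }
  tri_surface(verts, faces)
}
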