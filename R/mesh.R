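#' Triangulated vessel-wall surface
#'
#' @param vertices n x 3 numeric matrix of vertex positions, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param regions Optional per-face region labels.
#' @return An object of class `tri_surface`. Zero-area faces are dropped at
#'   construction (load-time cleaning) with a message.
#' @export
tri_surface <- function(vertices, faces, regions = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop_af("`vertices` must be n x 3")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_af("face indices out of range [1, %d]", nrow(vertices))
  if (!is.null(regions) && length(regions) != nrow(faces))
    stop_af("`regions` must have one label per face")
  area <- face_areas_(vertices, faces)
  degen <- area <= 1e-12
  if (any(degen)) {
    message(sprintf("dropping %d degenerate (zero-area) face(s)", sum(degen)))
    faces <- faces[!degen, , drop = FALSE]
    if (!is.null(regions)) regions <- regions[!degen]
  }
  structure(list(vertices = vertices, faces = faces, regions = regions),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_corners_ <- function(vertices, faces) {
  list(a = vertices[faces[, 1], , drop = FALSE],
       b = vertices[faces[, 2], , drop = FALSE],
       c = vertices[faces[, 3], , drop = FALSE])
}

cross3_ <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

face_areas_ <- function(vertices, faces) {
  if (nrow(faces) == 0) return(numeric(0))
  fc <- face_corners_(vertices, faces)
  0.5 * sqrt(rowSums(cross3_(fc$b - fc$a, fc$c - fc$a)^2))
}

#' Per-face areas, centroids and unit normals
#' @param surface A [tri_surface()].
#' @return A list with `areas` (mm^2), `centroids` (m x 3, mm) and unit
#'   `normals` (m x 3, orientation from the vertex winding).
#' @export
face_geometry <- function(surface) {
  fc <- face_corners_(surface$vertices, surface$faces)
  cr <- cross3_(fc$b - fc$a, fc$c - fc$a)
  nrm <- sqrt(rowSums(cr^2))
  list(areas = nrm / 2,
       centroids = (fc$a + fc$b + fc$c) / 3,
       normals = cr / nrm)
}

#' Apply a rigid transform to a surface
#' @param surface A [tri_surface()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation, mm.
#' @export
transform_surface <- function(surface, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- surface$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  tri_surface(v, surface$faces, surface$regions)
}

# Closest point on a triangulated surface for each query point.
# Region-based point-to-triangle projection (barycentric clamping),
# vectorised over points within each face, with a centroid-radius lower
# bound to skip faces that cannot improve the running minimum.
closest_point_on_surface <- function(points, surface) {
  points <- rbind(points)
  n <- nrow(points)
  fc <- face_corners_(surface$vertices, surface$faces)
  nf <- nrow(surface$faces)
  E0 <- fc$b - fc$a
  E1 <- fc$c - fc$a
  fa <- rowSums(E0 * E0)
  fb <- rowSums(E0 * E1)
  fcc <- rowSums(E1 * E1)
  det <- pmax(fa * fcc - fb * fb, 1e-300)
  cen <- (fc$a + fc$b + fc$c) / 3
  rad <- sqrt(pmax(rowSums((fc$a - cen)^2),
                   rowSums((fc$b - cen)^2),
                   rowSums((fc$c - cen)^2)))
  best <- rep(Inf, n)
  best_pt <- matrix(NA_real_, n, 3)
  best_face <- integer(n)
  for (f in seq_len(nf)) {
    dc <- sqrt((points[, 1] - cen[f, 1])^2 +
               (points[, 2] - cen[f, 2])^2 +
               (points[, 3] - cen[f, 3])^2)
    act <- which(dc - rad[f] < best)
    if (!length(act)) next
    P <- points[act, , drop = FALSE]
    D <- matrix(fc$a[f, ], length(act), 3, byrow = TRUE) - P
    a <- fa[f]; b <- fb[f]; cc <- fcc[f]; dt <- det[f]
    d <- D %*% E0[f, ]; e <- D %*% E1[f, ]
    s <- b * e - cc * d
    t <- b * d - a * e
    inside <- s + t <= dt & s >= 0 & t >= 0
    s[inside] <- s[inside] / dt
    t[inside] <- t[inside] / dt
    out <- which(!inside)
    if (length(out)) {
      so <- numeric(length(out)); to <- numeric(length(out))
      di <- d[out]; ei <- e[out]; si <- s[out]; ti <- t[out]
      low <- si + ti <= dt
      for (ii in seq_along(out)) {
        if (low[ii]) {
          if (si[ii] < 0) {
            if (ti[ii] < 0) {            # region 4
              if (di[ii] < 0) { to[ii] <- 0; so[ii] <- min(1, max(0, -di[ii] / a)) }
              else { so[ii] <- 0; to[ii] <- min(1, max(0, -ei[ii] / cc)) }
            } else {                     # region 3
              so[ii] <- 0; to[ii] <- min(1, max(0, -ei[ii] / cc))
            }
          } else {                       # region 5 (ti < 0)
            to[ii] <- 0; so[ii] <- min(1, max(0, -di[ii] / a))
          }
        } else {
          if (si[ii] < 0) {              # region 2
            tmp0 <- b + di[ii]; tmp1 <- cc + ei[ii]
            if (tmp1 > tmp0) {
              so[ii] <- min(1, max(0, (tmp1 - tmp0) / (a - 2 * b + cc)))
              to[ii] <- 1 - so[ii]
            } else { so[ii] <- 0; to[ii] <- min(1, max(0, -ei[ii] / cc)) }
          } else if (ti[ii] < 0) {       # region 6
            tmp0 <- b + ei[ii]; tmp1 <- a + di[ii]
            if (tmp1 > tmp0) {
              to[ii] <- min(1, max(0, (tmp1 - tmp0) / (a - 2 * b + cc)))
              so[ii] <- 1 - to[ii]
            } else { to[ii] <- 0; so[ii] <- min(1, max(0, -di[ii] / a)) }
          } else {                       # region 1
            numer <- cc + ei[ii] - b - di[ii]
            so[ii] <- if (numer <= 0) 0 else min(1, numer / (a - 2 * b + cc))
            to[ii] <- 1 - so[ii]
          }
        }
      }
      s[out] <- so; t[out] <- to
    }
    cp <- matrix(fc$a[f, ], length(act), 3, byrow = TRUE) +
      as.vector(s) * matrix(E0[f, ], length(act), 3, byrow = TRUE) +
      as.vector(t) * matrix(E1[f, ], length(act), 3, byrow = TRUE)
    dd <- sqrt(rowSums((P - cp)^2))
    upd <- dd < best[act]
    if (any(upd)) {
      best[act[upd]] <- dd[upd]
      best_pt[act[upd], ] <- cp[upd, , drop = FALSE]
      best_face[act[upd]] <- f
    }
  }
  list(distance = best, point = best_pt, face = best_face)
}

#' Surface-to-surface distance (mean, SD, Hausdorff)
#'
#' Samples every vertex of one mesh and measures its point-to-triangle
#' distance to the other surface (point-to-surface, not point-to-point); in
#' symmetric mode both directions are pooled. The Hausdorff distance is the
#' maximum over all samples. Callers are expected to have restricted both
#' meshes to the common region of interest beforehand.
#'
#' @param a,b [tri_surface()] objects.
#' @param symmetric Pool distances from both directions (default TRUE).
#' @return An object of class `surface_distance_result` with fields
#'   `mean_distance`, `sd_distance`, `hausdorff` (all mm) and `n_samples`.
#' @export
surface_distance <- function(a, b, symmetric = TRUE) {
  if (nrow(a$vertices) == 0 || nrow(b$vertices) == 0)
    stop_af("surface_distance: empty surface")
  d_ab <- closest_point_on_surface(a$vertices, b)$distance
  d <- if (symmetric) c(d_ab, closest_point_on_surface(b$vertices, a)$distance) else d_ab
  structure(list(mean_distance = mean(d),
                 sd_distance = stats::sd(d),
                 hausdorff = max(d),
                 n_samples = length(d)),
            class = "surface_distance_result")
}

#' @export
print.surface_distance_result <- function(x, ...) {
  cat(sprintf("surface distance: %.3g +/- %.3g mm (Hausdorff %.3g mm, n = %d)\n",
              x$mean_distance, x$sd_distance, x$hausdorff, x$n_samples))
  invisible(x)
}

#' @export
tidy.surface_distance_result <- function(x, ...) {
  tibble(mean_distance = x$mean_distance, sd_distance = x$sd_distance,
         hausdorff = x$hausdorff, n_samples = x$n_samples)
}

# Rodrigues: rotation matrix from an axis-angle vector
rodrigues_ <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-15) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid iterative-closest-point surface alignment
#'
#' Refines a rigid (rotation + translation, no scaling) transform that
#' aligns `moving` onto `fixed` by point-to-plane ICP: each iteration pairs
#' a subsample of moving vertices with their closest points on the fixed
#' surface and solves the linearised least-squares problem for the error
#' projected on the local surface normals (tangential sliding on facets is
#' free, which avoids the under-rotation bias of point-to-point pairing).
#' Deterministic given its inputs. If the refined transform does not improve
#' the mean point-to-surface distance the identity is returned instead.
#'
#' @param moving,fixed [tri_surface()] objects with gross initial overlap.
#' @param max_iter Maximum ICP iterations.
#' @param tol Convergence tolerance on the change in mean distance, mm.
#' @param n_sample Number of moving vertices used for correspondences
#'   (evenly strided subsample; all vertices if fewer).
#' @return A list of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (mm), `mean_distance` (mm, after alignment), `n_iter`,
#'   `converged`.
#' @export
rigid_align <- function(moving, fixed, max_iter = 50, tol = 1e-4, n_sample = 500) {
  mv <- moving$vertices
  idx <- if (nrow(mv) > n_sample)
    unique(round(seq(1, nrow(mv), length.out = n_sample))) else seq_len(nrow(mv))
  pts0 <- mv[idx, , drop = FALSE]
  fnrm <- face_geometry(fixed)$normals
  R_tot <- diag(3); t_tot <- c(0, 0, 0)
  pts <- pts0
  cp <- closest_point_on_surface(pts, fixed)
  d0 <- mean(cp$distance)
  d_prev <- d0
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    nrm <- fnrm[cp$face, , drop = FALSE]
    # linearised point-to-plane: minimise sum(( n.(p + w x p + t - q) )^2)
    A <- cbind(cross3_(pts, nrm), nrm)
    b <- -rowSums(nrm * (pts - cp$point))
    # minimum-norm least squares: unobservable motions (e.g. axial sliding
    # of an open cylinder, whose normals are all perpendicular to the axis)
    # are left at zero rather than blowing up the solve
    sv <- svd(A)
    keep <- sv$d > max(sv$d) * 1e-10
    x <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
    Rk <- rodrigues_(x[1:3])
    tk <- x[4:6]
    pts <- sweep(pts %*% t(Rk), 2, tk, "+")
    R_tot <- Rk %*% R_tot
    t_tot <- as.vector(Rk %*% t_tot) + tk
    cp <- closest_point_on_surface(pts, fixed)
    d_now <- mean(cp$distance)
    if (abs(d_prev - d_now) < tol) { converged <- TRUE; d_prev <- d_now; break }
    d_prev <- d_now
  }
  if (!converged)
    warn(sprintf("rigid_align: not converged after %d iterations", it))
  d_final <- d_prev
  if (d_final > d0) {   # never worsen the pair
    R_tot <- diag(3); t_tot <- c(0, 0, 0); d_final <- d0
  }
  structure(list(rotation = R_tot, translation = t_tot,
                 mean_distance = d_final, n_iter = it, converged = converged),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation %.3g deg, translation (%s) mm, mean dist %.3g mm\n",
              rotation_angle_of(x$rotation),
              paste(signif(x$translation, 3), collapse = ", "), x$mean_distance))
  invisible(x)
}

#' Rotation angle (degrees) of a 3 x 3 rotation matrix
#' @param rotation 3 x 3 rotation matrix.
#' @export
rotation_angle_of <- function(rotation) {
  ct <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Rotation matrix about a coordinate axis
#' @param axis One of "x", "y", "z".
#' @param angle_deg Angle in degrees.
#' @export
rotation_about_axis <- function(axis = c("z", "x", "y"), angle_deg) {
  axis <- match.arg(axis)
  th <- angle_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  switch(axis,
    z = matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3, 3),
    x = matrix(c(1, 0, 0, 0, cs, sn, 0, -sn, cs), 3, 3),
    y = matrix(c(cs, 0, -sn, 0, 1, 0, sn, 0, cs), 3, 3))
}
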