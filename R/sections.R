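#' Vessel centerline
#'
#' An ordered polyline with unit tangents and cumulative arclength, used to
#' place measurement planes and to reference streamline rotation.
#'
#' @param points n x 3 matrix of polyline points, mm (n >= 2).
#' @return An object of class `centerline` with `points`, `tangents`
#'   (unit, central differences) and `arclength` (mm, strictly increasing).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop_af("centerline needs >= 2 points")
  seg <- diff(points)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen <= 0)) stop_af("centerline has coincident consecutive points")
  arclength <- c(0, cumsum(seglen))
  tang <- rbind(seg[1, , drop = FALSE],
                (points[-(1:2), , drop = FALSE] - points[seq_len(n - 2), , drop = FALSE]),
                seg[n - 1, , drop = FALSE])
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, tangents = tang, arclength = arclength),
            class = "centerline")
}

#' Straight centerline between two points
#' @param p0,p1 End points, mm.
#' @param n Number of polyline points.
#' @export
straight_centerline <- function(p0, p1, n = 21) {
  s <- seq(0, 1, length.out = n)
  centerline(cbind(p0[1] + s * (p1[1] - p0[1]),
                   p0[2] + s * (p1[2] - p0[2]),
                   p0[3] + s * (p1[3] - p0[3])))
}

# point and unit tangent at arclength s (linear interpolation)
centerline_at <- function(cl, s) {
  s <- min(max(s, cl$arclength[1]), cl$arclength[length(cl$arclength)])
  i <- findInterval(s, cl$arclength, rightmost.closed = TRUE)
  i <- min(i, nrow(cl$points) - 1L)
  w <- (s - cl$arclength[i]) / (cl$arclength[i + 1] - cl$arclength[i])
  p <- (1 - w) * cl$points[i, ] + w * cl$points[i + 1, ]
  tg <- (1 - w) * cl$tangents[i, ] + w * cl$tangents[i + 1, ]
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

# orthonormal in-plane basis (u, v) for a unit normal n
plane_basis_ <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(normal = n, u = u, v = v)
}

# Intersect a plane with a triangle mesh; returns closed loops as ordered
# lists of 3D points. Segment endpoints are keyed by the crossed mesh edge,
# so chaining is exact (no coordinate tolerance).
plane_mesh_loops_ <- function(surface, origin, normal) {
  n <- normal / sqrt(sum(normal^2))
  sd <- as.vector(sweep(surface$vertices, 2, origin, "-") %*% n)
  sd[sd == 0] <- 1e-12
  f <- surface$faces
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  crossed <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossed)) return(list())
  fidx <- which(crossed)
  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  pt_cache <- new.env(parent = emptyenv())
  edge_point <- function(i, j) {
    k <- edge_key(i, j)
    p <- pt_cache[[k]]
    if (is.null(p)) {
      w <- sd[i] / (sd[i] - sd[j])
      p <- (1 - w) * surface$vertices[i, ] + w * surface$vertices[j, ]
      pt_cache[[k]] <- p
    }
    p
  }
  # per crossed face: the two crossed edges
  segs <- vector("list", length(fidx))
  for (q in seq_along(fidx)) {
    tri <- f[fidx[q], ]
    s <- sd[tri]
    ee <- list(c(1, 2), c(2, 3), c(3, 1))
    keys <- character(0)
    for (e in ee) {
      if (s[e[1]] * s[e[2]] < 0)
        keys <- c(keys, edge_key(tri[e[1]], tri[e[2]]))
    }
    segs[[q]] <- keys
  }
  # adjacency: edge key -> neighbouring edge keys (via shared faces)
  adj <- new.env(parent = emptyenv())
  for (q in seq_along(segs)) {
    k <- segs[[q]]
    if (length(k) != 2) next
    adj[[k[1]]] <- c(adj[[k[1]]], k[2])
    adj[[k[2]]] <- c(adj[[k[2]]], k[1])
  }
  keys_all <- unique(unlist(segs))
  visited <- new.env(parent = emptyenv())
  loops <- list()
  for (k0 in keys_all) {
    if (!is.null(visited[[k0]])) next
    loop_keys <- character(0)
    k <- k0; prev <- ""
    repeat {
      visited[[k]] <- TRUE
      loop_keys <- c(loop_keys, k)
      nxt <- NA_character_
      for (cand in setdiff(adj[[k]], prev))
        if (is.null(visited[[cand]])) { nxt <- cand; break }
      if (is.na(nxt)) break
      prev <- k; k <- nxt
    }
    pts <- t(vapply(loop_keys, function(kk) {
      ij <- as.integer(strsplit(kk, "_")[[1]])
      edge_point(ij[1], ij[2])
    }, numeric(3)))
    loops[[length(loops) + 1]] <- pts
  }
  loops
}

# 2D point-in-polygon, vectorised over points (ray casting)
points_in_polygon_ <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

shoelace_area_ <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Extract an oriented lumen cross-section
#'
#' Intersects a plane with the vessel wall, requires a single closed contour,
#' lays a regular in-plane sample lattice over it, and (when a velocity field
#' is supplied) samples through-plane and in-plane velocity components by
#' trilinear interpolation. The lumen area is the (shoelace) area of the
#' intersection contour; `r_mean = sqrt(area / pi)` is the equivalent-circle
#' radius.
#'
#' @param surface A [tri_surface()] vessel wall.
#' @param origin Point on the section plane, mm.
#' @param normal Plane normal (through-plane direction).
#' @param field Optional [velocity_field()]; sample points outside its grid
#'   are an error, never zero.
#' @param sample_spacing In-plane lattice pitch, mm.
#' @return An object of class `cross_section`: plane frame (`origin`,
#'   `normal`, `u`, `v`), `samples` tibble (`a`, `b` in-plane mm, `lumen`,
#'   and when a field is given `v_through` m/s and `v_in1`, `v_in2`),
#'   `area` (mm^2), `r_mean` (mm), `contour` (2D polygon).
#' @export
extract_cross_section <- function(surface, origin, normal, field = NULL,
                                  sample_spacing = 0.5) {
  basis <- plane_basis_(normal)
  loops <- plane_mesh_loops_(surface, origin, basis$normal)
  if (length(loops) != 1L)
    stop_af("section plane intersects the surface in %d loop(s); expected exactly 1",
            length(loops))
  rel <- sweep(loops[[1]], 2, origin, "-")
  poly <- cbind(rel %*% basis$u, rel %*% basis$v)
  area <- shoelace_area_(poly)
  r_mean <- sqrt(area / pi)
  sp <- sample_spacing
  aseq <- seq(min(poly[, 1]) + sp / 2, max(poly[, 1]), by = sp)
  bseq <- seq(min(poly[, 2]) + sp / 2, max(poly[, 2]), by = sp)
  lat <- expand.grid(a = aseq, b = bseq, KEEP.OUT.ATTRS = FALSE)
  lumen <- points_in_polygon_(lat$a, lat$b, poly)
  samples <- tibble(a = lat$a, b = lat$b, lumen = lumen)
  if (!is.null(field)) {
    pts <- cbind(origin[1] + lat$a * basis$u[1] + lat$b * basis$v[1],
                 origin[2] + lat$a * basis$u[2] + lat$b * basis$v[2],
                 origin[3] + lat$a * basis$u[3] + lat$b * basis$v[3])[lumen, , drop = FALSE]
    vel <- interp_velocity(field, pts)
    samples$v_through <- NA_real_
    samples$v_in1 <- NA_real_
    samples$v_in2 <- NA_real_
    samples$v_through[lumen] <- vel %*% basis$normal
    samples$v_in1[lumen] <- vel %*% basis$u
    samples$v_in2[lumen] <- vel %*% basis$v
  }
  structure(list(origin = origin, normal = basis$normal,
                 u = basis$u, v = basis$v,
                 samples = samples, sample_spacing = sp,
                 area = area, r_mean = r_mean, contour = poly),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> area %.4g mm^2 (R_mean %.3g mm), %d/%d lumen samples%s\n",
              x$area, x$r_mean, sum(x$samples$lumen), nrow(x$samples),
              if ("v_through" %in% names(x$samples)) ", with velocities" else ""))
  invisible(x)
}

#' Mean through-plane (forward) velocity of a section, m/s
#' @param section A [cross_section()] carrying velocities.
#' @export
mean_through_velocity <- function(section) {
  v <- section$samples$v_through[section$samples$lumen]
  if (!length(v) || all(is.na(v))) stop_af("section carries no lumen velocities")
  mean(v)
}

#' Average equivalent-circle diameter along a centerline span
#'
#' Takes sections perpendicular to the local tangent every `step` mm over the
#' arclength `span` and averages their equivalent-circle diameters
#' `2 * sqrt(area / pi)`. The default `step` of 2 mm resolves millimetre-scale
#' cohort differences in ascending-aorta diameter.
#'
#' @param surface A [tri_surface()].
#' @param cl A [centerline()].
#' @param span Arclength interval `c(s0, s1)`, mm; default the full
#'   centerline.
#' @param step Section spacing, mm.
#' @return Mean diameter, mm. Errors identify the failing arclength if any
#'   section cannot be extracted.
#' @export
mean_vessel_diameter <- function(surface, cl, span = NULL, step = 2) {
  if (is.null(span)) span <- range(cl$arclength)
  if (span[1] < min(cl$arclength) - 1e-9 || span[2] > max(cl$arclength) + 1e-9)
    stop_af("span [%g, %g] outside centerline arclength [%g, %g]",
            span[1], span[2], min(cl$arclength), max(cl$arclength))
  ss <- seq(span[1], span[2], by = step)
  d <- vapply(ss, function(s) {
    at <- centerline_at(cl, s)
    sec <- tryCatch(extract_cross_section(surface, at$point, at$tangent),
                    error = function(e)
                      stop_af("section at arclength %.3g mm failed: %s", s,
                              conditionMessage(e)))
    2 * sec$r_mean
  }, numeric(1))
  mean(d)
}

#' Centerline as iterated section-area centroids
#'
#' Starting from a straight axis guess, extracts sections along the current
#' centerline and replaces its points by the 3D centroids of the lumen
#' contours, iterating twice. A lightweight refinement for near-tubular
#' vessels — not a general skeletonisation.
#'
#' @param surface A [tri_surface()].
#' @param axis_guess A [centerline()] (e.g. [straight_centerline()]).
#' @param step Section spacing, mm.
#' @param n_iter Refinement passes.
#' @export
centerline_from_surface <- function(surface, axis_guess, step = 4, n_iter = 2) {
  cl <- axis_guess
  for (k in seq_len(n_iter)) {
    ss <- seq(min(cl$arclength), max(cl$arclength), by = step)
    pts <- t(vapply(ss, function(s) {
      at <- centerline_at(cl, s)
      sec <- extract_cross_section(surface, at$point, at$tangent)
      ctr2 <- colMeans(sec$contour)
      at$point + ctr2[1] * sec$u + ctr2[2] * sec$v
    }, numeric(3)))
    cl <- centerline(pts)
  }
  cl
}
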