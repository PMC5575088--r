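#' Regular voxel grid specification
#'
#' Describes the sampling lattice of a voxel-based velocity field. Coordinates
#' are physical millimetres; `origin` is the physical position of the centre
#' of voxel (0,0,0) and voxel indices are 0-based.
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 2).
#' @param spacing Voxel edge length in mm; scalar or length-3 vector, all > 0.
#' @param origin Physical coordinate (mm) of the centre of voxel (0,0,0).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop_af("`shape` must be 3 integers, all >= 2")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_af("`spacing` must be positive and finite")
  if (is.null(origin)) {
    # centre the grid on the physical origin
    origin <- -(shape - 1L) * spacing / 2
  }
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# physical coordinates (mm) of all voxel centres, as three 3D arrays
grid_axes <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

# n x 3 matrix of voxel-centre coordinates for all voxels (x fastest)
grid_coords <- function(grid) {
  ax <- grid_axes(grid)
  n <- grid$shape
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

# physical bounding box of voxel centres, 2 x 3 (min; max)
grid_extent <- function(grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  rbind(lo, hi)
}

#' Voxel-based vector velocity field
#'
#' Container for a single-phase, three-component velocity field sampled on a
#' regular voxel grid — the digital stand-in for 4D velocity-encoded MRI or a
#' CFD export. Components are in m/s; the grid is in mm.
#'
#' @param grid A [grid_spec()].
#' @param vx,vy,vz 3D numeric arrays with dimensions `grid$shape`, m/s.
#' @param venc Optional velocity-encoding limit (m/s). When supplied, any
#'   component exceeding it in magnitude is rejected (aliasing screen).
#' @param lumen Optional logical array marking lumen voxels (used by the
#'   synthetic generators so that noise is confined to the lumen).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(grid, vx, vy, vz, venc = NULL, lumen = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  for (nm in c("vx", "vy", "vz")) {
    comp <- get(nm)
    if (!identical(dim(comp), as.integer(grid$shape)))
      stop_af("component `%s` has dims (%s); grid expects (%s)", nm,
              paste(dim(comp), collapse = ","), paste(grid$shape, collapse = ","))
    if (any(!is.finite(comp)))
      stop_af("component `%s` contains non-finite values", nm)
  }
  if (!is.null(venc)) {
    vmax <- max(abs(vx), abs(vy), abs(vz))
    if (vmax > venc)
      stop_af("aliasing screen: |velocity| max %.3g m/s exceeds venc %.3g m/s", vmax, venc)
  }
  if (!is.null(lumen)) stopifnot(identical(dim(lumen), as.integer(grid$shape)))
  structure(list(grid = grid, vx = vx, vy = vy, vz = vz,
                 venc = venc, lumen = lumen),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- speed_volume(x)
  cat(sprintf("<velocity_field> %s voxels, |v| in [%.3g, %.3g] m/s\n",
              paste(x$grid$shape, collapse = " x "), min(sp), max(sp)))
  invisible(x)
}

# speed magnitude volume, m/s
speed_volume <- function(field) {
  sqrt(field$vx^2 + field$vy^2 + field$vz^2)
}

#' Trilinear velocity interpolation at physical points
#'
#' Samples the three velocity components at arbitrary physical positions by
#' trilinear interpolation from the surrounding voxel centres. Points outside
#' the voxel-centre lattice are an error, never silently zero.
#'
#' @param field A [velocity_field()].
#' @param points n x 3 matrix of physical coordinates, mm.
#' @return n x 3 matrix of interpolated (vx, vy, vz), m/s.
#' @export
interp_velocity <- function(field, points) {
  points <- rbind(points)
  g <- field$grid
  f <- sweep(sweep(points, 2, g$origin, "-"), 2, g$spacing, "/")
  i0 <- floor(f)
  # clamp points sitting exactly on the upper boundary into the last cell
  hi <- matrix(g$shape - 1, nrow(points), 3, byrow = TRUE)
  on_hi <- i0 == hi & abs(f - hi) < 1e-9
  i0[on_hi] <- i0[on_hi] - 1
  bad <- i0 < 0 | (i0 + 1) > (hi)
  if (any(bad)) {
    idx <- which(rowSums(bad) > 0)
    stop_af("%d point(s) outside the voxel grid (first: %s mm)",
            length(idx), paste(signif(points[idx[1], ], 4), collapse = ", "))
  }
  t <- f - i0
  out <- matrix(0, nrow(points), 3)
  comps <- list(field$vx, field$vy, field$vz)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) t[, 1] else 1 - t[, 1]) *
         (if (dy) t[, 2] else 1 - t[, 2]) *
         (if (dz) t[, 3] else 1 - t[, 3])
    ind <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    for (c in 1:3) out[, c] <- out[, c] + w * comps[[c]][ind]
  }
  out
}

# TRUE where physical points lie within the voxel-centre lattice
points_in_grid <- function(grid, points) {
  points <- rbind(points)
  ext <- grid_extent(grid)
  ok <- rep(TRUE, nrow(points))
  for (a in 1:3) ok <- ok & points[, a] >= ext[1, a] - 1e-9 & points[, a] <= ext[2, a] + 1e-9
  ok
}
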