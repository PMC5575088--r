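# Shared phantom builders: modest sizes keep the default run fast.

# grid centred on the origin covering an R-mm lumen with margin, mm spacing
phantom_grid <- function(radius = 14, spacing = 1, z_half = 16, margin = 2) {
  half_xy <- ceiling((radius + margin) / spacing)
  nz <- 2 * ceiling(z_half / spacing) + 1
  grid_spec(c(2 * half_xy + 1, 2 * half_xy + 1, nz), spacing)
}

# tube with vertices exactly on an x-scaled ellipse (breaks the rotational
# symmetry that makes z-rotations unidentifiable for alignment tests)
elliptical_tube <- function(radius = 14, length = 60, ax = 25, circ = 40,
                            scale_x = 1.25) {
  tube <- make_tube_surface(radius, length, ax, circ)
  tri_surface(tube$vertices %*% diag(c(scale_x, 1, 1)), tube$faces)
}

# linearly tapering tube (radius r0 at -length/2 to r1 at +length/2)
tapered_tube <- function(r0, r1, length, ax = 25, circ = 40) {
  tube <- make_tube_surface(1, length, ax, circ)
  z <- tube$vertices[, 3]
  r <- r0 + (r1 - r0) * (z + length / 2) / length
  tri_surface(cbind(tube$vertices[, 1] * r, tube$vertices[, 2] * r, z),
              tube$faces)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
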