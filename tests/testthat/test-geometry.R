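test_that("cross-section of an analytic tube recovers lumen area and frame", {
  tube <- make_tube_surface(14, 30, 16, 96)
  sec <- extract_cross_section(tube, c(0, 0, 0), c(0, 0, 1))
  expect_rel_error(sec$area, pi * 14^2, 0.02)
  expect_equal(sec$r_mean, sqrt(sec$area / pi))
  expect_equal(sum(sec$normal * sec$u), 0, tolerance = 1e-9)
  expect_equal(sum(sec$normal * sec$v), 0, tolerance = 1e-9)
  expect_equal(sum(sec$u * sec$v), 0, tolerance = 1e-9)
  # plane missing the vessel entirely
  expect_error(extract_cross_section(tube, c(0, 0, 40), c(0, 0, 1)), "0 loop")
})

test_that("section velocities decompose into through- and in-plane parts", {
  g <- phantom_grid(14, 1)
  pz <- make_poiseuille_field(g, 14, 1)
  tube <- make_tube_surface(14, 30, 16, 48)
  sec <- extract_cross_section(tube, c(0, 0, 0), c(0, 0, 1), field = pz$field)
  lum <- sec$samples$lumen
  expect_true(all(abs(sec$samples$v_in1[lum]) < 1e-12))
  expect_true(all(abs(sec$samples$v_in2[lum]) < 1e-12))
  expect_true(all(is.na(sec$samples$v_through[!lum])))
  # plug flow through a 60-degree tilted plane: mean v_through = v cos(60);
  # the tilted ellipse spans +-R tan(60) ~ +-24 mm axially
  gl <- phantom_grid(14, 1, z_half = 27)
  plug <- make_swirl_field(gl, 14, v_axial = 1, omega = 0)
  long <- make_tube_surface(14, 54, 28, 48)
  nrm <- c(sin(pi / 3), 0, cos(pi / 3))
  sec2 <- extract_cross_section(long, c(0, 0, 0), nrm, field = plug$field)
  # rim samples blend wall zeros under trilinear interpolation (~3% low)
  expect_rel_error(mean_through_velocity(sec2), 0.5, 0.05)
})

test_that("mean vessel diameter resolves straight and tapering tubes", {
  tube <- make_tube_surface(14, 60, 31, 96)
  cl <- straight_centerline(c(0, 0, -25), c(0, 0, 25))
  expect_rel_error(mean_vessel_diameter(tube, cl, step = 2), 28, 0.01)
  # 28 -> 32 mm linear taper averages to ~30 mm
  tap <- tapered_tube(14, 16, 60, 31, 96)
  expect_rel_error(mean_vessel_diameter(tap, cl, step = 2), 30, 0.01)
  expect_error(mean_vessel_diameter(tube, cl, span = c(0, 100)), "arclength")
})

test_that("section equivalent diameter converges to 2R under refinement", {
  cl <- straight_centerline(c(0, 0, -5), c(0, 0, 5))
  err <- vapply(c(24, 48, 96), function(nc) {
    tube <- make_tube_surface(14, 20, 9, nc)
    abs(mean_vessel_diameter(tube, cl, step = 5) - 28) / 28
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 5e-4)
})

test_that("surface distances: identity, concentric tubes, lateral offset", {
  t14 <- make_tube_surface(14, 40, 21, 36)
  self <- surface_distance(t14, t14)
  expect_equal(self$mean_distance, 0)
  expect_equal(self$hausdorff, 0)
  t15 <- make_tube_surface(15, 40, 21, 36)
  conc <- surface_distance(t14, t15)
  expect_equal(conc$mean_distance, 1, tolerance = 0.01)
  expect_equal(conc$hausdorff, 1, tolerance = 0.05)
  expect_lte(conc$mean_distance, conc$hausdorff)
  # symmetric mode invariant under argument swap
  swap <- surface_distance(t15, t14)
  expect_equal(conc$mean_distance, swap$mean_distance)
  expect_equal(conc$hausdorff, swap$hausdorff)
  # lateral translation: hausdorff approaches the offset from below
  off <- transform_surface(t14, translation = c(3, 0, 0))
  d3 <- surface_distance(t14, off)
  expect_gt(d3$hausdorff, 2.9)
  expect_lte(d3$hausdorff, 3 + 1e-9)
  expect_error(surface_distance(tri_surface(matrix(0, 0, 3), matrix(0L, 0, 3)), t14),
               "empty")
})

test_that("point-to-triangle distance matches a dense barycentric oracle", {
  set.seed(5)
  tri <- tri_surface(matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 1), 3, 3, byrow = TRUE),
                     matrix(1:3, 1))
  # oracle: minimum distance to a dense barycentric sampling of the triangle
  wq <- seq(0, 1, length.out = 201)
  bc <- expand.grid(w1 = wq, w2 = wq)
  bc <- bc[bc$w1 + bc$w2 <= 1, ]
  cloud <- as.matrix(bc$w1 %*% t(c(2, 0, 0)) + bc$w2 %*% t(c(0, 3, 1)))
  pts <- matrix(rnorm(60, sd = 2), 20, 3)
  got <- aortaflow:::closest_point_on_surface(pts, tri)$distance
  oracle <- apply(pts, 1, function(p)
    min(sqrt(colSums((t(cloud) - p)^2))))
  expect_equal(got, oracle, tolerance = 1e-2)
  expect_true(all(got <= oracle + 1e-12))
})

test_that("rigid alignment recovers known transforms on an elliptical tube", {
  ell <- elliptical_tube()
  mov <- transform_surface(ell, rotation_about_axis("z", 5))
  tr <- rigid_align(mov, ell)
  expect_equal(rotation_angle_of(tr$rotation), 5, tolerance = 0.1)
  # pure lateral translation
  mov2 <- transform_surface(ell, translation = c(2, 0, 0))
  tr2 <- rigid_align(mov2, ell)
  expect_equal(tr2$translation[1], -2, tolerance = 0.05)
  expect_lt(rotation_angle_of(tr2$rotation), 0.1)
  # identity case
  tr3 <- rigid_align(ell, ell)
  expect_equal(tr3$rotation, diag(3), tolerance = 1e-9)
  expect_lt(sqrt(sum(tr3$translation^2)), 1e-6)
})

test_that("alignment never worsens the mean surface distance", {
  ell <- elliptical_tube(ax = 15, circ = 24)
  for (ang in c(2, 8)) {
    mov <- transform_surface(ell, rotation_about_axis("x", ang), c(1, 0.5, 0))
    before <- surface_distance(mov, ell)$mean_distance
    tr <- rigid_align(mov, ell)
    after <- surface_distance(
      transform_surface(mov, tr$rotation, tr$translation), ell)$mean_distance
    expect_lte(after, before + 1e-9)
  }
})

test_that("centerline refinement finds the axis of an offset tube", {
  tube <- transform_surface(make_tube_surface(10, 40, 21, 36),
                            translation = c(3, -2, 0))
  guess <- straight_centerline(c(0, 0, -15), c(0, 0, 15))
  cl <- centerline_from_surface(tube, guess, step = 5)
  expect_equal(mean(cl$points[, 1]), 3, tolerance = 0.05)
  expect_equal(mean(cl$points[, 2]), -2, tolerance = 0.05)
  expect_true(all(abs(sqrt(rowSums(cl$tangents^2)) - 1) < 1e-9))
  expect_true(all(diff(cl$arclength) > 0))
})
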