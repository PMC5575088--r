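test_that("tube surfaces are exact cylinders, built deterministically", {
  tube <- make_tube_surface(14, 80, 40, 48)
  expect_equal(nrow(tube$vertices), 40 * 48)
  r <- sqrt(rowSums(tube$vertices[, 1:2]^2))
  expect_equal(r, rep(14, nrow(tube$vertices)), tolerance = 1e-12)
  expect_equal(range(tube$vertices[, 3]), c(-40, 40))
  expect_identical(tube, make_tube_surface(14, 80, 40, 48))
  expect_error(make_tube_surface(-1, 80), "radius")
  expect_error(make_tube_surface(14, 0), "length")
})

test_that("Poiseuille phantom carries its closed-form truths", {
  g <- phantom_grid(14, 1)
  pz <- make_poiseuille_field(g, radius = 14, v_peak = 1)
  # truth WSS = 2 eta v_peak / R = 2 * 0.0035 * 1 / 0.014
  expect_equal(pz$truth$closed_form_wss, 0.5)
  expect_equal(pz$truth$closed_form_sfd, 0)
  # no in-plane velocity anywhere, zero outside lumen
  expect_true(all(pz$field$vx == 0) && all(pz$field$vy == 0))
  expect_true(all(pz$field$vz[!pz$field$lumen] == 0))
  # disk integral of the parabola: lumen mean = v_peak / 2 (the pixelated
  # rim biases the mean by ~1% at 1 mm voxels)
  expect_rel_error(mean(pz$field$vz[pz$field$lumen]), 0.5, 0.02)
  # centreline maximum
  expect_rel_error(peak_velocity(pz$field), 1, 0.01)
  # lumen clipped by grid is rejected
  expect_error(make_poiseuille_field(grid_spec(c(9, 9, 9), 1), 14, 1), "clipped")
})

test_that("swirl phantom: SFD and rotation truths; omega = 0 is plug flow", {
  g <- phantom_grid(14, 1)
  # omega R = 0.3 m/s, v_axial = 1 -> SFD truth (2/3) * 0.3 = 0.2
  sw <- make_swirl_field(g, 14, v_axial = 1, omega = 0.3 / 0.014)
  expect_equal(sw$truth$closed_form_sfd, 0.2)
  expect_equal(sw$truth$rotation_per_length,
               (0.3 / 0.014) * (180 / pi) / 1000)
  plug <- make_swirl_field(g, 14, v_axial = 1, omega = 0)
  expect_equal(plug$truth$closed_form_sfd, 0)
  expect_true(all(plug$field$vx == 0) && all(plug$field$vy == 0))
  expect_error(make_swirl_field(g, 14, v_axial = 0, omega = 1), "v_axial")
})

test_that("eccentric jet phantom realises each eccentricity grade", {
  g <- phantom_grid(14, 0.5, z_half = 2)
  tube <- make_tube_surface(14, 4, 5, 96)
  cases <- list(
    list(off = 0,    jr = 0.8,  grade = "none"),
    list(off = 0.35, jr = 0.65, grade = "mild"),
    list(off = 0.7,  jr = 0.4,  grade = "marked"))
  for (cs in cases) {
    jet <- make_eccentric_jet_field(g, 14, cs$off, cs$jr, v_jet = 2)
    sec <- extract_cross_section(tube, c(0, 0, 0), c(0, 0, 1),
                                 field = jet$field)
    got <- grade_eccentricity(sec)
    expect_equal(as.character(got$grade), cs$grade)
    expect_equal(got$hv_area_fraction,
                 jet$truth$parameters$hv_area_fraction, tolerance = 0.1)
    expect_equal(got$hv_centroid_offset,
                 jet$truth$parameters$hv_centroid_offset, tolerance = 0.05)
  }
  # fully interior jet: analytic area fraction is exactly jr^2
  jin <- make_eccentric_jet_field(g, 14, 0.2, 0.5, 2)
  expect_equal(jin$truth$parameters$hv_area_fraction, 0.25)
  # the rim-hugging case clips the sub-disk: lens area < jr^2
  jcl <- make_eccentric_jet_field(g, 14, 0.7, 0.4, 2)
  expect_lt(jcl$truth$parameters$hv_area_fraction, 0.16)
  expect_error(make_eccentric_jet_field(g, 14, 1.2, 0.2, 2), "jet centre")
})

test_that("velocity noise is seed-reproducible and lumen-confined", {
  g <- phantom_grid(10, 1, z_half = 5)
  pz <- make_poiseuille_field(g, 10, 1)
  expect_identical(add_velocity_noise(pz$field, 0, 1), pz$field)
  n1 <- add_velocity_noise(pz$field, 0.05, 42)
  n2 <- add_velocity_noise(pz$field, 0.05, 42)
  expect_identical(n1, n2)
  n3 <- add_velocity_noise(pz$field, 0.05, 43)
  expect_false(identical(n1, n3))
  expect_true(all(n1$vz[!pz$field$lumen] == 0))
})

test_that("noise-induced SFD bias matches the Rayleigh in-plane prediction", {
  # in-plane noise magnitude is Rayleigh(sigma), mean sigma * sqrt(pi/2);
  # lumen-mean through-plane velocity of the parabola is v_peak / 2
  g <- phantom_grid(14, 0.8, z_half = 2)
  pz <- make_poiseuille_field(g, 14, 1)
  tube <- make_tube_surface(14, 4, 5, 48)
  sigma <- 0.05
  predicted <- sigma * sqrt(pi / 2) * 2 / 1
  sfd <- vapply(1:20, function(s) {
    noisy <- add_velocity_noise(pz$field, sigma, s)
    sec <- extract_cross_section(tube, c(0, 0, 0), c(0, 0, 1), field = noisy,
                                 sample_spacing = 0.8)
    secondary_flow_degree(sec)
  }, numeric(1))
  expect_rel_error(mean(sfd), predicted, 0.10)
})

test_that("paired cohort generator is reproducible and recovers its parameters", {
  expect_identical(make_paired_cohort(20, seed = 7), make_paired_cohort(20, seed = 7))
  co <- make_paired_cohort(1000, slope = 1.05, bias = 0, noise_sd = 1e-4,
                           x_range = c(0.5, 1.5), seed = 11)
  expect_equal(regression_through_origin(co)$slope, 1.05, tolerance = 1e-2)
  # pure offset: Bland-Altman bias recovers it
  co2 <- make_paired_cohort(500, slope = 1, bias = 0.3, noise_sd = 0.1,
                            x_range = c(0.5, 1.5), seed = 12)
  expect_lt(abs(bland_altman(co2)$bias - 0.3), 0.02)
  # noiseless identity: paired t-test mean difference 0
  co3 <- make_paired_cohort(50, slope = 1, bias = 0, noise_sd = 0, seed = 13)
  expect_equal(paired_ttest(co3)$mean_diff, 0)
})
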