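test_that("circle fit recovers exact circles and flags collinear input", {
  for (r in c(1, 10, 25, 1000)) {
    fit <- fit_circle(arc_points(r, n = 20, theta = c(0.3, 2.5)))
    expect_false(fit$degenerate)
    expect_lt(abs(fit$kappa_mag - 1 / r), 1e-9)
  }
  deg <- fit_circle(cbind(1:3, 2 * (1:3) + 1))
  expect_true(deg$degenerate)
  expect_identical(deg$kappa_mag, 0)
  expect_identical(deg$radius, Inf)
})

test_that("circle fit on noisy arcs matches the grid-search oracle", {
  pts <- arc_points(25, n = 50, theta = c(0.4, 2.2), noise_sd = 0.2,
                    seed = 11)
  fit <- fit_circle(pts)
  expect_lt(abs(fit$kappa_mag - 0.04) / 0.04, 0.02)
  orc <- oracle_circle_fit(pts)
  expect_lt(abs(fit$radius - orc$radius) / orc$radius, 0.02)
  expect_lt(max(abs(fit$center - orc$center)), 0.5)
})

test_that("circle fit is scale covariant", {
  pts <- arc_points(12, n = 30, theta = c(0.2, 1.9), noise_sd = 0.05,
                    seed = 3)
  k1 <- fit_circle(pts)$kappa_mag
  for (lam in c(0.5, 2, 7.3)) {
    expect_equal(fit_circle(pts * lam)$kappa_mag, k1 / lam,
                 tolerance = 1e-12)
  }
})

test_that("spline curvature matches analytic arcs, lines and sinusoids", {
  th <- seq(0, pi, length.out = 150)
  arc <- contour(cbind(20 * cos(th), 20 * sin(th)), closed = FALSE)
  prof <- spline_curvature(arc)
  expect_equal(abs(curvature_arc_mean(prof)), 0.05, tolerance = 0.001 / 0.05)
  expect_true(all(diff(prof$s) > 0))

  line <- contour(cbind(seq(0, 50, length.out = 120), 0 * 1:120),
                  closed = FALSE)
  expect_lt(max(abs(spline_curvature(line)$kappa)), 1e-6)

  # sinusoid y = A sin(x / lambda): curvature at the crest is A / lambda^2
  A <- 2; lam <- 5
  x <- seq(0, 10 * pi * lam / (2 * pi), length.out = 600)
  sn <- contour(cbind(x, A * sin(x / lam)), closed = FALSE)
  pr <- spline_curvature(sn, n_out = 600)
  k_crest <- max(abs(pr$kappa))
  expect_lt(abs(k_crest - A / lam^2) / (A / lam^2), 0.05)
})

test_that("spline curvature rejects bad input", {
  short <- contour(cbind(1:4, c(0, 1, 0, 1)), closed = FALSE)
  expect_error(spline_curvature(short), "at least 6")
  th <- seq(0, pi, length.out = 50)
  arc <- contour(cbind(cos(th), sin(th)), closed = FALSE)
  expect_error(spline_curvature(arc, smoothing = -1), "smoothing")
})

test_that("sign convention: convex positive, concave negative, flat zero", {
  # edge bulging up toward a gap probe above it
  th <- seq(pi / 4, 3 * pi / 4, length.out = 30)
  bump <- contour(cbind(10 * cos(th), 10 * sin(th)), closed = FALSE)
  probe_above <- c(0, 20)   # outside the circle -> gap side away from center
  expect_gt(assign_sign(0.1, bump, probe_above), 0)
  probe_inside <- c(0, 2)   # inside the circle -> indentation case
  expect_lt(assign_sign(0.1, bump, probe_inside), 0)
  flat <- contour(cbind(seq(0, 10, length.out = 10), rep(0, 10)),
                  closed = FALSE)
  expect_identical(assign_sign(0, flat, c(5, 3)), 0)
  expect_error(assign_sign(0.1, bump, bump$vertices[5, ]), "on the edge")
})

test_that("perimeter contact fraction implements the strict 20% filter", {
  # the wound edge sits exactly tol above the top side, so only that side
  # counts as contact: square 10x10 -> fraction 0.25
  tol <- 0.05
  cell <- contour(c(0, 10, 10, 0), c(0, 0, 10, 10))
  edge <- contour(cbind(seq(-5, 15, length.out = 30), rep(-tol, 30)),
                  closed = FALSE)
  pc <- perimeter_contact_fraction(cell, edge, tol = tol)
  expect_equal(pc$fraction, 0.25, tolerance = 1e-9)
  expect_true(pc$include)

  # interior cell far from the edge
  far <- contour(c(0, 10, 10, 0), c(50, 50, 60, 60))
  pc2 <- perimeter_contact_fraction(far, edge, tol = tol)
  expect_identical(pc2$fraction, 0)
  expect_false(pc2$include)

  # fraction exactly 0.20 is excluded (strict "more than"):
  # rectangle 10 x 15 has perimeter 50, contact side 10 -> 0.2
  rect <- contour(c(0, 10, 10, 0), c(0, 0, 15, 15))
  pc3 <- perimeter_contact_fraction(rect, edge, tol = tol)
  expect_equal(pc3$fraction, 0.2, tolerance = 1e-9)
  expect_false(pc3$include)

  expect_error(perimeter_contact_fraction(cell, edge, tol = 0), "tol")
})

test_that("contact fraction is monotone non-decreasing in tol", {
  sp <- synth_preset("concave-default", seed = 21)
  scene <- make_scene(sp)
  tols <- c(0.05, 0.1, 0.3, 1, 3)
  fr <- vapply(tols, function(tl)
    perimeter_contact_fraction(scene$cell, scene$wound_edge, tol = tl)$fraction,
    numeric(1))
  expect_true(all(diff(fr) >= -1e-12))
})

test_that("front ROI clips the cell to the band behind the edge", {
  cell <- contour(c(0, 20, 20, 0), c(0, 0, 12, 12))
  edge <- contour(cbind(seq(-5, 25, length.out = 40), rep(0, 40)),
                  closed = FALSE)
  roi <- front_roi(cell, edge, d_front = 5)
  expect_equal(contour_area(roi$polygon), 100, tolerance = 0.02)
  expect_equal(roi$tangent_deg, 0, tolerance = 1)

  whole <- front_roi(cell, edge, d_front = 50)
  expect_equal(contour_area(whole$polygon), contour_area(cell),
               tolerance = 1e-9)

  far <- contour(c(0, 20, 20, 0), c(40, 40, 52, 52))
  expect_error(front_roi(far, edge, d_front = 5), "not at edge")
})

test_that("front ROI area matches the annular-sector value on an arc edge", {
  # convex arc edge of radius 30; cell is an annular sector with radial
  # sides, so the d_front band is exactly an annulus sector
  R <- 30; d <- 5; half <- 0.4
  cen <- c(0, 10 - R)
  th <- seq(pi / 2 - 0.5, pi / 2 + 0.5, length.out = 80)
  edge <- contour(cbind(R * cos(th), cen[2] + R * sin(th)), closed = FALSE)
  th_c <- seq(pi / 2 - half, pi / 2 + half, length.out = 60)
  top <- cbind(R * cos(th_c), cen[2] + R * sin(th_c))
  bot <- cbind((R - 8) * cos(rev(th_c)), cen[2] + (R - 8) * sin(rev(th_c)))
  cell <- contour(rbind(top, bot))
  roi <- front_roi(cell, edge, d_front = d, grid_n = 500)
  sector <- 2 * half * (R * d - d^2 / 2)
  expect_equal(contour_area(roi$polygon), sector, tolerance = 0.02 * sector)
})

test_that("cell-level and tissue-level curvature agree on arc wounds", {
  # circular wound edges of both signs; per-cell circle fits must agree in
  # sign and magnitude with the spline curvature of the wound boundary
  for (kap in c(0.05, -0.05)) {
    sp <- synth_spec(seed = 31, kappa = kap)
    scene <- make_scene(sp)
    pc <- perimeter_contact_fraction(scene$cell, scene$wound_edge, tol = 0.2)
    expect_true(pc$include)
    near <- dist_to_contour(scene$cell$vertices, scene$wound_edge) <= 0.2
    fit <- fit_circle(scene$cell$vertices[near, ])
    k_cell <- assign_sign(fit$kappa_mag,
                          contour(scene$cell$vertices[near, ], closed = FALSE),
                          scene$gap_probe)
    expect_equal(k_cell, kap, tolerance = 0.02 * abs(kap))
    prof <- spline_curvature(scene$wound_edge)
    k_tissue_mag <- abs(curvature_arc_mean(prof))
    expect_equal(k_tissue_mag, abs(kap), tolerance = 0.05 * abs(kap))
    expect_identical(sign(k_cell), sign(kap))
  }
})
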