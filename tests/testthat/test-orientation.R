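stripes <- function(theta_deg, n = 128L, period = 8) {
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  th <- theta_deg * pi / 180
  # structures oriented along theta vary along the perpendicular direction
  matrix(sin(2 * pi * (-xy$x * sin(th) + xy$y * cos(th)) / period), n, n)
}

test_that("Fourier directionality finds stripe orientations", {
  h0 <- directionality_fourier(stripes(0), n_bins = 6, angle_range = c(0, 90))
  expect_equal(sum(h0$weight), 1, tolerance = 1e-9)
  b0 <- which.max(h0$weight)
  expect_true(h0$bin_lo[b0] <= 0 && 0 <= h0$bin_hi[b0])
  expect_gte(max(h0$weight), 0.5)

  h30 <- directionality_fourier(stripes(30), n_bins = 6,
                                angle_range = c(0, 90))
  b30 <- which.max(h30$weight)
  expect_true(h30$bin_lo[b30] <= 30 && 30 <= h30$bin_hi[b30])

  # structure-tensor oracle: the dominant gradient direction of the image
  # must agree with the spectral argmax within one bin
  img <- stripes(30)
  gx <- img[c(2:128, 128), ] - img; gy <- img[, c(2:128, 128)] - img
  st_ang <- 0.5 * atan2(2 * sum(gx * gy),
                        sum(gx^2) - sum(gy^2)) * 180 / pi
  struct_ang <- (st_ang + 90) %% 180
  struct_ang <- if (struct_ang > 90) 180 - struct_ang else struct_ang
  expect_lte(abs(struct_ang - (h30$bin_lo[b30] + h30$bin_hi[b30]) / 2), 15)

  expect_error(directionality_fourier(matrix(0, 16, 16)), "too small")
})

test_that("directionality of isotropic noise is near flat", {
  mx <- vapply(1:20, function(s) {
    set.seed(s)
    h <- directionality_fourier(matrix(rnorm(128^2), 128, 128),
                                n_bins = 6, angle_range = c(0, 90))
    max(h$weight)
  }, numeric(1))
  expect_lt(mean(mx), 1.5 / 6)
  expect_lt(max(mx), 2 / 6)
})

test_that("directionality is rotation equivariant within one bin", {
  for (base in c(10, 40)) {
    h1 <- directionality_fourier(stripes(base), n_bins = 10,
                                 angle_range = c(0, 180))
    h2 <- directionality_fourier(stripes(base + 36), n_bins = 10,
                                 angle_range = c(0, 180))
    c1 <- with(h1, (bin_lo[which.max(weight)] + bin_hi[which.max(weight)]) / 2)
    c2 <- with(h2, (bin_lo[which.max(weight)] + bin_hi[which.max(weight)]) / 2)
    dd <- abs((c2 - c1) %% 180 - 36)
    expect_lte(dd, 18 + 1e-9)
  }
})

test_that("microtubule mode uses 10 bins over 0-180 degrees", {
  h <- directionality_fourier(stripes(120), n_bins = 10,
                              angle_range = c(0, 180))
  expect_identical(nrow(h), 10L)
  b <- which.max(h$weight)
  expect_true(h$bin_lo[b] <= 120 && 120 <= h$bin_hi[b])
})

test_that("FA classification thresholds are inclusive and partition", {
  expect_identical(classify_fa(10), "parallel")
  expect_identical(classify_fa(80), "perpendicular")
  expect_identical(classify_fa(45), "excluded")
  expect_identical(classify_fa(18), "parallel")
  expect_identical(classify_fa(72), "perpendicular")
  expect_identical(classify_fa(18.0001), "excluded")
  expect_identical(classify_fa(71.9999), "excluded")
  expect_error(classify_fa(-1), "\\[0, 90\\]")
  expect_error(classify_fa(91), "\\[0, 90\\]")
  angs <- seq(0, 90, by = 0.5)
  cl <- classify_fa(angs)
  expect_true(all(cl %in% c("parallel", "perpendicular", "excluded")))
})

test_that("FA detection recovers ellipse angles and classes", {
  # single bright ellipse at 80 degrees to a straight edge
  sp <- synth_spec(seed = 3, kappa = 0, fa_n = 1L, fa_mean_deg = 80,
                   fa_conc = 1e6)
  fa <- render_fa(sp)
  det <- detect_fa(fa$image, wound_edge = fa$wound_edge)
  expect_identical(nrow(det), 1L)
  expect_equal(det$angle_deg[1], 80, tolerance = 2 / 80)
  expect_identical(det$class[1], "perpendicular")

  # blank image yields an empty table
  blank <- er_image(matrix(0, 64, 64), 0.065)
  expect_identical(nrow(detect_fa(blank)), 0L)

  # many ellipses at known angles: mean absolute angle error <= 3 degrees
  sp2 <- synth_spec(seed = 4, fa_n = 50L, fa_mean_deg = 45, fa_conc = 2)
  fa2 <- render_fa(sp2)
  det2 <- detect_fa(fa2$image, wound_edge = fa2$wound_edge)
  expect_gte(nrow(det2), 35L)
  nearest <- vapply(seq_len(nrow(det2)), function(i) {
    which.min((fa2$truth$x_um - det2$x_um[i])^2 +
                (fa2$truth$y_um - det2$y_um[i])^2)
  }, integer(1))
  mae <- mean(abs(det2$angle_deg - fa2$truth$angle_deg[nearest]))
  expect_lte(mae, 3)
})

test_that("FA-ER association finds the constructed contacts", {
  # ER mask: tubule block left, sheet block right
  mk <- matrix(0L, 100, 100)
  mk[10:40, 40:60] <- 1L
  mk[60:90, 40:60] <- 2L
  ermask <- class_mask(mk, pixel_size = 0.1)
  fas <- data.frame(
    fa_id = 1:3,
    x_um = c(2.5, 7.5, 2.5), y_um = c(5, 5, 9.5),
    area_um2 = 0.2, angle_deg = c(80, 10, 45),
    class = c("perpendicular", "parallel", "excluded"))
  out <- fa_er_association(fas, ermask, contact_radius = 0.3)
  expect_identical(out$fas$er_contact, c("tubule", "sheet", "none"))
  s <- out$summary
  expect_identical(s$frac_tubule[s$class == "perpendicular"], 1)
  expect_identical(s$frac_sheet[s$class == "parallel"], 1)
  expect_error(fa_er_association(fas, ermask, contact_radius = -1),
               "contact_radius")
})

test_that("generator-constructed FA-ER scene associates perfectly", {
  sp <- synth_spec(seed = 14, f_true = 0.5, fa_n = 10L, fa_mean_deg = 80,
                   fa_conc = 1e6)
  scn <- render_er(sp)
  fa_t <- render_fa(sp, place_on = "tubule", er_mask = scn$mask)
  det <- detect_fa(fa_t$image, wound_edge = fa_t$wound_edge)
  out <- fa_er_association(det, scn$mask, contact_radius = 0.3)
  expect_gte(mean(out$fas$er_contact == "tubule"), 0.9)
})
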