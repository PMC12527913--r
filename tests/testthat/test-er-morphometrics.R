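test_that("feature bank behaves on constant, line and blob images", {
  const <- er_image(matrix(5, 64, 64), 0.1)
  st <- compute_features(const, scales = c(1, 2))
  expect_lt(max(abs(st$planes$sobel_1)), 1e-9)
  expect_lt(max(abs(st$planes$dog_1)), 1e-9)
  expect_lt(max(abs(st$planes$hessian_e1_2)), 1e-9)
  expect_equal(max(abs(st$planes$gaussian_1 - 1)), 0, tolerance = 1e-9)

  # bright 1-px horizontal line: membrane max response on the line dwarfs
  # the response 10 px away (oracle: direct correlation with the 0-degree
  # line kernel, which sums 19 on-line pixels there and none off-line)
  ln <- matrix(0, 64, 64); ln[, 32] <- 1
  stl <- compute_features(er_image(ln, 0.1), scales = 1)
  on_line <- stl$planes$membrane_max[32, 32]
  off_line <- stl$planes$membrane_max[32, 42]
  expect_gt(on_line, 5 * max(off_line, 1e-12))

  # isotropic Gaussian blob: both Hessian eigenvalues at the center are
  # negative and equal (analytic Hessian of a Gaussian at its peak)
  xy <- expand.grid(x = 1:65, y = 1:65)
  blob <- matrix(exp(-((xy$x - 33)^2 + (xy$y - 33)^2) / (2 * 3^2)), 65, 65)
  stb <- compute_features(er_image(blob, 0.1), scales = 1)
  e1 <- stb$planes$hessian_e1_1[33, 33]; e2 <- stb$planes$hessian_e2_1[33, 33]
  expect_lt(e1, 0)
  expect_lt(abs(e1 - e2), 1e-6)

  expect_error(compute_features(er_image(matrix(1, 10, 10), 0.1)), "smaller")
})

test_that("classifier training validates labels and is deterministic", {
  sp <- synth_spec(seed = 55, f_true = 0.5, size_px = c(128L, 128L))
  scn <- render_er(sp)
  st <- compute_features(scn$image)
  m <- scn$mask$data
  set.seed(9)
  lab <- rbind(
    data.frame(idx = sample(which(m == 1L), 200), class = 1),
    data.frame(idx = sample(which(m == 2L), 200), class = 2),
    data.frame(idx = sample(which(m == 0L), 400), class = 3))
  model1 <- train_classifier(st, lab, seed = 7)
  model2 <- train_classifier(st, lab, seed = 7)
  expect_gt(model1$oob_accuracy, 0.8)
  mk1 <- classify(model1, scn$image)
  mk2 <- classify(model2, scn$image)
  expect_identical(mk1$data, mk2$data)

  # missing class errors by name
  lab2 <- lab[lab$class != 2, ]
  expect_error(train_classifier(st, lab2, seed = 7), "sheet")
})

test_that("classification recovers ground truth and background defaults", {
  model <- shared_model()
  sp <- synth_spec(seed = 7, kappa = 0.05, f_true = 0.64)
  scn <- render_er(sp)
  msk <- classify(model, scn$image)
  expect_gte(mean(msk$data == scn$mask$data), 0.90)
  # blank image classifies as all background
  blank <- er_image(matrix(0, 64, 64), 0.065)
  mkb <- classify(model, blank)
  expect_true(all(mkb$data == 0L))
  # wrong feature configuration is refused
  st_bad <- compute_features(scn$image, scales = c(1, 2))
  expect_error(classify(model, st_bad), "hash mismatch")
})

test_that("classifier serialization round-trips bit-identically", {
  model <- shared_model()
  p1 <- tempfile(fileext = ".rds"); p2 <- tempfile(fileext = ".rds")
  save_classifier(model, p1)
  reloaded <- load_classifier(p1)
  save_classifier(reloaded, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  sp <- synth_spec(seed = 77, size_px = c(96L, 96L))
  scn <- render_er(sp)
  expect_identical(classify(model, scn$image)$data,
                   classify(reloaded, scn$image)$data)
  unlink(c(p1, p2))
})

test_that("tubule fraction partitions areas and handles edge cases", {
  mk <- class_mask(matrix(c(1L, 1L, 2L, 0L), 2, 2), pixel_size = 0.5)
  fr <- tubule_fraction(mk)
  expect_equal(fr$f_tubule, 2 / 3)
  expect_equal(fr$area_tubule + fr$area_sheet, 3 * 0.25)
  # partition: areas sum to the ROI area exactly
  a_bg <- sum(mk$data == 0L) * 0.25
  expect_identical(fr$area_tubule + fr$area_sheet + a_bg,
                   length(mk$data) * 0.25)

  all_t <- class_mask(matrix(1L, 4, 4), 0.5)
  expect_identical(tubule_fraction(all_t)$f_tubule, 1)
  half <- class_mask(matrix(rep(c(1L, 2L), 8), 4, 4), 0.5)
  expect_identical(tubule_fraction(half)$f_tubule, 0.5)
  bg <- class_mask(matrix(0L, 4, 4), 0.5)
  expect_error(tubule_fraction(bg), "empty ER")
})

test_that("tubule fraction is invariant to uniform intensity rescaling", {
  model <- shared_model()
  sp <- synth_spec(seed = 88, f_true = 0.5, size_px = c(128L, 128L))
  scn <- render_er(sp)
  f1 <- tubule_fraction(classify(model, scn$image))$f_tubule
  scaled <- er_image(scn$image$data * 3.7, scn$image$pixel_size)
  f2 <- tubule_fraction(classify(model, scaled))$f_tubule
  expect_identical(f1, f2)
})

test_that("front intensity fraction matches generator placement", {
  sp <- synth_spec(seed = 12)
  scn <- render_er(sp)
  front <- scn$truth$front_roi; cellm <- scn$truth$cell_mask
  # all signal inside the front ROI
  img1 <- matrix(0, 256, 256); img1[front] <- 50
  expect_equal(front_intensity_fraction(er_image(img1, 0.065), front, cellm), 1)
  # no signal in the front ROI
  img2 <- matrix(0, 256, 256); img2[cellm & !front] <- 50
  expect_equal(front_intensity_fraction(er_image(img2, 0.065), front, cellm), 0)
  # 70% of total intensity in the front band, plus noise and background
  img3 <- matrix(0, 256, 256)
  img3[front] <- 70 / sum(front)
  img3[cellm & !front] <- 30 / sum(cellm & !front)
  img3 <- img3 * 1e4
  set.seed(4); img3 <- pmax(img3 + matrix(rnorm(256^2, 0, 0.1), 256, 256), 0)
  est <- front_intensity_fraction(er_image(img3, 0.065), front, cellm)
  expect_equal(est, 0.70, tolerance = 0.03 / 0.70)
})

test_that("MDE matches analytic cases and is translation invariant", {
  edge <- contour(rbind(c(0, 1.9), c(5, 1.9), c(10, 1.9)), closed = FALSE)
  cellm <- matrix(FALSE, 100, 100); cellm[10:90, 20:80] <- TRUE
  # uniform slab of depth L flush behind the edge: MDE = L/2
  img <- matrix(0, 100, 100); img[10:90, 20:80] <- 1
  r <- mde(er_image(img, 0.1), cellm, edge)
  expect_equal(r$mde, mean((20:80) * 0.1 - 0.05 - 1.9), tolerance = 1e-9)
  L <- (80 - 20 + 1) * 0.1
  expect_equal(r$mde, L / 2, tolerance = 0.02 * L)
  # point mass at 10 um from the edge (pixel center y = 9.95, edge at -0.05)
  edge10 <- contour(rbind(c(0, -0.05), c(5, -0.05), c(10, -0.05)),
                    closed = FALSE)
  ptimg <- matrix(0, 100, 100)
  ptimg[50, 100] <- 3
  rp <- mde(er_image(ptimg, 0.1), matrix(TRUE, 100, 100), edge10)
  expect_equal(rp$mde, 10, tolerance = 0.05 / 10)
  # edge-adjacent signal: MDE below one pixel
  adj <- matrix(0, 100, 100); adj[10:90, 20] <- 1
  expect_lt(mde(er_image(adj, 0.1), cellm, edge)$mde, 0.1 + 1e-9)
  # translation invariance
  sh <- 7L
  img_t <- matrix(0, 100, 100); img_t[(10:90) + 5, (20:80) + sh] <- 1
  cell_t <- matrix(FALSE, 100, 100); cell_t[(10:90) + 5, (20:80) + sh] <- TRUE
  edge_t <- contour(rbind(c(0.5, 1.9 + sh * 0.1), c(5.5, 1.9 + sh * 0.1),
                          c(10.5, 1.9 + sh * 0.1)), closed = FALSE)
  rt <- mde(er_image(img_t, 0.1), cell_t, edge_t)
  expect_equal(rt$mde, r$mde, tolerance = 1e-9)
  # zero signal errors
  expect_error(mde(er_image(matrix(0, 50, 50), 0.1), matrix(TRUE, 50, 50),
                   edge), "zero total signal")
})

test_that("shape index matches analytic polygons", {
  sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(shape_index(sq), 4)
  th <- seq(0, 2 * pi, length.out = 720)[-720]
  circ <- contour(cbind(cos(th), sin(th)))
  expect_equal(shape_index(circ), 2 * sqrt(pi), tolerance = 0.001)
  hexth <- seq(0, 2 * pi, length.out = 7)[-7]
  hex <- contour(cbind(cos(hexth), sin(hexth)))
  expect_equal(shape_index(hex), 6 / sqrt(6 * sqrt(3) / 4 * 1),
               tolerance = 0.001)
  expect_error(contour(c(0, 1, 0, 1), c(0, 1, 1, 0)), "self-intersecting")
})

test_that("validate_fractions computes Pearson r with guards", {
  expect_equal(validate_fractions(1:5, 1:5)$r, 1)
  expect_equal(validate_fractions(1:5, -(1:5))$r, -1)
  expect_error(validate_fractions(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(validate_fractions(1:2, 1:2), "at least 3")
})
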