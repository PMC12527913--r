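test_that("generator is deterministic and leaves the RNG stream alone", {
  sp <- synth_preset("convex-default", seed = 42)
  a <- render_er(sp)
  set.seed(999); before <- rnorm(1)
  b <- render_er(sp)
  set.seed(999); after <- rnorm(1)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(before, after)
  s1 <- make_scene(sp); s2 <- make_scene(sp)
  expect_identical(s1$cell$vertices, s2$cell$vertices)
  fa1 <- render_fa(sp); fa2 <- render_fa(sp)
  expect_identical(fa1$image$data, fa2$image$data)
})

test_that("scene geometry honours curvature and the contact filter", {
  # flat edge
  s0 <- make_scene(synth_spec(seed = 2, kappa = 0))
  pc0 <- perimeter_contact_fraction(s0$cell, s0$wound_edge, tol = 0.065)
  expect_gt(pc0$fraction, 0.2)
  # measured arc curvature matches the requested value within 2%
  for (kap in c(0.05, -0.05)) {
    s <- make_scene(synth_spec(seed = 2, kappa = kap))
    fit <- fit_circle(s$wound_edge$vertices)
    expect_equal(fit$kappa_mag, abs(kap), tolerance = 0.02 * abs(kap))
    signed <- assign_sign(fit$kappa_mag, s$wound_edge, s$gap_probe)
    expect_identical(sign(signed), sign(kap))
  }
  # arcs that cannot fit the frame are rejected
  expect_error(synth_spec(seed = 2, kappa = 0.3), "kappa")
})

test_that("rendered ER fraction tracks the request across the range", {
  for (f in c(0.2, 0.5, 0.8)) {
    scn <- render_er(synth_spec(seed = 300 + round(100 * f), f_true = f))
    expect_lte(abs(scn$truth$f_realized - f), 0.02)
  }
  # pure-tubule scene contains no sheet pixels
  scn1 <- render_er(synth_spec(seed = 9, f_true = 1))
  expect_identical(sum(scn1$mask$data == 2L), 0L)
  expect_equal(scn1$truth$f_realized, 1)
})

test_that("noiseless rendering thresholds back to the mask exactly", {
  sp <- synth_spec(seed = 10, f_true = 0.5, psf_sigma_px = 0,
                   poisson_scale = 0, read_noise_sd = 0)
  scn <- render_er(sp)
  img <- scn$image$data
  rec <- matrix(0L, nrow(img), ncol(img))
  rec[img >= (sp$intensity[["cyto"]] + sp$intensity[["tubule"]]) / 2] <- 1L
  rec[img >= (sp$intensity[["tubule"]] + sp$intensity[["sheet"]]) / 2] <- 2L
  expect_identical(rec, scn$mask$data)
})

test_that("flat-region noise variance follows the Poisson slope", {
  means <- c(20, 60, 120)
  vars <- vapply(means, function(mu) {
    sp <- synth_spec(seed = 500 + mu, read_noise_sd = 0, psf_sigma_px = 0)
    img <- matrix(mu, 128, 128)
    noisy <- with_seed(sp$seed, erfront:::synth_apply_noise(sp, img))
    stats::var(as.vector(noisy))
  }, numeric(1))
  # var = mean / poisson_scale for scaled Poisson counts
  slope <- stats::coef(stats::lm(vars ~ means))[2]
  expect_equal(unname(slope), 1 / 2, tolerance = 0.1)
})

test_that("presets produce the documented convex/concave contrast", {
  cx <- render_er(synth_preset("convex-default", seed = 3))
  cc <- render_er(synth_preset("concave-default", seed = 3))
  expect_gt(cx$truth$f_realized, cc$truth$f_realized)
  expect_equal(cx$truth$f_realized, 0.64, tolerance = 0.02 / 0.64)
  expect_equal(cc$truth$f_realized, 0.35, tolerance = 0.02 / 0.35)
})

test_that("FA angle distribution follows the requested concentration", {
  # degenerate concentration: all angles at the mean
  sp <- synth_spec(seed = 11, fa_n = 40L, fa_mean_deg = 90, fa_conc = 1e8)
  fa <- render_fa(sp)
  expect_true(all(abs(fa$truth$angle_deg - 90) <= 1))
  # zero concentration: uniform angles on [0, 90] (KS test across seeds)
  angs <- unlist(lapply(1:5, function(s) {
    render_fa(synth_spec(seed = s, fa_n = 40L, fa_conc = 0))$truth$angle_deg
  }))
  ks <- stats::ks.test(angs, "punif", 0, 90)
  expect_gt(ks$p.value, 0.01)
  # strongly parallel population classifies parallel downstream
  sp3 <- synth_spec(seed = 12, fa_n = 50L, fa_mean_deg = 10, fa_conc = 50)
  fa3 <- render_fa(sp3)
  expect_gte(mean(fa3$truth$class == "parallel"), 0.9)
})

test_that("training sets are balanced and deterministic", {
  specs <- list(synth_spec(seed = 901, f_true = 0.3,
                           size_px = c(128L, 128L)),
                synth_spec(seed = 902, f_true = 0.7,
                           size_px = c(128L, 128L)))
  t1 <- make_training_set(specs, n_per_class = 300, seed = 4)
  t2 <- make_training_set(specs, n_per_class = 300, seed = 4)
  lab1 <- do.call(rbind, t1$labels)
  expect_identical(lab1, do.call(rbind, t2$labels))
  counts <- table(lab1$class)
  expect_identical(unname(counts[["1"]]), 300L)
  expect_identical(unname(counts[["2"]]), 300L)
  # background is deliberately oversampled around structure boundaries
  expect_gte(counts[["3"]], 300L)
  # a class missing from every scene errors by name
  pure <- list(synth_spec(seed = 903, f_true = 1,
                          size_px = c(128L, 128L)))
  expect_error(make_training_set(pure, n_per_class = 100), "sheet")
})

test_that("time-lapse renderer respects velocity bounds and zero flow", {
  sp <- synth_spec(seed = 13, flow_um_min = 0, n_frames = 6)
  tl <- render_timelapse(sp)
  d <- dim(tl$stack$data)
  expect_identical(d[3], 6L)
  # frames differ only by noise: correlation between frames stays high
  expect_gt(stats::cor(as.vector(tl$stack$data[, , 1]),
                       as.vector(tl$stack$data[, , 6])), 0.95)
  expect_error(render_timelapse(synth_spec(seed = 13, flow_um_min = 8,
                                           n_frames = 12)),
               "out of frame")
  expect_error(render_timelapse(synth_spec(seed = 13, n_frames = 3L)),
               "at least 5")
})
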