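# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code from seeded specs; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)()
  .fixtures[[name]]
}

# classifier trained on three scenes spanning low / mid / high fractions
shared_model <- function() {
  fixture("model", function() {
    specs <- list(synth_spec(seed = 101L, f_true = 0.2),
                  synth_spec(seed = 102L, f_true = 0.5),
                  synth_spec(seed = 103L, f_true = 0.8))
    tset <- make_training_set(specs, seed = 5L)
    train_on_synthetic(tset, seed = 5L)
  })
}

# full two-mode curvature sweep at default parameters, shared by the
# mechanics acceptance checks
shared_sweep_convex <- function() {
  fixture("sweep_convex", function() {
    curvature_sweep(kappas = c(0, seq(0.01, 0.08, by = 0.01)),
                    modes = c("protrusion", "contraction"))
  })
}

shared_sweep_concave <- function() {
  fixture("sweep_concave", function() {
    curvature_sweep(kappas = seq(-0.01, -0.08, by = -0.01),
                    modes = c("protrusion", "contraction"))
  })
}

# points on a circular arc, with optional jitter
arc_points <- function(r, n = 50, theta = c(0, pi), noise_sd = 0,
                       center = c(0, 0), seed = NULL) {
  th <- seq(theta[1], theta[2], length.out = n)
  p <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    p <- p + matrix(rnorm(2 * n, 0, noise_sd), n, 2)
  }
  p
}

# brute-force circle-fit oracle: grid search over (center, R) minimizing
# the sum of squared radial residuals, refined around the best cell
oracle_circle_fit <- function(pts, span = 2, steps = 21L, rounds = 4L) {
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  best <- c(cx, cy + 10, 10)
  obj <- function(c1, c2, r) {
    d <- sqrt((pts[, 1] - c1)^2 + (pts[, 2] - c2)^2)
    sum((d - r)^2)
  }
  # initial radius guess from pairwise spread
  r0 <- max(dist(pts[seq(1, nrow(pts), length.out = 10), ])) / 2
  ctr <- c(cx, cy); rr <- r0 * 2
  sp <- span * r0
  for (round in seq_len(rounds)) {
    g1 <- seq(ctr[1] - sp, ctr[1] + sp, length.out = steps)
    g2 <- seq(ctr[2] - sp, ctr[2] + sp, length.out = steps)
    g3 <- seq(max(rr - sp, 1e-3), rr + sp, length.out = steps)
    sc <- expand.grid(c1 = g1, c2 = g2, r = g3)
    vals <- mapply(obj, sc$c1, sc$c2, sc$r)
    b <- sc[which.min(vals), ]
    ctr <- c(b$c1, b$c2); rr <- b$r
    sp <- sp * 2.5 / steps
  }
  # local polish of the grid optimum (still the geometric criterion,
  # independent of the algebraic fit under test)
  o <- stats::optim(c(ctr, rr), function(p) obj(p[1], p[2], p[3]))
  list(center = o$par[1:2], radius = o$par[3])
}
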