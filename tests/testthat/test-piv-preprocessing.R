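test_that("POD removal strips a static background and keeps mode bookkeeping honest", {
  # rank-1 static stack: one mode removes (essentially) everything
  frame <- outer(seq_len(32), seq_len(48), function(i, j) 1 + sin(i / 5) * cos(j / 7))
  stack <- array(rep(frame, each = 5), dim = c(5, 32, 48))
  out <- pod_background_removal(stack, 1L)
  rng <- diff(range(stack))
  expect_lt(max(abs(out$frames)), 1e-6 * rng)
  sv <- out$singular_values
  expect_gt(sv[1]^2 / sum(sv^2), 0.999)

  # background reconstruction is orthogonal to the unclipped residual
  st <- generate_particle_images(image_stack_config(n_frames = 8L, seed = 2L))
  o <- pod_background_removal(st$frames, 1L)
  ip <- sum(o$background * o$residual_raw) /
    sqrt(sum(o$background^2) * sum(o$residual_raw^2))
  expect_lt(abs(ip), 1e-6)

  expect_error(pod_background_removal(stack, 5L), "number of frames")
  expect_error(pod_background_removal(stack, 0L), "number of frames")
})

test_that("POD removal reduces the residual against ground truth at least tenfold", {
  cfg <- image_stack_config(n_frames = 24L, particle_density = 0.02,
                            background_amplitude = 0.8,
                            reflection_amplitude = 0,
                            sensor_noise_sigma = 0.005,
                            jitter_px = 4, seed = 4L)
  st <- generate_particle_images(cfg)
  out <- pod_background_removal(st$frames, 1L)
  err_before <- sqrt(mean((st$frames - st$particles)^2))
  err_after <- sqrt(mean((out$frames - st$particles)^2))
  expect_gt(err_before / err_after, 10)
})

test_that("anisotropic diffusion flattens bright bands while keeping edges and particles", {
  # uniform frame: diffusion is a no-op, output residual is zero
  uf <- array(0.7, dim = c(2, 20, 30))
  out <- anisotropic_diffusion_background(uf, kappa = 0.1)
  expect_equal(out$background, uf, tolerance = 1e-12)
  expect_equal(max(abs(out$frames)), 0)

  # step edge of height 10 kappa stays sharp: 10-90% width grows < 2 px
  kappa <- 0.05
  step <- matrix(0, 24, 60)
  step[, 31:60] <- 10 * kappa
  st <- array(rep(step, each = 2), dim = c(2, 24, 60))
  bg <- anisotropic_diffusion_background(st, kappa = kappa)$background[1, , ]
  prof <- colMeans(bg)
  h <- 10 * kappa
  width <- function(p) {
    i10 <- min(which(p >= 0.1 * h)); i90 <- min(which(p >= 0.9 * h))
    i90 - i10
  }
  expect_lt(width(prof), width(colMeans(step)) + 2)

  # reflection band removed >= 5x while particle peaks retain >= 80%
  cfg <- image_stack_config(n_frames = 2L, particle_density = 0.008,
                            particle_intensity = 0.25,
                            background_amplitude = 0,
                            reflection_amplitude = 1,
                            reflection_osc_px = 0,
                            sensor_noise_sigma = 0, seed = 6L)
  stx <- generate_particle_images(cfg)
  o <- anisotropic_diffusion_background(stx$frames, kappa = 0.1)
  band_cols <- abs(seq_len(cfg$width) - cfg$reflection_center_px) <=
    cfg$reflection_width_px
  band_before <- sqrt(mean((stx$reflections[, , band_cols])^2))
  resid_band <- o$frames[, , band_cols] - stx$particles[, , band_cols]
  expect_gt(band_before / sqrt(mean(resid_band^2)), 5)

  # particle amplitude at the ground-truth peak locations
  peaks <- which(stx$particles[1, , ] > 0.9 * max(stx$particles[1, , ]))
  expect_gt(mean(o$frames[1, , ][peaks] / stx$particles[1, , ][peaks]), 0.8)

  expect_error(anisotropic_diffusion_background(uf, kappa = 0.1, dt = 0.5),
               "stability")
})

test_that("region blending honours the split column and cross-fade contracts", {
  a <- array(stats::runif(2 * 10 * 20), dim = c(2, 10, 20))
  b <- array(stats::runif(2 * 10 * 20), dim = c(2, 10, 20))
  expect_equal(blend_preprocessed(a, b, 0)$frames, b)
  expect_equal(blend_preprocessed(a, b, 20)$frames, a)
  expect_equal(blend_preprocessed(a, a, 7)$frames, a)
  # hard seam: left of the split from the first stack, right from the second
  h <- blend_preprocessed(a, b, 7, overlap = 0L)$frames
  expect_equal(h[, , 1:7], a[, , 1:7])
  expect_equal(h[, , 8:20], b[, , 8:20])
  expect_error(blend_preprocessed(a, b, 25), "width")
  expect_error(blend_preprocessed(a, array(0, c(2, 5, 20)), 3), "identical")
})

test_that("normalized-median detection flags exactly a seeded spike and repairs it", {
  # smooth linear field + one spiked vector
  u <- outer(seq_len(9), seq_len(11), function(i, j) 0.3 * i + 0.1 * j)
  v <- outer(seq_len(9), seq_len(11), function(i, j) 0.05 * i - 0.2 * j)
  u[5, 6] <- u[5, 6] + 25
  res <- universal_outlier_detection(vector_field(u, v))
  expect_identical(which(res$outliers), which(matrix(seq_len(99), 9, 11) == 50))

  # repair contract: the spiked vector becomes the median of its 8 neighbours
  nb <- u[4:6, 5:7]; nb <- nb[-5]
  expect_equal(res$field$u[5, 6], stats::median(nb))

  # uniform field with eps > 0: nothing flagged
  res0 <- universal_outlier_detection(vector_field(matrix(2, 8, 8),
                                                   matrix(-1, 8, 8)))
  expect_false(any(res0$outliers))

  expect_error(universal_outlier_detection(vector_field(matrix(1, 2, 5),
                                                        matrix(1, 2, 5))),
               "3 x 3")
})

test_that("normalized-median statistics agree with an independent oracle and stabilise on repair", {
  set.seed(21)
  u <- smooth_component(15, 12, 1, 1) + 0.1 * matrix(stats::rnorm(180), 12, 15)
  v <- smooth_component(15, 12, 1, 1) + 0.1 * matrix(stats::rnorm(180), 12, 15)
  spikes <- cbind(c(3, 8, 10), c(4, 12, 7))
  u[spikes] <- u[spikes] + c(6, -7, 8)
  res <- universal_outlier_detection(vector_field(u, v))
  expect_identical(res$outliers, oracle_nmt_flags(u, v))

  # a second pass on the repaired field flags no more vectors than the first
  res2 <- universal_outlier_detection(res$field)
  expect_lte(sum(res2$outliers), sum(res$outliers))
})

test_that("spike detection reaches high sensitivity at low false-positive rate", {
  set.seed(31)
  ny <- 40; nx <- 50
  base_u <- 3 * smooth_component(nx, ny, 1, 1)
  base_v <- 1.2 * smooth_component(nx, ny, 1, 1)
  trials_sens <- 0; trials_hit <- 0; fp <- 0; clean_n <- 0
  for (rep in 1:5) {
    u <- base_u + 0.05 * matrix(stats::rnorm(ny * nx), ny, nx)
    v <- base_v + 0.05 * matrix(stats::rnorm(ny * nx), ny, nx)
    idx <- cbind(sample(3:(ny - 2), 15), sample(3:(nx - 2), 15))
    # spikes at >= 5 local standard deviations
    for (k in 1:15) {
      i <- idx[k, 1]; j <- idx[k, 2]
      s <- stats::sd(u[(i - 1):(i + 1), (j - 1):(j + 1)])
      u[i, j] <- u[i, j] + sample(c(-1, 1), 1) * 6 * max(s, 0.1)
    }
    res <- universal_outlier_detection(vector_field(u, v))
    hits <- res$outliers[idx]
    trials_sens <- trials_sens + length(hits)
    trials_hit <- trials_hit + sum(hits)
    clean <- res$outliers
    clean[idx] <- NA
    fp <- fp + sum(clean, na.rm = TRUE)
    clean_n <- clean_n + sum(!is.na(clean))
  }
  expect_gte(trials_hit / trials_sens, 0.95)
  expect_lte(fp / clean_n, 0.01)
})
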