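test_that("an isolated particle yields one full-length trajectory", {
  set.seed(1)
  pos <- cumsum(rnorm(30L, 0, 50))
  df <- data.frame(frame = 0:29, x = pos, y = 1000 + pos, z = 0)
  trk <- link_localizations(df, max_disp = 500, memory = 1L, dt = 0.02)
  expect_length(trk, 1L)
  expect_identical(nrow(trk[[1L]]), 30L)
  expect_equal(trk[[1L]]$t, df$frame * 0.02)
})

test_that("well-separated particles never swap identities", {
  set.seed(2)
  n_frames <- 40L
  a <- data.frame(frame = 0:(n_frames - 1L),
                  x = cumsum(rnorm(n_frames, 0, 60)),
                  y = cumsum(rnorm(n_frames, 0, 60)), z = 0)
  b <- a
  b$x <- b$x + 5000  # always > 2 x max_disp apart
  df <- rbind(a, b)
  trk <- link_localizations(df, max_disp = 500, memory = 1L)
  expect_length(trk, 2L)
  xs <- vapply(trk, function(tr) diff(range(abs(tr$x))), numeric(1L))
  for (tr in trk) {
    expect_true(all(tr$x < 2500) || all(tr$x > 2500))  # no identity mixing
  }
})

test_that("gap closing bridges a single missing frame", {
  df <- data.frame(frame = c(0L, 1L, 3L, 4L), x = c(0, 50, 150, 200),
                   y = 0, z = 0)
  with_memory <- link_localizations(df, max_disp = 500, memory = 1L)
  expect_length(with_memory, 1L)
  expect_identical(nrow(with_memory[[1L]]), 4L)
  without <- link_localizations(df, max_disp = 500, memory = 0L)
  expect_length(without, 2L)
})

test_that("linking matches a brute-force optimal assignment oracle", {
  set.seed(33)
  n_particles <- 50L
  n_frames <- 12L
  step_sd <- 80
  pos <- lapply(seq_len(n_particles), function(i) {
    cbind(x = cumsum(rnorm(n_frames, 0, step_sd)) + runif(1L, 0, 12000),
          y = cumsum(rnorm(n_frames, 0, step_sd)) + runif(1L, 0, 12000),
          z = cumsum(rnorm(n_frames, 0, step_sd)))
  })
  df <- do.call(rbind, lapply(seq_len(n_particles), function(i) {
    data.frame(frame = 0:(n_frames - 1L), x = pos[[i]][, 1L],
               y = pos[[i]][, 2L], z = pos[[i]][, 3L], truth = i)
  }))
  df <- df[order(df$frame), ]
  trk <- link_localizations(df, max_disp = 500, memory = 0L)
  # package labels per row of df
  labels <- integer(nrow(df))
  key <- paste(df$frame, round(df$x, 6), round(df$y, 6))
  for (i in seq_along(trk)) {
    kk <- paste(trk[[i]]$frame, round(trk[[i]]$x, 6), round(trk[[i]]$y, 6))
    labels[match(kk, key)] <- i
  }
  oracle <- brute_force_link(df, max_disp = 500)
  expect_identical(partition_signature(labels), partition_signature(oracle))
  # at this density the truth is recovered exactly, too
  expect_identical(partition_signature(labels),
                   partition_signature(df$truth))
})

test_that("time-averaged MSD matches closed forms", {
  # ballistic motion: positions 0,1,2,3 -> MSD(k) = k^2
  tr <- data.frame(frame = 0:3, t = 0:3, x = 0:3, y = 0, z = 0)
  m <- compute_msd(tr)
  expect_equal(m$msd_x, c(1, 4, 9))
  expect_equal(m$lag, 1:3)
  expect_equal(m$n, c(3L, 2L, 1L))

  # two-sample track: a single lag point
  short <- data.frame(frame = 0:1, t = c(0, 0.02), x = c(0, 5), y = 0, z = 0)
  expect_identical(nrow(compute_msd(short)), 1L)

  # immobile particle with iid noise sigma: MSD plateaus at 2 sigma^2
  set.seed(3)
  sigma <- 30
  long <- data.frame(frame = 0:4999, t = (0:4999) * 0.02,
                     x = rnorm(5000L, 0, sigma), y = 0, z = 0)
  m2 <- compute_msd(long, max_lag = 5L)
  expect_lt(max(abs(m2$msd_x / (2 * sigma^2) - 1)), 0.1)
})

test_that("ensemble MSD excludes short tracks and weights by pair counts", {
  mk <- function(n, seed) {
    set.seed(seed)
    data.frame(frame = 0:(n - 1L), t = (0:(n - 1L)) * 0.02,
               x = cumsum(rnorm(n, 0, 40)), y = cumsum(rnorm(n, 0, 40)),
               z = cumsum(rnorm(n, 0, 40)))
  }
  trks <- structure(list(mk(10L, 1), mk(25L, 2), mk(40L, 3)),
                    dt = 0.02, class = "trajectory_set")
  em <- ensemble_msd(trks, min_track_len = 20L)
  expect_identical(attr(em, "n_tracks"), 2L)
  # pair counts at lag 1: (25-1) + (40-1)
  expect_equal(em$n[1L], 24L + 39L)
  expect_true(all(diff(em$n) <= 0))

  single <- ensemble_msd(trks[3], min_track_len = 20L)
  expect_equal(single$msd_x, compute_msd(mk(40L, 3))$msd_x)

  twin <- structure(list(mk(30L, 7), mk(30L, 7)), dt = 0.02,
                    class = "trajectory_set")
  em2 <- ensemble_msd(twin, min_track_len = 20L)
  expect_equal(em2$msd_x, compute_msd(mk(30L, 7))$msd_x)

  expect_error(ensemble_msd(trks, min_track_len = 50L), "min_track_len")
})

test_that("ensemble MSD is invariant to ordering and global translation", {
  sim <- simulate_trajectories(20L, D = c(0.05, 0.05, 0.02), n_frames = 30L,
                               seed = 9)
  trk <- link_localizations(sim$observed, max_disp = 600)
  em1 <- ensemble_msd(trk, min_track_len = 20L)
  em2 <- ensemble_msd(rev(trk), min_track_len = 20L)
  expect_equal(em1$msd_x, em2$msd_x)
  shifted <- lapply(trk, function(tr) {
    tr$x <- tr$x + 1e5; tr$y <- tr$y - 2e5; tr
  })
  em3 <- ensemble_msd(shifted, min_track_len = 20L)
  expect_equal(em3$msd_x, em1$msd_x, tolerance = 1e-9)
})

test_that("an exact linear MSD returns its own slope and intercept", {
  # MSD(tau) = 0.004 um^2 + 2 * 0.058 um^2/s * tau, expressed in nm^2
  tau <- (1:8) * 0.02
  line <- 0.004 * 1e6 + 2 * 0.058 * 1e6 * tau
  msd <- structure(data.frame(lag = 1:8, tau = tau, msd_x = line,
                              msd_y = line, msd_z = line, n = 100L),
                   class = c("msd_result", "data.frame"))
  fit <- fit_diffusion(msd, n_fit_points = 5L)
  cf <- coef(fit)
  expect_equal(unname(cf["x", "D"]), 0.058, tolerance = 1e-12)
  expect_equal(unname(cf["x", "offset"]), 4000, tolerance = 1e-9)  # 0.004 um^2

  expect_error(fit_diffusion(msd[1:4, ], n_fit_points = 5L), "lag points")
})

test_that("the full link-MSD-fit pipeline recovers anisotropic diffusion", {
  D_true <- c(0.058, 0.059, 0.023)
  noise <- c(20, 20, 70)
  sim <- simulate_trajectories(150L, D = D_true, dt = 0.02, n_frames = 50L,
                               noise_sigma = noise, seed = 14)
  trk <- link_localizations(sim$observed, max_disp = 500, memory = 1L,
                            dt = 0.02)
  fit <- fit_diffusion(ensemble_msd(trk, min_track_len = 20L),
                       n_fit_points = 5L)
  cf <- coef(fit)
  for (r in c("x", "y", "z")) {
    i <- match(r, c("x", "y", "z"))
    expect_lt(abs(cf[r, "D"] - D_true[i]), 3 * cf[r, "D_se"] + 0.1 * D_true[i])
    # offset reflects the squared localization precision: o ~ 2 sigma^2
    expect_lt(abs(cf[r, "offset"] - 2 * noise[i]^2),
              0.2 * 2 * noise[i]^2 + 3 * cf[r, "offset_se"])
  }
  # anisotropy ordering preserved
  expect_gt(cf["x", "D"], cf["z", "D"])
})
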