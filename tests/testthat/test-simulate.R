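test_that("zero densities produce zero emitters", {
  sc <- scene_spec(rho_basal = 0, rho_apical = 0, rho_interface = 0)
  gt <- sample_membrane_emitters(sc, seed = 1)
  expect_identical(nrow(gt), 0L)
})

test_that("basal emitter counts are Poisson with mean density x area", {
  # one-cell scene built to have a basal disc of 10 um^2 at 100 emitters/um^2
  sc <- scene_with_basal_area(10, rho_basal = 100)
  areas <- region_areas(sc)
  expect_equal(areas[["basal"]], 10, tolerance = 1e-6)
  counts <- vapply(1:200, function(s) {
    nrow(sample_membrane_emitters(sc, seed = s))
  }, integer(1L))
  # Poisson(1000) mean over 200 seeds: SE = sqrt(1000/200)
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 200))
  expect_true(all(sample_membrane_emitters(sc, seed = 3)$z == 0))
})

test_that("interface density twice apical is reflected in sampled counts", {
  sc <- scene_spec(rho_basal = 0, rho_apical = 200, rho_interface = 400)
  areas <- region_areas(sc)
  tot_i <- 0; tot_a <- 0
  for (s in 1:30) {
    gt <- sample_membrane_emitters(sc, seed = s)
    tot_i <- tot_i + sum(gt$region == "interface")
    tot_a <- tot_a + sum(gt$region == "apical")
  }
  dens_ratio <- (tot_i / areas[["interface"]]) / (tot_a / areas[["apical"]])
  # ratio of two Poisson-mean estimates; generous 3-sigma band
  expect_lt(abs(dens_ratio - 2), 0.15)
})

test_that("sampled emitters lie exactly on the membrane surface", {
  sc <- scene_spec()
  gt <- sample_membrane_emitters(sc, seed = 9)
  R <- sc$cap_radius
  z0 <- sc$cap_height - R
  for (cell in 1:2) {
    g <- gt[gt$cell == cell, ]
    yc <- if (cell == 1L) sc$contact_offset else sc$contact_offset + sc$gap
    y_local <- if (cell == 1L) g$y else 2 * sc$contact_offset + sc$gap - g$y
    r <- sqrt(g$x^2 + y_local^2 + (g$z - z0)^2)
    expect_true(all(abs(r[g$region == "apical"] - R) < 1e-9))
    expect_true(all(g$z[g$region == "basal"] == 0))
    expect_true(all(abs(g$y[g$region == "interface"] - yc) < 1e-9))
  }
})

test_that("blinking kinetics: no activation means no events, forced means all on", {
  gt <- data.frame(id = 1:5)
  off <- simulate_blinking(gt, 50L, activation_rate = 0, seed = 1)
  expect_identical(nrow(off$events), 0L)
  expect_true(all(lengths(off$active) == 0L))

  on <- simulate_blinking(data.frame(id = 1L), 30L, mean_on_time = 30,
                          activation_rate = 1, on_time_dist = "fixed",
                          seed = 1)
  expect_true(all(lengths(on$active) == 1L))
})

test_that("mean blink on-time matches the geometric model", {
  gt <- data.frame(id = seq_len(12000L))
  bl <- simulate_blinking(gt, 500L, mean_on_time = 3, activation_rate = 0.05,
                          seed = 4)
  dur <- bl$events$end - bl$events$start + 1L
  dur <- dur[bl$events$end < 499L]  # drop events truncated by the movie end
  expect_gt(length(dur), 1e4)
  expect_lt(abs(mean(dur) - 3) / 3, 0.05)
})

test_that("rendering: empty frame is flat, photons are conserved, astigmatism flips", {
  cal <- synthetic_calibration()
  flat <- render_frame(NULL, c(16L, 16L), cal, background = 0,
                       camera = list(offset = 100, gain = 1), noise = FALSE)
  expect_true(all(flat == 100))

  em <- data.frame(x = 24 * 103.8, y = 24 * 103.8, z = 0)
  img <- render_frame(em, c(48L, 48L), cal, mean_photons = 2000,
                      background = 0, noise = FALSE)
  expect_lt(abs(sum(img) - 2000) / 2000, 0.005)  # truncation only

  # second-moment anisotropy flips sign with the sign of z
  moments <- function(z) {
    im <- render_frame(data.frame(x = 24 * 103.8, y = 24 * 103.8, z = z),
                       c(48L, 48L), cal, mean_photons = 2000,
                       background = 0, noise = FALSE)
    xs <- col(im) - 24.5; ys <- row(im) - 24.5
    c(vx = sum(im * xs^2) / sum(im), vy = sum(im * ys^2) / sum(im))
  }
  m_neg <- moments(-300); m_pos <- moments(300)
  expect_gt(m_neg["vx"] - m_neg["vy"], 0)
  expect_lt(m_pos["vx"] - m_pos["vy"], 0)

  # out-of-range z is skipped and counted
  skip_img <- render_frame(data.frame(x = 100, y = 100, z = 5000),
                           c(16L, 16L), cal, background = 0, noise = FALSE)
  expect_identical(attr(skip_img, "n_skipped"), 1L)
  expect_true(all(skip_img == 0))
})

test_that("the acquisition plan and sheet visibility follow the sawtooth scan", {
  g <- acquisition_geometry(n_stacks = 573L)
  plan <- scan_plan(g)
  expect_identical(nrow(plan), 573573L)
  expect_equal(max(plan$s), 40000)
  expect_equal(plan$s[1002L], 0)  # sawtooth reset at the second stack

  # an emitter farther than sheet_thickness/2 from the sheet in every frame
  # is never excitable
  g2 <- acquisition_geometry(frames_per_stack = 11L, n_stacks = 1L,
                             scan_step = 40, deskew_angle = 30)
  gt <- structure(data.frame(id = 1L, x = 0, y = 50000, z = 0),
                  class = c("ground_truth", "data.frame"))
  out <- simulate_scan_acquisition(gt, g2, seed = 1)
  expect_true(all(lengths(out$visible) == 0L))

  # visibility bound holds exactly for a scene's emitters
  sc <- scene_spec(rho_basal = 30, rho_apical = 30, rho_interface = 30)
  truth <- sample_membrane_emitters(sc, seed = 2)
  g3 <- acquisition_geometry(frames_per_stack = 51L, n_stacks = 1L,
                             scan_step = 200)
  vis <- simulate_scan_acquisition(truth, g3, seed = 2)
  a <- g3$deskew_angle * pi / 180
  for (i in seq_along(vis$visible)) {
    ids <- vis$visible[[i]]
    if (length(ids) == 0L) next
    j <- match(ids, truth$id)
    z_acq <- -(truth$y[j] - vis$plan$s[i]) * sin(a) + truth$z[j] * cos(a)
    expect_true(all(abs(z_acq) <= g3$sheet_thickness / 2))
  }
})

test_that("Brownian increments have variance 2 D dt per dimension", {
  sim <- simulate_trajectories(40L, D = c(0.06, 0.04, 0.01), dt = 0.02,
                               n_frames = 60L, noise_sigma = c(0, 0, 0),
                               seed = 6)
  for (dim_i in list(c("x", 0.06), c("y", 0.04), c("z", 0.01))) {
    v <- unlist(lapply(split(sim$true[[dim_i[[1L]]]], sim$true$id), diff))
    expected <- 2 * as.numeric(dim_i[[2L]]) * 1e6 * 0.02
    n_inc <- length(v)
    # chi-square: var of the variance estimate is 2 sigma^4 / n
    expect_lt(abs(var(v) / expected - 1), 3 * sqrt(2 / n_inc))
  }
  static <- simulate_trajectories(3L, D = c(0, 0, 0), dt = 0.02,
                                  n_frames = 10L, noise_sigma = c(0, 0, 0),
                                  seed = 1)
  expect_equal(var(static$true$x[static$true$id == 1L]), 0)
})

test_that("FRAP trace matches the closed-form recovery model", {
  tr <- simulate_frap(tau = 15, mobile_fraction = 0.8, bleach_depth = 0.7,
                      n_prebleach = 3L, frame_interval = 1.5,
                      total_time = 120, noise_sd = 0)
  t <- tr$t
  expect_equal(t[2L] - t[1L], 1.5)
  expect_equal(max(t), 120)
  expect_true(all(tr$intensity[1:3] == 1))
  ti <- t - t[4L]
  model <- 0.3 + 0.8 * 0.7 * (1 - exp(-ti / 15))
  expect_equal(tr$intensity[-(1:3)], model[-(1:3)], tolerance = 1e-12)

  immobile <- simulate_frap(mobile_fraction = 0, bleach_depth = 0.5,
                            noise_sd = 0)
  expect_true(all(immobile$intensity[-(1:3)] == 0.5))

  full <- simulate_frap(tau = 5, mobile_fraction = 1, total_time = 300,
                        noise_sd = 0)
  expect_lt(abs(tail(full$intensity, 1L) - 1), 1e-10)
})

test_that("stochastic generators are reproducible given a seed", {
  sc <- scene_spec(rho_basal = 50, rho_apical = 50, rho_interface = 100)
  expect_identical(sample_membrane_emitters(sc, seed = 5),
                   sample_membrane_emitters(sc, seed = 5))
  g <- acquisition_geometry(frames_per_stack = 41L, scan_step = 200)
  truth <- sample_membrane_emitters(sc, seed = 5)
  t1 <- simulate_localizations(truth, g, activation_rate = 0.05, seed = 8)
  t2 <- simulate_localizations(truth, g, activation_rate = 0.05, seed = 8)
  expect_identical(t1, t2)
  expect_false(identical(
    t1, simulate_localizations(truth, g, activation_rate = 0.05, seed = 9)))
})
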