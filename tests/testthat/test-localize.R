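# build a noise-free bead z-stack from a known calibration
make_bead_stack <- function(cal, z_planes, beads, fov = c(40L, 40L),
                            photons = 20000, background = 5) {
  stack <- array(0, dim = c(length(z_planes), fov[1L], fov[2L]))
  for (p in seq_along(z_planes)) {
    em <- data.frame(x = beads$x, y = beads$y, z = z_planes[p])
    stack[p, , ] <- render_frame(em, fov, cal, pixel_size = 103.8,
                                 mean_photons = photons,
                                 background = background, noise = FALSE)
  }
  stack
}

test_that("bead-stack calibration recovers the width curves within 2 nm", {
  true_cal <- synthetic_calibration(z_range = c(-700, 700))
  z_planes <- seq(-600, 600, by = 100)  # 13 planes, inside the model range
  beads <- data.frame(x = c(12, 28) * 103.8, y = c(13, 26) * 103.8)
  stack <- make_bead_stack(true_cal, z_planes, beads)
  cal <- calibrate_astigmatism(stack, z_step = 100, roi_size = 15L)
  zt <- seq(cal$z_range[1L], cal$z_range[2L], length.out = 41L)
  fit <- sigma_at(cal, zt)
  truth <- sigma_at(true_cal, zt)
  expect_lt(max(abs(fit$sigma_x - truth$sigma_x)), 2)
  expect_lt(max(abs(fit$sigma_y - truth$sigma_y)), 2)
  s0 <- sigma_at(cal, 0)
  expect_lt(abs(s0$sigma_x - s0$sigma_y), 2)  # crossing recentred to z = 0
})

test_that("calibration is rejected without astigmatism or enough planes", {
  # symmetric PSF: sigma_x == sigma_y at every z (rendered directly, since
  # such curves cannot form a valid calibration object)
  gauss_img <- function(fov, cx, cy, sigma, photons, bg) {
    mx <- diff(pnorm(103.8 * 0:fov[2L], cx, sigma))
    my <- diff(pnorm(103.8 * 0:fov[1L], cy, sigma))
    photons * (my %o% mx) + bg
  }
  z_planes <- seq(-500, 500, by = 100)
  stack <- array(0, dim = c(length(z_planes), 40L, 40L))
  for (p in seq_along(z_planes)) {
    s <- 150 * sqrt(1 + (z_planes[p] / 400)^2)
    stack[p, , ] <- gauss_img(c(40L, 40L), 20 * 103.8, 20 * 103.8, s,
                              20000, 5)
  }
  expect_error(calibrate_astigmatism(stack, 100), "astigmatism|monotone")

  beads <- data.frame(x = 20 * 103.8, y = 20 * 103.8)
  small <- make_bead_stack(synthetic_calibration(), c(-100, 0, 100), beads)
  expect_error(calibrate_astigmatism(small, 100), "9")
})

test_that("strictly symmetric sigma curves cannot form a calibration", {
  expect_error(astig_calibration(c(150, 0, 2e-4, 0, 0),
                                 c(150, 0, 2e-4, 0, 0), c(-600, 600)),
               "monotone")
})

test_that("spot detection finds isolated emitters and merges adjacent ones", {
  cal <- synthetic_calibration()
  expect_identical(nrow(detect_spots(matrix(0, 32L, 32L), 5)), 0L)

  set.seed(1)
  grid <- expand.grid(row = c(10, 25, 40), col = c(10, 25, 40))
  grid <- grid[1:9, ]
  extra <- data.frame(row = 55, col = 55)
  pos <- rbind(grid, extra)  # 10 well-separated emitters
  em <- data.frame(x = (pos$col - 0.5) * 103.8, y = (pos$row - 0.5) * 103.8,
                   z = 0)
  img <- render_frame(em, c(64L, 64L), cal, mean_photons = 5000,
                      background = 0, noise = FALSE)
  found <- detect_spots(img, 5)
  expect_identical(nrow(found), 10L)
  d <- outer(found$row, pos$row, "-")^2 + outer(found$col, pos$col, "-")^2
  expect_true(all(apply(d, 2L, min) <= 1))  # each truth matched at its pixel

  # two emitters one pixel apart merge into a single candidate
  pair <- data.frame(x = c(15.5, 16.5) * 103.8, y = c(16, 16) * 103.8, z = 0)
  img2 <- render_frame(pair, c(32L, 32L), cal, mean_photons = 5000,
                       background = 0, noise = FALSE)
  expect_identical(nrow(detect_spots(img2, 5)), 1L)
})

test_that("noise-free spot fits are unbiased and recover offsets", {
  cal <- synthetic_calibration()
  px <- 103.8
  centred <- data.frame(x = 7.5 * px, y = 7.5 * px, z = 150)
  roi <- render_frame(centred, c(15L, 15L), cal, mean_photons = 2000,
                      background = 3, noise = FALSE)
  fit <- fit_spot(roi, pixel_size = px)
  expect_true(fit$converged)
  expect_lt(abs(fit$x / px - 7.5), 0.01)
  expect_lt(abs(fit$y / px - 7.5), 0.01)
  expect_lt(abs(fit$photons - 2000) / 2000, 0.01)

  off <- data.frame(x = (7.5 + 1.3) * px, y = (7.5 - 0.7) * px, z = 150)
  roi2 <- render_frame(off, c(15L, 15L), cal, mean_photons = 2000,
                       background = 3, noise = FALSE)
  fit2 <- fit_spot(roi2, pixel_size = px)
  expect_lt(abs(fit2$x / px - 8.8), 0.02)
  expect_lt(abs(fit2$y / px - 6.8), 0.02)

  expect_error(fit_spot(matrix(0, 11L, 11L)), "zero")
  expect_error(fit_spot(matrix(c(NA, 1:120), 11L, 11L)), "NA")
})

test_that("z assignment inverts the calibration within 1 nm", {
  cal <- synthetic_calibration()
  zs <- seq(cal$z_range[1L] + 20, cal$z_range[2L] - 20, by = 40)
  sg <- sigma_at(cal, zs)
  za <- assign_z(sg$sigma_x, sg$sigma_y, cal)
  expect_true(all(za$valid))
  expect_lt(max(abs(za$z - zs)), 1)

  # the crossing point maps to z = 0
  sg0 <- sigma_at(cal, 0)
  expect_lt(abs(assign_z(sg0$sigma_x, sg0$sigma_y, cal)$z), 0.5)

  # a width pair far from the achievable set is invalid
  bad <- assign_z(5000, 5000, cal)
  expect_false(bad$valid)
})

test_that("localizing a sparse movie recovers the truth with high recall/precision", {
  cal <- synthetic_calibration()
  px <- 103.8
  set.seed(11)
  n_frames <- 25L
  truth <- vector("list", n_frames)
  stack <- array(0, dim = c(n_frames, 48L, 48L))
  for (f in seq_len(n_frames)) {
    k <- sample(2:5, 1L)
    repeat {
      em <- data.frame(x = runif(k, 8, 40) * px, y = runif(k, 8, 40) * px,
                       z = runif(k, -350, 350))
      if (k < 2L || min(dist(cbind(em$x, em$y))) > 10 * px) break
    }
    truth[[f]] <- cbind(frame = f - 1L, em)
    stack[f, , ] <- render_frame(em, c(48L, 48L), cal, mean_photons = 3000,
                                 background = 8,
                                 camera = list(offset = 100, gain = 1),
                                 noise = TRUE)
  }
  truth <- do.call(rbind, truth)
  cfg <- load_config(NULL)
  loc <- localize_movie(stack, cal, cfg, camera_offset = 100,
                        detection_threshold = 4)
  # match localizations to truth within 250 nm laterally, frame by frame
  tp <- 0L
  for (f in unique(truth$frame)) {
    tr <- truth[truth$frame == f, ]
    lo <- loc[loc$frame == f, ]
    if (nrow(lo) == 0L) next
    d <- sqrt(outer(tr$x, lo$x, "-")^2 + outer(tr$y, lo$y, "-")^2)
    while (nrow(d) > 0L && ncol(d) > 0L && min(d) <= 250) {
      k <- which(d == min(d), arr.ind = TRUE)[1L, ]
      tp <- tp + 1L
      d <- d[-k[1L], -k[2L], drop = FALSE]
    }
  }
  recall <- tp / nrow(truth)
  precision <- tp / nrow(loc)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  # determinism: running the same movie twice gives the identical table
  loc2 <- localize_movie(stack, cal, cfg, camera_offset = 100,
                         detection_threshold = 4)
  expect_identical(as.data.frame(loc), as.data.frame(loc2))

  empty <- localize_movie(array(100, dim = c(3L, 32L, 32L)), cal, cfg,
                          camera_offset = 100)
  expect_identical(nrow(empty), 0L)
})

test_that("filtering discards exactly the non-compliant rows and reports them", {
  set.seed(3)
  n <- 1000L
  photons <- rep(1500, n); z <- rep(0, n)
  bad <- sample(n, 137L)
  flip_photon <- bad[1:70]
  flip_z <- bad[71:137]
  photons[flip_photon] <- 100
  z[flip_z] <- 900
  tab <- localization_table(data.frame(
    x = runif(n), y = runif(n), z = z, frame = 0L, photons = photons,
    sigma_x = 150, sigma_y = 150))
  out <- suppressMessages(filter_localizations(tab, min_photons = 500,
                                               axial_halfwidth = 700))
  expect_identical(nrow(out), 863L)
  expect_identical(attr(out, "discarded"), 137L)
  expect_identical(nrow(out) + attr(out, "discarded"), nrow(tab))

  ident <- suppressMessages(filter_localizations(tab, min_photons = 0,
                                                 axial_halfwidth = Inf))
  expect_identical(nrow(ident), n)
})
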