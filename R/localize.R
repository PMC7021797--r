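# Astigmatic 3D localization: a cylindrical lens makes the PSF width
# z-dependent and anisotropic; sigma_x(z), sigma_y(z) calibrated on bead
# stacks encode depth. Spots are fit with a pixel-integrated elliptical
# Gaussian by Poisson maximum likelihood.

#' Astigmatism calibration object
#'
#' Holds quartic polynomial models of the defocus curves `sigma_x(z)` and
#' `sigma_y(z)` (nm), valid over `z_range`, with z = 0 at the crossing point
#' where the two widths are equal. The difference `sigma_x - sigma_y` must be
#' strictly monotone over the valid range, otherwise z assignment would be
#' ambiguous and the calibration is rejected.
#'
#' @param coef_x,coef_y polynomial coefficients, ascending degree (length 5).
#' @param z_range c(zmin, zmax) nm of validity.
#' @return an `astig_calibration`.
#' @export
astig_calibration <- function(coef_x, coef_y, z_range) {
  stopifnot(length(coef_x) == 5L, length(coef_y) == 5L,
            length(z_range) == 2L, z_range[1L] < z_range[2L])
  cal <- structure(list(coef_x = as.numeric(coef_x),
                        coef_y = as.numeric(coef_y),
                        z_range = as.numeric(z_range)),
                   class = "astig_calibration")
  zs <- seq(z_range[1L], z_range[2L], length.out = 501L)
  sg <- sigma_at(cal, zs)
  if (any(sg$sigma_x <= 0) || any(sg$sigma_y <= 0)) {
    stop("calibration rejected: sigma curves not positive over valid range")
  }
  d <- sg$sigma_x - sg$sigma_y
  dd <- diff(d)
  if (!(all(dd > 0) || all(dd < 0))) {
    stop("calibration rejected: sigma_x - sigma_y not strictly monotone ",
         "over the valid range (no usable astigmatism)")
  }
  cal
}

#' Evaluate the calibration curves
#' @param calibration an [astig_calibration()]
#' @param z axial position(s), nm
#' @return list with vectors `sigma_x`, `sigma_y` (nm)
#' @export
sigma_at <- function(calibration, z) {
  pow <- outer(z, 0:4, `^`)
  list(sigma_x = as.numeric(pow %*% calibration$coef_x),
       sigma_y = as.numeric(pow %*% calibration$coef_y))
}

#' @export
print.astig_calibration <- function(x, ...) {
  sg0 <- sigma_at(x, 0)
  cat(sprintf(
    "Astigmatism calibration: valid z in [%g, %g] nm, sigma(0) = %.1f nm\n",
    x$z_range[1L], x$z_range[2L], sg0$sigma_x))
  invisible(x)
}

#' Synthetic astigmatism calibration
#'
#' A defocus model in common use for astigmatic imaging:
#' `sigma_x(z) = sigma0 * sqrt(1 + ((z - gamma)/d)^2)` and symmetrically for
#' y with `+gamma`, converted to the package's quartic-polynomial calibration
#' form by least squares on a fine grid. Serves as the image-formation model
#' of the simulator and as a known-truth calibration in tests.
#'
#' @param z_range valid axial range (nm).
#' @param sigma0 in-focus PSF width (nm).
#' @param gamma focal-plane offset of the two axes (nm).
#' @param d depth scale of defocusing (nm).
#' @return an [astig_calibration()]
#' @export
synthetic_calibration <- function(z_range = c(-600, 600), sigma0 = 150,
                                  gamma = 400, d = 500) {
  zs <- seq(z_range[1L], z_range[2L], length.out = 241L)
  sx <- sigma0 * sqrt(1 + ((zs - gamma) / d)^2)
  sy <- sigma0 * sqrt(1 + ((zs + gamma) / d)^2)
  astig_calibration(.fit_quartic(zs, sx), .fit_quartic(zs, sy), z_range)
}

.fit_quartic <- function(z, sigma) {
  stats::lm.fit(outer(z, 0:4, `^`), sigma)$coefficients
}

#' Calibrate astigmatism from a bead z-stack
#'
#' Fluorescent beads on a coverslip are stepped through focus; each plane is
#' fit per bead with the elliptical-Gaussian model, widths are pooled across
#' beads, and quartic polynomials are fit to `sigma_x(z)` and `sigma_y(z)`.
#' The z axis is re-centred on the crossing point where the two widths are
#' equal. Calibrations whose width difference is not strictly monotone (no
#' usable astigmatism) are rejected.
#'
#' @param bead_stack array planes x rows x cols, photons.
#' @param z_step axial step between planes (nm).
#' @param pixel_size nm per pixel.
#' @param detection_threshold spot-detection threshold for finding beads in
#'   the central plane.
#' @param roi_size fitting ROI side (odd pixels).
#' @param margin fraction of the scanned range trimmed from each end of the
#'   valid range (defocus fits degrade far from focus).
#' @return an [astig_calibration()]
#' @export
calibrate_astigmatism <- function(bead_stack, z_step, pixel_size = 103.8,
                                  detection_threshold = 5, roi_size = 11L,
                                  margin = 0.1) {
  n_planes <- dim(bead_stack)[1L]
  if (n_planes < 9L) {
    stop("need at least 9 z planes for calibration, got ", n_planes)
  }
  mid <- (n_planes + 1L) %/% 2L
  beads <- detect_spots(bead_stack[mid, , ], detection_threshold)
  if (nrow(beads) == 0L) stop("no beads detected in the central plane")
  half <- roi_size %/% 2L
  z_stack <- (seq_len(n_planes) - (n_planes + 1) / 2) * z_step
  sx <- matrix(NA_real_, n_planes, nrow(beads))
  sy <- matrix(NA_real_, n_planes, nrow(beads))
  for (b in seq_len(nrow(beads))) {
    r0 <- beads$row[b]; c0 <- beads$col[b]
    if (r0 - half < 1L || r0 + half > dim(bead_stack)[2L] ||
        c0 - half < 1L || c0 + half > dim(bead_stack)[3L]) next
    for (p in seq_len(n_planes)) {
      roi <- bead_stack[p, (r0 - half):(r0 + half), (c0 - half):(c0 + half)]
      fit <- tryCatch(fit_spot(roi, pixel_size = pixel_size),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$converged) {
        sx[p, b] <- fit$sigma_x
        sy[p, b] <- fit$sigma_y
      }
    }
  }
  mx <- rowMeans(sx, na.rm = TRUE)
  my <- rowMeans(sy, na.rm = TRUE)
  ok <- is.finite(mx) & is.finite(my)
  if (sum(ok) < 9L) stop("too few usable calibration planes after fitting")
  px <- .fit_quartic(z_stack[ok], mx[ok])
  py <- .fit_quartic(z_stack[ok], my[ok])
  # crossing point sigma_x = sigma_y
  zr <- range(z_stack[ok])
  zs <- seq(zr[1L], zr[2L], length.out = 2001L)
  d <- as.numeric(outer(zs, 0:4, `^`) %*% (px - py))
  sgn <- which(d[-1L] * d[-length(d)] <= 0)
  if (length(sgn) == 0L) {
    stop("calibration rejected: sigma_x and sigma_y never cross ",
         "(no astigmatism in the bead stack)")
  }
  z0 <- zs[sgn[1L]]
  # re-centre: refit the quartics on the shifted axis over the trimmed range
  trim <- margin * diff(zr)
  zv <- seq(zr[1L] + trim, zr[2L] - trim, length.out = 1001L)
  vx <- as.numeric(outer(zv, 0:4, `^`) %*% px)
  vy <- as.numeric(outer(zv, 0:4, `^`) %*% py)
  astig_calibration(.fit_quartic(zv - z0, vx), .fit_quartic(zv - z0, vy),
                    range(zv - z0))
}

# ---- spot detection ------------------------------------------------------

# separable Gaussian blur with edge replication
.gauss_blur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) {
    rbind(m[rep(1L, n), , drop = FALSE], m, m[rep(nrow(m), n), , drop = FALSE])
  }
  conv_cols <- function(m) {
    p <- pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * p[i:(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

#' Detect candidate spots in one frame
#'
#' Difference-of-Gaussians band-pass followed by 8-connected local maxima
#' above `threshold` times a robust noise estimate (MAD) of the filtered
#' image; candidates closer than `min_sep` pixels are merged, keeping the
#' brighter one.
#'
#' @param frame 2D matrix, photons.
#' @param threshold detection threshold in robust-noise SDs.
#' @param sigma_small,sigma_large DoG kernel widths (px).
#' @param min_sep minimum candidate separation (px).
#' @param margin border width (px) in which candidates are ignored.
#' @return data.frame `row`, `col` (1-based pixel indices), `value`.
#' @export
detect_spots <- function(frame, threshold = 5, sigma_small = 1.2,
                         sigma_large = 3, min_sep = 4, margin = 3L) {
  dog <- .gauss_blur(frame, sigma_small) - .gauss_blur(frame, sigma_large)
  noise <- stats::mad(dog)
  cut <- threshold * max(noise, 1e-12)
  nr <- nrow(dog); nc <- ncol(dog)
  if (nr < 3L || nc < 3L) return(data.frame(row = integer(0),
                                            col = integer(0),
                                            value = numeric(0)))
  core <- dog[2:(nr - 1L), 2:(nc - 1L)]
  is_max <- core > cut
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- dog[(2:(nr - 1L)) + dr, (2:(nc - 1L)) + dc]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  }
  cand <- data.frame(row = idx[, 1L] + 1L, col = idx[, 2L] + 1L,
                     value = core[idx])
  cand <- cand[cand$row > margin & cand$row <= nr - margin &
                 cand$col > margin & cand$col <= nc - margin, , drop = FALSE]
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (cand$row[i] - prev$row)^2 + (cand$col[i] - prev$col)^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- elliptical-Gaussian Poisson MLE ------------------------------------

#' Fit one spot with the astigmatic elliptical-Gaussian model
#'
#' Maximum-likelihood fit under Poisson noise of the pixel-integrated model
#' `mu_ij = b + N * Gx_j * Gy_i`, where `Gx`, `Gy` are Gaussian masses over
#' pixel edges. Minimizes `sum(mu - c * log(mu))` with box constraints
#' (L-BFGS-B). Non-converged fits are returned with `converged = FALSE`,
#' never silently dropped.
#'
#' @param roi square ROI matrix (photons), odd side length.
#' @param init optional list with starting values `x`, `y` (px, ROI-local),
#'   `sigma` (px), `photons`, `background`.
#' @param pixel_size nm per pixel.
#' @return a `spot_fit`: `x`, `y` (nm from the ROI's top-left corner),
#'   `sigma_x`, `sigma_y` (nm), `photons`, `background` (photons/px),
#'   `converged`, `residual` (RMS per pixel).
#' @export
fit_spot <- function(roi, init = NULL, pixel_size = 103.8) {
  if (any(is.na(roi))) stop("ROI contains NA/NaN pixels")
  if (all(roi == 0)) stop("all-zero ROI")
  nr <- nrow(roi); nc <- ncol(roi)
  b0 <- if (!is.null(init$background)) init$background else {
    edges <- c(roi[1L, ], roi[nr, ], roi[, 1L], roi[, nc])
    stats::median(edges)
  }
  sub <- pmax(roi - b0, 0)
  tot <- sum(sub)
  x0 <- if (!is.null(init$x)) init$x else {
    if (tot > 0) sum(sub %*% (seq_len(nc) - 0.5)) / tot else nc / 2
  }
  y0 <- if (!is.null(init$y)) init$y else {
    if (tot > 0) sum((seq_len(nr) - 0.5) %*% sub) / tot else nr / 2
  }
  s0 <- if (!is.null(init$sigma)) init$sigma else 1.3
  A0 <- max(if (!is.null(init$photons)) init$photons else tot, 10)
  nll <- function(p) {
    mx <- diff(stats::pnorm(seq(0L, nc), p[1L], p[3L]))
    my <- diff(stats::pnorm(seq(0L, nr), p[2L], p[4L]))
    mu <- p[6L] + p[5L] * (my %o% mx)
    mu <- pmax(mu, 1e-12)
    sum(mu - roi * log(mu))
  }
  start <- c(x0, y0, s0, s0, A0, max(b0, 1e-4))
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(0, 0, 0.3, 0.3, 1e-6, 0),
                      upper = c(nc, nr, nc, nr, Inf, Inf),
                      control = list(maxit = 400L, factr = 1e4,
                                     parscale = c(1, 1, 1, 1, A0,
                                                  max(b0, 0.1))))
  p <- fit$par
  mx <- diff(stats::pnorm(seq(0L, nc), p[1L], p[3L]))
  my <- diff(stats::pnorm(seq(0L, nr), p[2L], p[4L]))
  mu <- p[6L] + p[5L] * (my %o% mx)
  structure(list(x = p[1L] * pixel_size, y = p[2L] * pixel_size,
                 sigma_x = p[3L] * pixel_size, sigma_y = p[4L] * pixel_size,
                 photons = p[5L], background = p[6L],
                 converged = fit$convergence == 0L,
                 residual = sqrt(mean((roi - mu)^2))),
            class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf(
    "Spot fit: (%.1f, %.1f) nm, sigma (%.1f, %.1f) nm, %.0f photons%s\n",
    x$x, x$y, x$sigma_x, x$sigma_y, x$photons,
    if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

# ---- z assignment --------------------------------------------------------

#' Assign axial positions from fitted PSF widths
#'
#' Finds the z minimizing the square-root width metric
#' `(sqrt(sx) - sqrt(sx_cal(z)))^2 + (sqrt(sy) - sqrt(sy_cal(z)))^2`
#' by a 1 nm grid search over the calibration's valid range with parabolic
#' refinement. Ties break toward smaller |z|. A fit is invalid when the
#' minimum sits on the range boundary or the residual mismatch exceeds
#' `max_mismatch` (the width pair is not achievable by the calibration).
#'
#' @param sigma_x,sigma_y fitted widths (nm), vectorized.
#' @param calibration an [astig_calibration()].
#' @param max_mismatch maximum allowed sqrt-width mismatch
#'   (sqrt-nm units).
#' @return data.frame `z` (nm), `valid`, `mismatch`.
#' @export
assign_z <- function(sigma_x, sigma_y, calibration, max_mismatch = 2) {
  stopifnot(length(sigma_x) == length(sigma_y))
  zg <- seq(calibration$z_range[1L], calibration$z_range[2L], by = 1)
  sg <- sigma_at(calibration, zg)
  # grid ordered by |z| so the first minimum breaks ties toward small |z|
  ord <- order(abs(zg), zg)
  rx <- sqrt(sg$sigma_x[ord]); ry <- sqrt(sg$sigma_y[ord])
  n <- length(sigma_x)
  z <- numeric(n); valid <- logical(n); mism <- numeric(n)
  sxr <- sqrt(sigma_x); syr <- sqrt(sigma_y)
  for (i in seq_len(n)) {
    d <- (sxr[i] - rx)^2 + (syr[i] - ry)^2
    k <- which.min(d)            # first minimum in |z| order
    gi <- ord[k]                 # index on the monotone grid
    mism[i] <- sqrt(d[k])
    at_edge <- gi == 1L || gi == length(zg)
    if (!at_edge) {
      # parabolic refinement on the monotone grid
      dg <- (sxr[i] - sqrt(sg$sigma_x))^2 + (syr[i] - sqrt(sg$sigma_y))^2
      denom <- dg[gi - 1L] - 2 * dg[gi] + dg[gi + 1L]
      delta <- if (denom > 0) 0.5 * (dg[gi - 1L] - dg[gi + 1L]) / denom else 0
      z[i] <- zg[gi] + max(min(delta, 0.5), -0.5)
    } else {
      z[i] <- zg[gi]
    }
    valid[i] <- !at_edge && mism[i] <= max_mismatch
  }
  data.frame(z = z, valid = valid, mismatch = mism)
}

# ---- movie localization --------------------------------------------------

#' Localize a movie
#'
#' Runs detect / fit / z-assign over every frame of a stack and assembles an
#' acquisition-frame localization table. Deterministic given its inputs.
#' Candidates whose fitting ROI would be clipped by the frame edge are
#' skipped; non-converged or invalid-z fits are kept and flagged in the
#' `converged` and `z_valid` columns.
#'
#' @param stack array frames x rows x cols of camera counts.
#' @param calibration an [astig_calibration()].
#' @param config a `pipeline_config` (see [load_config()]); supplies
#'   `pixel_size` and `frames_per_stack`.
#' @param camera_offset,camera_gain linear camera model used to convert
#'   counts to photons before fitting.
#' @param detection_threshold see [detect_spots()].
#' @param roi_size fitting ROI side (odd pixels).
#' @return a [localization_table()] with `frame_kind = "acquisition"`.
#' @export
localize_movie <- function(stack, calibration, config = load_config(),
                           camera_offset = 100, camera_gain = 1,
                           detection_threshold = 5, roi_size = 11L) {
  stopifnot(length(dim(stack)) == 3L)
  half <- roi_size %/% 2L
  fps <- config$frames_per_stack
  px <- config$pixel_size
  rows <- vector("list", dim(stack)[1L])
  for (f in seq_len(dim(stack)[1L])) {
    img <- counts_to_photons(stack[f, , ], camera_offset, camera_gain)
    cand <- detect_spots(img, detection_threshold)
    if (nrow(cand) == 0L) next
    frame_rows <- vector("list", nrow(cand))
    for (k in seq_len(nrow(cand))) {
      r0 <- cand$row[k]; c0 <- cand$col[k]
      if (r0 - half < 1L || r0 + half > nrow(img) ||
          c0 - half < 1L || c0 + half > ncol(img)) next
      roi <- img[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
      fit <- tryCatch(fit_spot(roi, pixel_size = px),
                      error = function(e) NULL)
      if (is.null(fit)) next
      zf <- assign_z(fit$sigma_x, fit$sigma_y, calibration)
      frame_rows[[k]] <- data.frame(
        x = (c0 - half - 1L) * px + fit$x,
        y = (r0 - half - 1L) * px + fit$y,
        z = zf$z,
        frame = f - 1L,
        photons = fit$photons, background = fit$background,
        sigma_x = fit$sigma_x, sigma_y = fit$sigma_y,
        converged = fit$converged, z_valid = zf$valid)
    }
    rows[[f]] <- do.call(rbind, frame_rows)
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L) {
    return(empty_localization_table("acquisition"))
  }
  localization_table(df, frame_kind = "acquisition", frames_per_stack = fps)
}

#' Filter localizations on photon count and axial range
#'
#' Keeps rows with `photons >= min_photons` and `|z| <= axial_halfwidth`
#' (the axial range illuminated by the light sheet, acquisition frame). The
#' number of discarded rows is reported as attribute `discarded` and via a
#' message, so no row is ever silently dropped.
#'
#' @param table acquisition-frame [localization_table()].
#' @param min_photons minimum photon count.
#' @param axial_halfwidth half of the accepted axial range (nm).
#' @return the filtered table with attribute `discarded`.
#' @export
filter_localizations <- function(table, min_photons = 500,
                                 axial_halfwidth = 700) {
  if (frame_kind(table) != "acquisition") {
    stop("filter_localizations expects an acquisition-frame table")
  }
  keep_photons <- if (min_photons > 0) {
    !is.na(table$photons) & table$photons >= min_photons
  } else {
    rep(TRUE, nrow(table))
  }
  keep <- keep_photons & abs(table$z) <= axial_halfwidth
  out <- table[keep, , drop = FALSE]
  discarded <- nrow(table) - nrow(out)
  attr(out, "frame_kind") <- frame_kind(table)
  attr(out, "discarded") <- discarded
  message(sprintf("filter_localizations: kept %d of %d (%d discarded)",
                  nrow(out), nrow(table), discarded))
  out
}
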