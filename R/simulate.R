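# Synthetic-data generators. These define the study conditions under which
# the pipeline is validated: blinking emitters on membrane surfaces of two
# adherent cells, astigmatic image formation under sawtooth scanning,
# Brownian receptor motion, and exponential FRAP recovery.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Specify a synthetic two-cell scene
#'
#' The minimal geometry exhibiting the three membrane regions the density
#' analysis distinguishes: each cell is a spherical cap resting on the
#' coverslip (basal disc at z' = 0, spherical apical surface), truncated by a
#' vertical contact plane where the two cells meet; the flattened contact
#' discs, a small `gap` apart, form the cell-cell interface. Emitters are laid
#' down per region as a Poisson process at the configured surface density.
#'
#' All lengths in nm; densities in emitters/um^2.
#'
#' @param cap_radius sphere radius of each cell.
#' @param cap_height cell height above the coverslip (must be <= 2*cap_radius).
#' @param contact_offset distance from each cell's axis to its flat contact
#'   face (< cap_radius); the face is the chord plane y = +/- contact_offset.
#' @param gap membrane-to-membrane distance across the interface.
#' @param interface_dist membrane points within this distance of the other
#'   cell's membrane count as interface; must exceed `gap` for the contact
#'   discs to qualify.
#' @param rho_basal,rho_apical,rho_interface region densities (emitters/um^2).
#' @param mean_photons mean photon yield per blink.
#' @param background mean background (photons/pixel).
#' @param mean_on_time mean blink on-duration (frames).
#' @param activation_rate per-emitter activation probability per frame.
#' @param camera_offset,camera_gain,read_noise linear camera model
#'   (counts = offset + gain*photons + read noise).
#' @param n_cells 1 or 2 (1 drops the contact truncation and the interface).
#' @return a `scene_spec` (validated list).
#' @export
scene_spec <- function(cap_radius = 4000, cap_height = 6000,
                       contact_offset = 3000, gap = 20, interface_dist = 50,
                       rho_basal = 139, rho_apical = 361,
                       rho_interface = 1234,
                       mean_photons = 2000, background = 10,
                       mean_on_time = 3, activation_rate = 0.01,
                       camera_offset = 100, camera_gain = 1, read_noise = 0,
                       n_cells = 2L) {
  s <- as.list(environment())
  s$n_cells <- as.integer(n_cells)
  if (cap_height > 2 * cap_radius) {
    stop("cap_height must be <= 2 * cap_radius")
  }
  if (any(c(rho_basal, rho_apical, rho_interface) < 0)) {
    stop("region densities must be >= 0")
  }
  if (s$n_cells == 2L) {
    if (contact_offset <= 0 || contact_offset >= cap_radius) {
      stop("contact_offset must lie in (0, cap_radius)")
    }
    if (gap < 0 || gap > interface_dist) {
      stop("gap must lie in [0, interface_dist] so contact discs qualify ",
           "as interface")
    }
  }
  structure(s, class = "scene_spec")
}

# sphere centre height above the coverslip
.scene_z0 <- function(scene) scene$cap_height - scene$cap_radius

#' Membrane region areas of a scene
#'
#' Deterministic numerical quadrature of the per-cell region areas (um^2):
#' basal disc (with contact chord cut), apical spherical surface, and the flat
#' contact disc (interface).
#'
#' @param scene a [scene_spec()]
#' @return named numeric vector (um^2) with elements basal, apical, interface.
#' @export
region_areas <- function(scene) {
  R <- scene$cap_radius; z0 <- .scene_z0(scene)
  yc <- if (scene$n_cells == 2L) scene$contact_offset else Inf
  a <- sqrt(R^2 - z0^2)  # basal disc radius
  # basal: disc of radius a, cut at chord y = yc
  basal <- .disc_chord_area(a, yc)
  # apical: sphere surface with z in (0, h], y < yc; area element 2*pi*R dz
  # scaled by the fraction of azimuth with y < yc at each height
  zs <- seq(1e-9, scene$cap_height - 1e-9, length.out = 20001)
  r_ring <- sqrt(pmax(R^2 - (zs - z0)^2, 0))
  frac <- ifelse(yc >= r_ring, 1,
                 1 - acos(pmin(pmax(yc / r_ring, -1), 1)) / pi)
  apical <- 2 * pi * R * mean(frac) * (scene$cap_height - 2e-9)
  # interface: contact disc {x^2 + (z - z0)^2 <= rc^2, z >= 0} in plane y = yc
  interface <- 0
  if (scene$n_cells == 2L) {
    rc <- sqrt(R^2 - yc^2)
    interface <- .disc_chord_area(rc, z0)  # cut at z = 0, i.e. chord at -z0
  }
  c(basal = basal, apical = apical, interface = interface) / 1e6
}

# area of a disc of radius r restricted to {coordinate < c}, c measured from
# the disc centre (c may be negative)
.disc_chord_area <- function(r, c) {
  if (c >= r) return(pi * r^2)
  if (c <= -r) return(0)
  # full area minus circular segment beyond the chord
  seg <- r^2 * acos(c / r) - c * sqrt(r^2 - c^2)
  pi * r^2 - seg
}

#' Sample ground-truth emitters on the membrane of a scene
#'
#' Per region and cell, the emitter count is Poisson(density x region area)
#' and positions are uniform on the surface patch, so every emitter lies on
#' the membrane exactly.
#'
#' @param scene a [scene_spec()]
#' @param seed integer seed (reproducible draws).
#' @return a `ground_truth` data.frame: `id`, biological-frame `x`, `y`, `z`
#'   (nm), `region` in basal/apical/interface, `cell` (1 or 2), with the
#'   per-region areas attached as attribute `areas_um2`.
#' @export
sample_membrane_emitters <- function(scene, seed = NULL) {
  areas <- region_areas(scene)
  with_seed(seed, {
    pieces <- list()
    for (cell in seq_len(scene$n_cells)) {
      pieces[[length(pieces) + 1L]] <-
        .sample_cell(scene, areas, cell)
    }
    df <- do.call(rbind, pieces)
    if (is.null(df)) {
      df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       region = character(0), cell = integer(0))
    }
    df$id <- seq_len(nrow(df))
    rownames(df) <- NULL
    structure(df[, c("id", "x", "y", "z", "region", "cell")],
              areas_um2 = areas, class = c("ground_truth", "data.frame"))
  })
}

# sample one cell; cell 2 is cell 1 mirrored across the contact plane and
# shifted by the gap
.sample_cell <- function(scene, areas, cell) {
  R <- scene$cap_radius; z0 <- .scene_z0(scene)
  yc <- if (scene$n_cells == 2L) scene$contact_offset else Inf
  a <- sqrt(R^2 - z0^2)
  out <- list()

  n_b <- stats::rpois(1L, scene$rho_basal * areas[["basal"]])
  if (n_b > 0L) {
    p <- .runif_disc_chord(n_b, a, yc)
    out$basal <- data.frame(x = p[, 1L], y = p[, 2L], z = rep(0, n_b),
                            region = "basal")
  }

  n_a <- stats::rpois(1L, scene$rho_apical * areas[["apical"]])
  if (n_a > 0L) {
    # uniform on the sphere band z in (0, h]: z uniform, azimuth uniform,
    # rejected where y >= yc (truncated by the contact plane)
    pts <- matrix(numeric(0), ncol = 3L)
    while (nrow(pts) < n_a) {
      m <- max(2L * (n_a - nrow(pts)), 16L)
      z <- stats::runif(m, 0, scene$cap_height)
      phi <- stats::runif(m, 0, 2 * pi)
      r <- sqrt(pmax(R^2 - (z - z0)^2, 0))
      x <- r * cos(phi); y <- r * sin(phi)
      ok <- y < yc
      pts <- rbind(pts, cbind(x[ok], y[ok], z[ok]))
    }
    pts <- pts[seq_len(n_a), , drop = FALSE]
    out$apical <- data.frame(x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                             region = "apical")
  }

  if (scene$n_cells == 2L) {
    n_i <- stats::rpois(1L, scene$rho_interface * areas[["interface"]])
    if (n_i > 0L) {
      rc <- sqrt(R^2 - yc^2)
      p <- .runif_disc_chord(n_i, rc, z0, lower = TRUE)
      # disc lives in the plane y = yc with in-plane axes (x, z - z0)
      out$interface <- data.frame(x = p[, 1L], y = rep(yc, n_i),
                                  z = p[, 2L] + z0, region = "interface")
    }
  }

  df <- do.call(rbind, out)
  if (is.null(df)) return(NULL)
  df$cell <- cell
  if (cell == 2L) {
    # mirror across the contact plane, offset by the gap
    df$y <- 2 * scene$contact_offset + scene$gap - df$y
  }
  df
}

# uniform points on a disc of radius r restricted to {second coord < c}
# (lower = TRUE restricts to {second coord > -c}, used for the z >= 0 cut)
.runif_disc_chord <- function(n, r, c, lower = FALSE) {
  pts <- matrix(numeric(0), ncol = 2L)
  while (nrow(pts) < n) {
    m <- max(2L * (n - nrow(pts)), 16L)
    u <- r * sqrt(stats::runif(m))
    phi <- stats::runif(m, 0, 2 * pi)
    x <- u * cos(phi); y <- u * sin(phi)
    ok <- if (lower) y > -c else y < c
    pts <- rbind(pts, cbind(x[ok], y[ok]))
  }
  pts[seq_len(n), , drop = FALSE]
}

# ---- blinking kinetics ---------------------------------------------------

#' Simulate photoswitching (blinking) of emitters
#'
#' Each emitter activates as a memoryless process (probability
#' `activation_rate` per dark frame), stays on for a Geometric number of
#' frames with the given mean (support >= 1), then bleaches, or with
#' probability `recurrence` returns to the dark state and may activate again.
#'
#' @param truth a `ground_truth` (or anything with an `id` column / a count).
#' @param n_frames number of frames to simulate.
#' @param mean_on_time mean on-duration in frames.
#' @param activation_rate per-frame activation probability while dark.
#' @param recurrence probability of surviving an off-switch instead of
#'   bleaching (0 = single blink per emitter).
#' @param on_time_dist `"geometric"` (default) or `"fixed"` (every on-period
#'   lasts exactly `mean_on_time` frames).
#' @param seed integer seed.
#' @return list with `events` (data.frame emitter, start, end; frames
#'   0-based, inclusive) and `active` (list of length `n_frames` of emitter id
#'   vectors).
#' @export
simulate_blinking <- function(truth, n_frames, mean_on_time = 3,
                              activation_rate = 0.01, recurrence = 0,
                              on_time_dist = c("geometric", "fixed"),
                              seed = NULL) {
  on_time_dist <- match.arg(on_time_dist)
  stopifnot(mean_on_time >= 1, activation_rate >= 0, activation_rate <= 1,
            recurrence >= 0, recurrence <= 1)
  # recurrence = 1 models the photoswitching quasi-equilibrium of dSTORM:
  # emitters keep cycling for the whole movie and per-frame occupancy is
  # stationary at roughly activation_rate * mean_on_time
  ids <- if (is.data.frame(truth)) truth$id else seq_len(truth)
  n_em <- length(ids)
  with_seed(seed, {
    chunks <- list()
    if (activation_rate > 0 && n_em > 0L) {
      # number of on-cycles each emitter survives: 1 + Geometric(1 - p_recur)
      budget <- if (recurrence == 0) {
        rep(1, n_em)
      } else if (recurrence < 1) {
        stats::rgeom(n_em, 1 - recurrence) + 1
      } else {
        rep(Inf, n_em)
      }
      clock <- rep(0L, n_em)   # next dark frame per emitter
      cycles <- rep(0, n_em)
      alive <- rep(TRUE, n_em)
      while (any(alive)) {
        a <- which(alive)
        wait <- stats::rgeom(length(a), activation_rate)
        dur <- if (on_time_dist == "fixed") {
          rep(as.integer(mean_on_time), length(a))
        } else {
          stats::rgeom(length(a), 1 / mean_on_time) + 1L
        }
        start <- clock[a] + wait
        ok <- start < n_frames
        if (any(ok)) {
          chunks[[length(chunks) + 1L]] <- data.frame(
            emitter = ids[a[ok]], start = start[ok],
            end = pmin(start[ok] + dur[ok] - 1L, n_frames - 1L))
        }
        clock[a] <- start + dur
        cycles[a] <- cycles[a] + 1
        alive[a] <- ok & cycles[a] < budget[a] & clock[a] < n_frames
      }
    }
    events <- if (length(chunks) > 0L) {
      ev <- do.call(rbind, chunks)
      ev[order(ev$emitter, ev$start), , drop = FALSE]
    } else {
      data.frame(emitter = integer(0), start = integer(0), end = integer(0))
    }
    rownames(events) <- NULL
    active <- rep(list(integer(0)), n_frames)
    if (nrow(events) > 0L) {
      lens <- events$end - events$start + 1L
      fr <- sequence(lens) - 1L + rep(events$start, lens) + 1L
      em <- rep(events$emitter, lens)
      filled <- split(em, fr)
      active[as.integer(names(filled))] <- filled
    }
    list(events = events, active = active)
  })
}

# ---- image formation -----------------------------------------------------

#' Render one camera frame of active emitters
#'
#' Each emitter contributes a pixel-integrated elliptical Gaussian with
#' widths `sigma_x(z)`, `sigma_y(z)` taken from the astigmatism calibration,
#' with an integrated photon count that is Poisson around `mean_photons`
#' (exact when `noise = FALSE`). Poisson background is added, then the linear
#' camera model. Emitters whose z lies outside the calibration range are
#' skipped; the number skipped is reported in attribute `n_skipped`.
#'
#' @param emitters data.frame with `x`, `y`, `z` in nm; x runs along columns,
#'   y along rows, origin at the frame's top-left corner.
#' @param fov c(rows, cols) in pixels.
#' @param calibration an [astig_calibration()].
#' @param pixel_size nm per pixel.
#' @param mean_photons mean photons per emitter.
#' @param background mean background photons/pixel.
#' @param camera `NULL` for a photon-space image, or
#'   `list(offset=, gain=, read_noise=)` for integer camera counts.
#' @param noise emit Poisson photon/background noise (and camera read noise)?
#' @return matrix rows x cols (photons, or counts when `camera` is given).
#' @export
render_frame <- function(emitters, fov, calibration, pixel_size = 103.8,
                         mean_photons = 2000, background = 0,
                         camera = NULL, noise = TRUE) {
  rows <- fov[1L]; cols <- fov[2L]
  img <- matrix(0, rows, cols)
  n_skipped <- 0L
  if (!is.null(emitters) && nrow(emitters) > 0L) {
    xe <- pixel_size * seq(0L, cols)  # pixel edges, nm
    ye <- pixel_size * seq(0L, rows)
    for (k in seq_len(nrow(emitters))) {
      z <- emitters$z[k]
      if (z < calibration$z_range[1L] || z > calibration$z_range[2L]) {
        n_skipped <- n_skipped + 1L
        next
      }
      sg <- sigma_at(calibration, z)
      mx <- diff(stats::pnorm(xe, emitters$x[k], sg[["sigma_x"]]))
      my <- diff(stats::pnorm(ye, emitters$y[k], sg[["sigma_y"]]))
      img <- img + mean_photons * (my %o% mx)
    }
  }
  img <- img + background
  if (noise) {
    # one Poisson draw per pixel of the expected photon image: the emitter's
    # integrated count is then Poisson(mean_photons x in-frame mass) and the
    # background Poisson(background), as sums of independent Poissons
    img <- matrix(stats::rpois(rows * cols, pmax(img, 0)), rows, cols)
  }
  if (!is.null(camera)) {
    img <- camera$offset + camera$gain * img
    if (!is.null(camera$read_noise) && camera$read_noise > 0 && noise) {
      img <- img + matrix(stats::rnorm(rows * cols, 0, camera$read_noise),
                          rows, cols)
    }
    img <- round(pmax(img, 0))
  }
  attr(img, "n_skipped") <- n_skipped
  img
}

# ---- sawtooth scan acquisition ------------------------------------------

#' Per-frame scan plan of a sawtooth acquisition
#'
#' @param geometry an [acquisition_geometry()]
#' @param n_stacks number of stacks (defaults to the geometry's).
#' @return data.frame with 0-based `frame`, `stack`, `frame_in_stack` and the
#'   sheet position `s` (nm) for every frame of the acquisition.
#' @export
scan_plan <- function(geometry, n_stacks = geometry$n_stacks) {
  fps <- geometry$frames_per_stack
  n <- fps * n_stacks
  frame <- seq_len(n) - 1L
  fis <- frame %% fps
  data.frame(frame = frame, stack = frame %/% fps, frame_in_stack = fis,
             s = fis * geometry$scan_step)
}

# acquisition-frame coordinates of biological-frame points for sheet
# position s (the inverse of the deskew rotation, applied pointwise)
.bio_to_acq <- function(x, y, z, s, angle_deg) {
  a <- angle_deg * pi / 180
  yr <- y - s
  list(x = x, y = yr * cos(a) + z * sin(a), z = -yr * sin(a) + z * cos(a))
}

#' Simulate a sawtooth-scanned acquisition
#'
#' Frame `f` of each stack places the light sheet at `s = f * scan_step`;
#' only emitters within half the sheet thickness of the sheet plane are
#' excitable. Optionally renders camera frames (see [render_frame()]); with
#' `render = FALSE` only the visibility bookkeeping is returned, which is
#' what the geometry and density tests consume.
#'
#' @param scene a [scene_spec()], or a `ground_truth` data.frame to reuse
#'   fixed emitter positions.
#' @param geometry an [acquisition_geometry()].
#' @param n_stacks number of stacks.
#' @param calibration astigmatism calibration used for rendering (defaults to
#'   [synthetic_calibration()]).
#' @param seed integer seed.
#' @param render render camera frames? (requires a modest field of view)
#' @param fov c(rows, cols) pixels when rendering.
#' @param fov_origin biological-frame (x, y) of the frame's top-left corner
#'   (nm) when rendering.
#' @param blinking result of [simulate_blinking()]; if `NULL` all emitters
#'   are always on.
#' @return list with `plan` (see [scan_plan()]), `truth`, `visible` (list per
#'   frame of excitable emitter ids) and, when rendered, `movie`
#'   (frames x rows x cols counts array).
#' @export
simulate_scan_acquisition <- function(scene, geometry,
                                      n_stacks = geometry$n_stacks,
                                      calibration = synthetic_calibration(),
                                      seed = NULL, render = FALSE,
                                      fov = c(32L, 32L), fov_origin = c(0, 0),
                                      blinking = NULL) {
  truth <- if (inherits(scene, "ground_truth")) scene else
    sample_membrane_emitters(scene, seed = seed)
  plan <- scan_plan(geometry, n_stacks)
  half <- geometry$sheet_thickness / 2
  visible <- vector("list", nrow(plan))
  with_seed(if (inherits(scene, "ground_truth")) seed else
    if (is.null(seed)) NULL else seed + 1L, {
    movie <- if (render) {
      array(0, dim = c(nrow(plan), fov[1L], fov[2L]))
    } else NULL
    cam <- if (inherits(scene, "scene_spec")) {
      list(offset = scene$camera_offset, gain = scene$camera_gain,
           read_noise = scene$read_noise)
    } else {
      list(offset = 100, gain = 1, read_noise = 0)
    }
    mean_photons <- if (inherits(scene, "scene_spec")) scene$mean_photons
      else 2000
    bg <- if (inherits(scene, "scene_spec")) scene$background else 0
    for (i in seq_len(nrow(plan))) {
      acq <- .bio_to_acq(truth$x, truth$y, truth$z, plan$s[i],
                         geometry$deskew_angle)
      vis <- which(abs(acq$z) <= half)
      if (!is.null(blinking)) {
        vis <- intersect(vis, match(blinking$active[[i]], truth$id))
        vis <- vis[!is.na(vis)]
      }
      visible[[i]] <- truth$id[vis]
      if (render) {
        em <- data.frame(x = acq$x[vis] - fov_origin[1L],
                         y = acq$y[vis] - fov_origin[2L],
                         z = acq$z[vis])
        movie[i, , ] <- render_frame(em, fov, calibration,
                                     pixel_size = geometry$pixel_size,
                                     mean_photons = mean_photons,
                                     background = bg, camera = cam)
      }
    }
    out <- list(plan = plan, truth = truth, visible = visible)
    if (render) out$movie <- movie
    out
  })
}

#' Simulate a localization table from ground truth
#'
#' Table-level counterpart of the full image-formation path: every
#' (blink event, frame) pair in which the emitter sits inside the light sheet
#' yields one localization at the emitter's acquisition-frame position plus
#' independent Gaussian localization noise per dimension. Used to exercise
#' the scan-correction, rotation, precision and density stages at realistic
#' localization counts without rendering camera frames.
#'
#' @param truth a `ground_truth` (biological frame).
#' @param geometry an [acquisition_geometry()].
#' @param n_stacks stacks to simulate.
#' @param noise_sigma per-dimension localization noise c(x, y, z) in nm,
#'   acquisition frame.
#' @param mean_on_time,activation_rate,recurrence blinking kinetics, see
#'   [simulate_blinking()].
#' @param mean_photons mean photons per localization (Poisson).
#' @param calibration calibration used to fill the PSF width columns.
#' @param seed integer seed.
#' @return a [localization_table()] (`frame_kind = "acquisition"`).
#' @export
simulate_localizations <- function(truth, geometry,
                                   n_stacks = geometry$n_stacks,
                                   noise_sigma = c(16, 17, 74),
                                   mean_on_time = 3, activation_rate = 0.01,
                                   recurrence = 0, mean_photons = 2000,
                                   calibration = synthetic_calibration(),
                                   seed = NULL) {
  n_frames <- geometry$frames_per_stack * n_stacks
  if (nrow(truth) == 0L) return(empty_localization_table("acquisition"))
  with_seed(seed, {
    blink <- simulate_blinking(truth, n_frames, mean_on_time,
                               activation_rate, recurrence)
    plan <- scan_plan(geometry, n_stacks)
    half <- geometry$sheet_thickness / 2
    rows <- vector("list", n_frames)
    idx <- match(seq_len(max(truth$id, 0L)), truth$id)
    for (i in seq_len(n_frames)) {
      on <- blink$active[[i]]
      if (length(on) == 0L) next
      j <- idx[on]
      acq <- .bio_to_acq(truth$x[j], truth$y[j], truth$z[j], plan$s[i],
                         geometry$deskew_angle)
      vis <- which(abs(acq$z) <= half)
      if (length(vis) == 0L) next
      m <- length(vis)
      z <- acq$z[vis] + stats::rnorm(m, 0, noise_sigma[3L])
      sg <- sigma_at(calibration, pmin(pmax(z, calibration$z_range[1L]),
                                       calibration$z_range[2L]))
      rows[[i]] <- data.frame(
        x = acq$x[vis] + stats::rnorm(m, 0, noise_sigma[1L]),
        y = acq$y[vis] + stats::rnorm(m, 0, noise_sigma[2L]),
        z = z,
        frame = plan$frame[i], stack = plan$stack[i],
        frame_in_stack = plan$frame_in_stack[i],
        photons = stats::rpois(m, mean_photons),
        background = 0,
        sigma_x = sg[["sigma_x"]], sigma_y = sg[["sigma_y"]],
        emitter = truth$id[j][vis])
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) return(empty_localization_table("acquisition"))
    localization_table(df, frame_kind = "acquisition")
  })
}

# ---- Brownian trajectories ----------------------------------------------

#' Simulate 3D Brownian trajectories with localization noise
#'
#' Per-dimension increments are Gaussian with mean 0 and variance
#' `2 * D_r * dt`; the observed copy adds i.i.d. Gaussian localization noise
#' per dimension. Diffusion constants are in um^2/s, positions in nm.
#'
#' @param n number of trajectories.
#' @param D per-dimension diffusion constants c(Dx, Dy, Dz) in um^2/s.
#' @param dt frame interval (s).
#' @param n_frames frames per trajectory.
#' @param noise_sigma per-dimension localization noise (nm).
#' @param spread lateral extent (nm) over which starting points scatter.
#' @param seed integer seed.
#' @return list with `true` and `observed`: data.frames
#'   `id, frame, t, x, y, z`.
#' @export
simulate_trajectories <- function(n, D = c(0.058, 0.059, 0.023), dt = 0.02,
                                  n_frames = 50L,
                                  noise_sigma = c(20, 20, 70),
                                  spread = 20000, seed = NULL) {
  stopifnot(all(D >= 0), dt > 0, n_frames >= 2)
  D <- rep(D, length.out = 3L)
  noise_sigma <- rep(noise_sigma, length.out = 3L)
  step_sd <- sqrt(2 * D * 1e6 * dt)  # nm per dimension
  with_seed(seed, {
    start <- cbind(stats::runif(n, 0, spread), stats::runif(n, 0, spread),
                   stats::runif(n, 0, spread))
    res <- vector("list", n)
    for (i in seq_len(n)) {
      steps <- cbind(stats::rnorm(n_frames - 1L, 0, step_sd[1L]),
                     stats::rnorm(n_frames - 1L, 0, step_sd[2L]),
                     stats::rnorm(n_frames - 1L, 0, step_sd[3L]))
      pos <- rbind(start[i, ], sweep(apply(steps, 2L, cumsum), 2L,
                                     start[i, ], "+"))
      res[[i]] <- data.frame(id = i, frame = seq_len(n_frames) - 1L,
                             t = (seq_len(n_frames) - 1L) * dt,
                             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L])
    }
    true <- do.call(rbind, res)
    observed <- true
    observed$x <- observed$x + stats::rnorm(nrow(true), 0, noise_sigma[1L])
    observed$y <- observed$y + stats::rnorm(nrow(true), 0, noise_sigma[2L])
    observed$z <- observed$z + stats::rnorm(nrow(true), 0, noise_sigma[3L])
    list(true = true, observed = observed)
  })
}

# ---- FRAP traces ---------------------------------------------------------

#' Simulate a FRAP recovery trace
#'
#' Prebleach frames sit at 1; after the bleach the normalized intensity
#' follows `I(t) = I0 + MF * (1 - I0) * (1 - exp(-t/tau))` with
#' `I0 = 1 - bleach_depth`, `t` measured from the first post-bleach frame.
#' Gaussian noise is added, and the trace can be scaled back to raw camera
#' units to exercise the normalization stage.
#'
#' @param tau recovery time constant (s).
#' @param mobile_fraction fraction of the bleached pool that recovers.
#' @param bleach_depth 1 - immediate post-bleach intensity.
#' @param n_prebleach prebleach frames.
#' @param frame_interval s between frames.
#' @param total_time total acquisition (s).
#' @param noise_sd Gaussian noise on the normalized scale.
#' @param scale,background linear raw-intensity model
#'   `raw = background + scale * I`.
#' @param seed integer seed.
#' @return data.frame `t`, `intensity`, `background` with attributes `tau`,
#'   `mobile_fraction`, `n_prebleach`.
#' @export
simulate_frap <- function(tau = 15, mobile_fraction = 0.8,
                          bleach_depth = 0.7, n_prebleach = 3L,
                          frame_interval = 1.5, total_time = 120,
                          noise_sd = 0, scale = 1, background = 0,
                          seed = NULL) {
  stopifnot(tau > 0, mobile_fraction >= 0, mobile_fraction <= 1,
            bleach_depth >= 0, bleach_depth <= 1)
  t <- seq(0, total_time, by = frame_interval)
  if (length(t) < n_prebleach + 2L) stop("trace too short")
  I0 <- 1 - bleach_depth
  ti <- t - t[n_prebleach + 1L]  # time since first post-bleach frame
  I <- ifelse(seq_along(t) <= n_prebleach, 1,
              I0 + mobile_fraction * (1 - I0) * (1 - exp(-ti / tau)))
  with_seed(seed, {
    if (noise_sd > 0) I <- I + stats::rnorm(length(I), 0, noise_sd)
    structure(data.frame(t = t, intensity = background + scale * I,
                         background = background),
              tau = tau, mobile_fraction = mobile_fraction,
              n_prebleach = n_prebleach)
  })
}
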