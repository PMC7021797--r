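#' Acquisition geometry of the stage-scanned light-sheet instrument
#'
#' Bundles the instrument and scan parameters that define the skewed
#' acquisition-to-biological coordinate transform and the excitation filters.
#' Defaults are the acquisition plan used throughout: 103.8 nm pixels, a
#' sawtooth scan of 40 nm per frame with 1001 frames per stack, and a
#' light-sheet thickness of 1.4 um.
#'
#' @param pixel_size camera pixel size at the sample (nm).
#' @param scan_step sample displacement per frame along the scan axis (nm).
#' @param frames_per_stack frames in one sawtooth sweep.
#' @param n_stacks number of stacks acquired.
#' @param deskew_angle angle alpha (degrees) between the camera y axis and
#'   the coverslip plane; must lie strictly between 0 and 90.
#' @param sheet_thickness light-sheet thickness (nm).
#' @param exposure camera exposure per frame (s).
#' @return an `acquisition_geometry` object (a validated list).
#' @export
acquisition_geometry <- function(pixel_size = 103.8, scan_step = 40,
                                 frames_per_stack = 1001L, n_stacks = 1L,
                                 deskew_angle = 32.45,
                                 sheet_thickness = 1400, exposure = 0.02) {
  g <- list(pixel_size = pixel_size, scan_step = scan_step,
            frames_per_stack = as.integer(frames_per_stack),
            n_stacks = as.integer(n_stacks), deskew_angle = deskew_angle,
            sheet_thickness = sheet_thickness, exposure = exposure)
  for (key in c("pixel_size", "scan_step", "sheet_thickness", "exposure")) {
    if (!is.numeric(g[[key]]) || length(g[[key]]) != 1L || g[[key]] <= 0) {
      stop("invalid geometry parameter '", key, "': must be a positive number")
    }
  }
  if (g$frames_per_stack < 1L) {
    stop("invalid geometry parameter 'frames_per_stack': must be >= 1")
  }
  if (g$n_stacks < 1L) {
    stop("invalid geometry parameter 'n_stacks': must be >= 1")
  }
  if (g$deskew_angle <= 0 || g$deskew_angle >= 90) {
    stop("invalid geometry parameter 'deskew_angle': must be in (0, 90) degrees")
  }
  structure(g, class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("Acquisition geometry\n")
  cat(sprintf("  pixel size      %g nm\n", x$pixel_size))
  cat(sprintf("  scan step       %g nm/frame (sawtooth)\n", x$scan_step))
  cat(sprintf("  frames/stack    %d  (x %d stacks = %d frames)\n",
              x$frames_per_stack, x$n_stacks, total_frames(x)))
  cat(sprintf("  deskew angle    %g deg\n", x$deskew_angle))
  cat(sprintf("  sheet thickness %g nm\n", x$sheet_thickness))
  cat(sprintf("  exposure        %g s\n", x$exposure))
  invisible(x)
}

#' Total number of frames in an acquisition plan
#' @param geometry an [acquisition_geometry()]
#' @return `frames_per_stack * n_stacks`
#' @export
total_frames <- function(geometry) {
  geometry$frames_per_stack * geometry$n_stacks
}

#' Scan extent of one stack
#'
#' The distance covered along the scan axis by one sawtooth sweep:
#' `(frames_per_stack - 1) * scan_step` nanometres.
#'
#' @param geometry an [acquisition_geometry()]
#' @return extent in nm
#' @export
scan_extent <- function(geometry) {
  (geometry$frames_per_stack - 1) * geometry$scan_step
}

# ---- pipeline configuration ---------------------------------------------

.config_defaults <- function() {
  list(
    pixel_size = 103.8,        # nm
    scan_step = 40,            # nm/frame
    frames_per_stack = 1001L,
    n_stacks = 1L,
    deskew_angle = 32.45,      # degrees
    sheet_thickness = 1400,    # nm
    exposure = 0.02,           # s
    min_photons = 500,
    axial_halfwidth = 700,     # nm; half of the illuminated 1.4 um range
    window_size = 2000,        # nm
    step = 200,                # nm
    render_pixel = 20,         # nm
    max_disp = 500,            # nm/frame
    memory = 1L,               # frames
    min_track_len = 20L,       # frames
    n_fit_points = 5L,
    frame_interval = 1.5,      # s
    n_prebleach = 3L,
    seed = 1L
  )
}

#' Load a pipeline configuration
#'
#' Reads a flat-key YAML file, fills every absent key with its documented
#' default, and validates the result. With `path = NULL` the full default
#' configuration is returned.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @return a `pipeline_config` (named list).
#' @export
load_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user) > 0L) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown) > 0L) {
        warning("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", "))
      }
      for (key in intersect(names(user), names(cfg))) cfg[[key]] <- user[[key]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  positive <- c("pixel_size", "scan_step", "sheet_thickness", "exposure",
                "axial_halfwidth", "window_size", "step", "render_pixel",
                "max_disp", "frame_interval")
  for (key in positive) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("config key '", key, "' must be a positive number, got ",
           cfg[[key]])
    }
  }
  if (cfg$min_photons < 0) stop("config key 'min_photons' must be >= 0")
  if (cfg$memory < 0) stop("config key 'memory' must be >= 0")
  if (cfg$n_fit_points < 2) stop("config key 'n_fit_points' must be >= 2")
  if (cfg$min_track_len < 2) stop("config key 'min_track_len' must be >= 2")
  if (cfg$n_prebleach < 1) stop("config key 'n_prebleach' must be >= 1")
  if (cfg$frames_per_stack < 1) {
    stop("config key 'frames_per_stack' must be >= 1")
  }
  if (cfg$deskew_angle <= 0 || cfg$deskew_angle >= 90) {
    stop("config key 'deskew_angle' must be in (0, 90)")
  }
  invisible(TRUE)
}

#' Extract the acquisition geometry from a pipeline config
#' @param config a `pipeline_config`
#' @return an [acquisition_geometry()]
#' @export
config_geometry <- function(config) {
  acquisition_geometry(pixel_size = config$pixel_size,
                       scan_step = config$scan_step,
                       frames_per_stack = config$frames_per_stack,
                       n_stacks = config$n_stacks,
                       deskew_angle = config$deskew_angle,
                       sheet_thickness = config$sheet_thickness,
                       exposure = config$exposure)
}
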