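#' Localization tables
#'
#' A localization table holds one row per single-molecule blink localization.
#' It is an ordinary `data.frame` carrying the columns below plus a
#' `frame_kind` attribute recording which coordinate frame the positions live
#' in. All lengths are in nanometres, frame and stack indices are 0-based.
#'
#' Columns:
#' \describe{
#'   \item{x, y}{lateral position (nm)}
#'   \item{z}{axial position (nm): distance from the light-sheet/focal centre
#'     in the acquisition frame, height above the coverslip in the biological
#'     frame}
#'   \item{frame}{0-based global frame index}
#'   \item{stack}{0-based stack index}
#'   \item{frame_in_stack}{0-based frame index within its stack}
#'   \item{photons}{detected photon count}
#'   \item{background}{background level (photons/pixel)}
#'   \item{sigma_x, sigma_y}{fitted PSF widths (nm)}
#' }
#' Optional columns: `s` (scan coordinate, added by [correct_scan_shift()]),
#' `uncertainty_xy`, `uncertainty_z` (nm), `converged` (logical fit flag).
#'
#' The coordinate frame progresses only forward:
#' `acquisition -> scan_corrected -> biological`.
#'
#' @param df data.frame with at least columns x, y, z, frame. Missing
#'   bookkeeping columns are filled with defaults (`stack = 0`,
#'   `frame_in_stack = frame`, `photons = NA`, ...).
#' @param frame_kind one of `"acquisition"`, `"scan_corrected"`,
#'   `"biological"`.
#' @param frames_per_stack if supplied, `stack` and `frame_in_stack` are
#'   derived from `frame` and validated against it.
#' @return a `localization_table` (a data.frame).
#' @export
localization_table <- function(df, frame_kind = "acquisition",
                               frames_per_stack = NULL) {
  stopifnot(is.data.frame(df))
  frame_kind <- match.arg(frame_kind, .frame_kinds)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "frame")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("localization table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  n <- nrow(df)
  if (!is.null(frames_per_stack)) {
    stopifnot(frames_per_stack >= 1)
    df$stack <- df$frame %/% frames_per_stack
    df$frame_in_stack <- df$frame %% frames_per_stack
  }
  if (is.null(df$stack)) df$stack <- rep(0L, n)
  if (is.null(df$frame_in_stack)) df$frame_in_stack <- df$frame
  for (col in c("photons", "background", "sigma_x", "sigma_y")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, n)
  }
  validate_localization_table(df, frame_kind)
  structure(df, frame_kind = frame_kind,
            class = c("localization_table", "data.frame"))
}

.frame_kinds <- c("acquisition", "scan_corrected", "biological")

validate_localization_table <- function(df, frame_kind) {
  if (nrow(df) == 0L) return(invisible(TRUE))
  if (any(!is.na(df$photons) & df$photons < 0)) {
    stop("photons must be >= 0")
  }
  for (col in c("sigma_x", "sigma_y")) {
    if (any(!is.na(df[[col]]) & df[[col]] <= 0)) {
      stop(col, " must be > 0")
    }
  }
  if (any(df$frame_in_stack < 0)) stop("frame_in_stack must be >= 0")
  invisible(TRUE)
}

#' Coordinate frame of a localization table
#' @param table a [localization_table()]
#' @return one of `"acquisition"`, `"scan_corrected"`, `"biological"`
#' @export
frame_kind <- function(table) {
  fk <- attr(table, "frame_kind")
  if (is.null(fk)) stop("not a localization table: no frame_kind attribute")
  fk
}

# enforce forward-only frame_kind transitions
set_frame_kind <- function(table, new_kind) {
  old <- frame_kind(table)
  if (match(new_kind, .frame_kinds) < match(old, .frame_kinds)) {
    stop("frame_kind may only move forward (", old, " -> ", new_kind,
         " is not allowed)")
  }
  attr(table, "frame_kind") <- new_kind
  table
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("Localization table: %d localizations [%s frame]\n",
              nrow(x), frame_kind(x)))
  if (nrow(x) > 0L) {
    cat(sprintf("  frames %d..%d, stacks %d..%d\n",
                min(x$frame), max(x$frame), min(x$stack), max(x$stack)))
  }
  NextMethod()
}

# ---- CSV I/O -------------------------------------------------------------

.native_columns <- c("x", "y", "z", "frame", "stack", "frame_in_stack",
                     "photons", "background", "sigma_x", "sigma_y")

#' Read a localization table from CSV
#'
#' Two dialects are supported. `"native"` is this package's schema (all
#' columns of [localization_table()] plus `frame_kind`). `"thunderstorm"`
#' reads the ThunderSTORM export convention (`"x [nm]"`, `"y [nm]"`,
#' `"z [nm]"`, `frame` 1-based, `"intensity [photon]"`, `"sigma1 [nm]"`,
#' `"sigma2 [nm]"`, `"offset [photon]"`). A 2D ThunderSTORM table (no z
#' column) is accepted: z is filled with 0 and the result carries attribute
#' `z_filled = TRUE`.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"thunderstorm"`.
#' @param frame_kind frame tag to assign when the file does not record one
#'   (thunderstorm dialect).
#' @param frames_per_stack used to reconstruct stack / frame_in_stack indices
#'   for the thunderstorm dialect; if `NULL`, all rows are placed in stack 0.
#' @return a [localization_table()]
#' @export
read_localizations <- function(path, dialect = c("native", "thunderstorm"),
                               frame_kind = "acquisition",
                               frames_per_stack = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "native") {
    miss <- setdiff(c("x", "y", "z", "frame"), names(df))
    if (length(miss) > 0L) {
      stop("native localization CSV missing column(s): ",
           paste(miss, collapse = ", "))
    }
    fk <- if ("frame_kind" %in% names(df) && nrow(df) > 0L) {
      df$frame_kind[1L]
    } else {
      frame_kind
    }
    df$frame_kind <- NULL
    if (nrow(df) == 0L) return(empty_localization_table(fk))
    return(localization_table(df, frame_kind = fk))
  }
  # thunderstorm dialect
  ts_map <- c(`x [nm]` = "x", `y [nm]` = "y", `z [nm]` = "z",
              `intensity [photon]` = "photons", `offset [photon]` = "background",
              `sigma1 [nm]` = "sigma_x", `sigma2 [nm]` = "sigma_y",
              `sigma [nm]` = "sigma_x",
              `uncertainty [nm]` = "uncertainty_xy",
              `uncertainty_z [nm]` = "uncertainty_z")
  if (!all(c("x [nm]", "y [nm]", "frame") %in% names(df))) {
    stop("thunderstorm CSV must contain 'x [nm]', 'y [nm]' and 'frame' columns")
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (ts in names(ts_map)) {
    if (ts %in% names(df)) out[[ts_map[[ts]]]] <- df[[ts]]
  }
  out$frame <- as.integer(df$frame) - 1L  # ThunderSTORM frames are 1-based
  z_filled <- FALSE
  if (is.null(out$z)) {
    out$z <- rep(0, nrow(out))
    z_filled <- TRUE
  }
  if (!is.null(out$sigma_x) && is.null(out$sigma_y)) out$sigma_y <- out$sigma_x
  if (nrow(out) == 0L) {
    tab <- empty_localization_table(frame_kind)
  } else {
    tab <- localization_table(out, frame_kind = frame_kind,
                              frames_per_stack = frames_per_stack)
  }
  attr(tab, "z_filled") <- z_filled
  tab
}

#' Write a localization table to CSV
#'
#' @inheritParams read_localizations
#' @param table a [localization_table()]
#' @details The native dialect writes every column plus `frame_kind`; the
#'   thunderstorm dialect writes a 1-based `id` column, 1-based `frame`, and
#'   the `"x [nm]"`-style headers understood by ThunderSTORM's import.
#' @export
write_localizations <- function(table, path,
                                dialect = c("native", "thunderstorm")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(table)
  if (dialect == "native") {
    df$frame_kind <- rep(frame_kind(table), nrow(df))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  out <- data.frame(id = seq_len(nrow(df)), frame = df$frame + 1L)
  out[["x [nm]"]] <- df$x
  out[["y [nm]"]] <- df$y
  out[["z [nm]"]] <- df$z
  if (!is.null(df$sigma_x)) out[["sigma1 [nm]"]] <- df$sigma_x
  if (!is.null(df$sigma_y)) out[["sigma2 [nm]"]] <- df$sigma_y
  if (!is.null(df$photons)) out[["intensity [photon]"]] <- df$photons
  if (!is.null(df$background)) out[["offset [photon]"]] <- df$background
  if (!is.null(df$uncertainty_xy)) out[["uncertainty [nm]"]] <- df$uncertainty_xy
  if (!is.null(df$uncertainty_z)) out[["uncertainty_z [nm]"]] <- df$uncertainty_z
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_localization_table <- function(frame_kind = "acquisition") {
  df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                   frame = integer(0), stack = integer(0),
                   frame_in_stack = integer(0), photons = numeric(0),
                   background = numeric(0), sigma_x = numeric(0),
                   sigma_y = numeric(0))
  structure(df, frame_kind = frame_kind,
            class = c("localization_table", "data.frame"))
}

# ---- TIFF stacks ---------------------------------------------------------

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file.
#' @return numeric array `frames x rows x cols` of raw camera counts, with a
#'   `pixel_size_nm` attribute when resolution metadata is present.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) {
                      stop("cannot read TIFF '", path, "': ",
                           conditionMessage(e))
                    })
  if (length(pages) == 0L) stop("TIFF has zero pages: ", path)
  dims <- dim(pages[[1L]])
  stack <- array(0, dim = c(length(pages), dims[1L], dims[2L]))
  for (f in seq_along(pages)) stack[f, , ] <- pages[[f]]
  info <- attributes(pages[[1L]])
  # TIFF x.resolution is pixels per unit; with unit cm, nm/px = 1e7 / res
  if (!is.null(info$x.resolution) && isTRUE(info$resolution.unit == "cm") &&
      info$x.resolution > 0) {
    attr(stack, "pixel_size_nm") <- 1e7 / info$x.resolution
  }
  stack
}

#' Write a movie as multi-page TIFF
#'
#' @param stack array `frames x rows x cols` (or a matrix for one frame) of
#'   non-negative counts; stored as 16-bit.
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1L, dim(stack)))
  stopifnot(length(dim(stack)) == 3L)
  maxv <- 65535
  pages <- lapply(seq_len(dim(stack)[1L]), function(f) {
    m <- stack[f, , ]
    pmin(pmax(m, 0), maxv) / maxv  # writeTIFF takes [0,1]; 16-bit storage
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Convert raw camera counts to photons
#'
#' Inverts the linear camera model `counts = offset + gain * photons`.
#'
#' @param frame matrix or array of raw counts.
#' @param offset camera offset (counts).
#' @param gain camera gain (counts/photon).
#' @return same shape, photons (negative values clipped to 0).
#' @export
counts_to_photons <- function(frame, offset = 100, gain = 1) {
  stopifnot(gain > 0)
  pmax((frame - offset) / gain, 0)
}
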