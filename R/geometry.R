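#' Record the sawtooth scan coordinate of each localization
#'
#' During acquisition the sample is stepped a fixed increment along the scan
#' axis once per frame, resetting at the start of every stack (a sawtooth).
#' This stage attaches to each localization the known shift
#' `s = frame_in_stack * scan_step` so the subsequent rotation can place the
#' point back into sample space. Coordinates themselves are unchanged.
#'
#' @param table a [localization_table()] in the acquisition frame.
#' @param geometry an [acquisition_geometry()].
#' @return the table with an `s` column (nm), `frame_kind = "scan_corrected"`.
#' @export
correct_scan_shift <- function(table, geometry) {
  if (frame_kind(table) != "acquisition") {
    stop("correct_scan_shift expects a table in the acquisition frame, got ",
         frame_kind(table))
  }
  if (nrow(table) > 0L &&
      any(table$frame_in_stack >= geometry$frames_per_stack)) {
    stop("frame_in_stack >= frames_per_stack (", geometry$frames_per_stack,
         "): table inconsistent with geometry")
  }
  table$s <- table$frame_in_stack * geometry$scan_step
  set_frame_kind(table, "scan_corrected")
}

#' Rotate scan-corrected localizations into the biological frame
#'
#' Maps the skewed, stage-scanned acquisition coordinates (camera x, camera
#' y, astigmatic z, scan coordinate s) to coverslip-aligned "biological"
#' coordinates (x', y', z') by a rotation about the x axis through the deskew
#' angle alpha, composed with the scan translation:
#' \deqn{x' = x, \quad y' = s + y\cos\alpha - z\sin\alpha, \quad
#'       z' = y\sin\alpha + z\cos\alpha}
#' The per-frame transform is rigid, so pairwise distances within a frame and
#' point densities per true area are preserved.
#'
#' @param table a scan-corrected [localization_table()] (see
#'   [correct_scan_shift()]).
#' @param geometry an [acquisition_geometry()].
#' @param anchor_coverslip if `TRUE`, shift z' so the coverslip plane
#'   (estimated as the 1st percentile of z') sits at 0; the shift is stored in
#'   attribute `coverslip_offset` and undone by [invert_deskew()].
#' @return the table in the biological frame; the `s` column is retained so
#'   the transform stays invertible.
#' @export
deskew_rotate <- function(table, geometry, anchor_coverslip = FALSE) {
  if (frame_kind(table) != "scan_corrected") {
    stop("deskew_rotate expects a scan-corrected table, got ",
         frame_kind(table))
  }
  if (is.null(table$s)) stop("table has no scan coordinate 's'")
  a <- geometry$deskew_angle * pi / 180
  y <- table$y
  z <- table$z
  table$y <- table$s + y * cos(a) - z * sin(a)
  table$z <- y * sin(a) + z * cos(a)
  offset <- 0
  if (anchor_coverslip && nrow(table) > 0L) {
    offset <- stats::quantile(table$z, 0.01, names = FALSE)
    table$z <- table$z - offset
  }
  table <- set_frame_kind(table, "biological")
  attr(table, "coverslip_offset") <- offset
  table
}

#' Invert the deskew rotation
#'
#' Exact algebraic inverse of [deskew_rotate()]; used for round-trip checks
#' and for placing simulated ground truth into the acquisition frame.
#'
#' @param table a biological-frame table that still carries its `s` column.
#' @param geometry an [acquisition_geometry()].
#' @return the table back in the scan-corrected frame. The frame-kind chain is
#'   forward-only for the measurement pipeline; inversion is a geometry
#'   utility and rebuilds the table instead of mutating the tag backwards.
#' @export
invert_deskew <- function(table, geometry) {
  if (frame_kind(table) != "biological") {
    stop("invert_deskew expects a biological-frame table, got ",
         frame_kind(table))
  }
  if (is.null(table$s)) stop("table has no scan coordinate 's'")
  a <- geometry$deskew_angle * pi / 180
  offset <- attr(table, "coverslip_offset")
  zb <- table$z + if (is.null(offset)) 0 else offset
  yr <- table$y - table$s
  df <- as.data.frame(table)
  df$y <- yr * cos(a) + zb * sin(a)
  df$z <- -yr * sin(a) + zb * cos(a)
  out <- localization_table(df, frame_kind = "acquisition")
  out$s <- df$s
  set_frame_kind(out, "scan_corrected")
}

# ---- localization precision from blinking events -------------------------

#' Estimate experimental localization precision from blinking events
#'
#' A fluorophore's single on-period produces localizations in consecutive
#' frames; their scatter around the event mean measures the localization
#' precision directly, without ground truth. Localizations closer than
#' `group_radius` laterally and separated by at most `max_gap` frames are
#' grouped into one blinking event; the per-dimension precision is the pooled
#' within-event standard deviation over all events with at least two members:
#' \deqn{\hat\sigma_r^2 = \sum_e \sum_i (r_{ei} - \bar r_e)^2 \Big/
#'       \sum_e (n_e - 1)}
#'
#' @param table a [localization_table()] in a single coordinate frame.
#' @param group_radius lateral (xy) grouping radius in nm.
#' @param max_gap maximum frame gap inside one event.
#' @return a `precision_estimate` with fields `sigma_x`, `sigma_y`, `sigma_z`
#'   (nm), `n_events`, `n_localizations` and the table's frame tag.
#' @export
estimate_precision <- function(table, group_radius = 100, max_gap = 1L) {
  if (nrow(table) < 2L) stop("need at least 2 localizations")
  ord <- order(table$frame)
  x <- table$x[ord]; y <- table$y[ord]; z <- table$z[ord]
  fr <- table$frame[ord]
  n <- length(x)
  event <- integer(n)
  # open events: last seen position/frame per event id; only events touched
  # within the last max_gap+1 frames stay active
  ex <- numeric(n); ey <- numeric(n); ef <- integer(n)
  active <- integer(0)
  next_id <- 0L
  r2 <- group_radius^2
  for (i in seq_len(n)) {
    if (length(active) > 0L) {
      active <- active[fr[i] - ef[active] <= max_gap + 1L]
    }
    cand <- active[fr[i] - ef[active] >= 1L]
    if (length(cand) > 0L) {
      d2 <- (x[i] - ex[cand])^2 + (y[i] - ey[cand])^2
      j <- cand[which.min(d2)]
      if (min(d2) <= r2) {
        event[i] <- j
        ex[j] <- x[i]; ey[j] <- y[i]; ef[j] <- fr[i]
        next
      }
    }
    next_id <- next_id + 1L
    event[i] <- next_id
    ex[next_id] <- x[i]; ey[next_id] <- y[i]; ef[next_id] <- fr[i]
    active <- c(active, next_id)
  }
  sizes <- tabulate(event)
  keep <- which(sizes >= 2L)
  if (length(keep) == 0L) {
    stop("no blinking event has >= 2 localizations; ",
         "increase group_radius or max_gap")
  }
  dof <- sum(sizes[keep] - 1L)
  pooled_sd <- function(v) {
    sums <- rowsum(v, event)[, 1L]
    sq <- rowsum(v^2, event)[, 1L]
    ss <- sq[keep] - sums[keep]^2 / sizes[keep]
    sqrt(sum(ss) / dof)
  }
  structure(list(sigma_x = pooled_sd(x), sigma_y = pooled_sd(y),
                 sigma_z = pooled_sd(z),
                 n_events = length(keep),
                 n_localizations = sum(sizes[keep]),
                 frame_kind = frame_kind(table)),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf(
    "Localization precision (%s frame): sigma = (%.1f, %.1f, %.1f) nm\n",
    x$frame_kind, x$sigma_x, x$sigma_y, x$sigma_z))
  cat(sprintf("  from %d blinking events (%d localizations)\n",
              x$n_events, x$n_localizations))
  invisible(x)
}
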