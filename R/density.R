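# Sliding-window localization densities over membrane regions, the summary
# statistic used to compare basal, apical and cell-cell interface membranes.

#' Define a region mask
#'
#' A region of interest for density analysis: a simple 2D polygon in a named
#' projection plane plus slab bounds along the projection axis. Localizations
#' inside the slab are orthogonally projected onto the plane and tested
#' against the polygon.
#'
#' @param polygon n x 2 matrix of vertices (nm) in the projection plane.
#' @param plane `"xy"` (project along z), `"xz"` (along y) or `"yz"` (along
#'   x).
#' @param slab c(min, max) bounds (nm) on the projection axis; half-open
#'   `[min, max)`.
#' @param label region label, e.g. basal / apical / interface.
#' @return a `region_mask`.
#' @export
region_mask <- function(polygon, plane = c("xy", "xz", "yz"),
                        slab = c(-Inf, Inf), label = "custom") {
  plane <- match.arg(plane)
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2L, nrow(polygon) >= 3L)
  if (slab[1L] > slab[2L]) stop("slab bounds must satisfy min <= max")
  # min == max is permitted: a zero-thickness slab selects nothing
  # (half-open membership)
  if (.polygon_self_intersects(polygon)) {
    stop("polygon is self-intersecting; region masks must be simple polygons")
  }
  structure(list(polygon = polygon, plane = plane, slab = as.numeric(slab),
                 label = label),
            class = "region_mask")
}

#' Rectangular region mask
#' @param xlim,ylim in-plane bounds (nm).
#' @inheritParams region_mask
#' @return a `region_mask`
#' @export
rect_mask <- function(xlim, ylim, plane = "xy", slab = c(-Inf, Inf),
                      label = "custom") {
  poly <- cbind(c(xlim[1L], xlim[2L], xlim[2L], xlim[1L]),
                c(ylim[1L], ylim[1L], ylim[2L], ylim[2L]))
  region_mask(poly, plane = plane, slab = slab, label = label)
}

# O(n^2) proper-crossing check between non-adjacent edges
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1L), ])
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the wrap-around
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1L], a[2L], a[3L], a[4L], b[1L], b[2L])
      d2 <- cross(a[1L], a[2L], a[3L], a[4L], b[3L], b[4L])
      d3 <- cross(b[1L], b[2L], b[3L], b[4L], a[1L], a[2L])
      d4 <- cross(b[1L], b[2L], b[3L], b[4L], a[3L], a[4L])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          all(c(d1, d2, d3, d4) != 0)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

.plane_axes <- list(xy = c("x", "y", "z"), xz = c("x", "z", "y"),
                    yz = c("y", "z", "x"))

#' Project localizations onto a mask's plane
#'
#' Selects the rows inside the mask's slab (half-open) and polygon and
#' returns their in-plane coordinates. Counts are conserved: the number of
#' projected points equals the number of rows passing both tests.
#'
#' @param table a [localization_table()] in the biological frame.
#' @param mask a [region_mask()].
#' @return data.frame `u`, `v` (nm) with attribute `n_input`.
#' @export
project_to_plane <- function(table, mask) {
  if (frame_kind(table) != "biological") {
    stop("project_to_plane expects a biological-frame table")
  }
  ax <- .plane_axes[[mask$plane]]
  u <- table[[ax[1L]]]; v <- table[[ax[2L]]]; w <- table[[ax[3L]]]
  in_slab <- w >= mask$slab[1L] & w < mask$slab[2L]
  u <- u[in_slab]; v <- v[in_slab]
  if (length(u) > 0L) {
    inp <- pracma::inpolygon(u, v, mask$polygon[, 1L], mask$polygon[, 2L],
                             boundary = TRUE)
    u <- u[inp]; v <- v[inp]
  }
  structure(data.frame(u = u, v = v), n_input = nrow(table),
            label = mask$label)
}

#' Sliding-window localization density
#'
#' Windows of side `window_size` are centred on a grid with spacing `step`;
#' a window is retained only when it lies fully inside the mask polygon.
#' Membership is half-open (`[c - w/2, c + w/2)` per axis) so no point is
#' counted twice by adjacent windows. Windows overlapping the mask edge are
#' dropped, not rescaled.
#'
#' @param points2d data.frame `u`, `v` from [project_to_plane()] (or any 2D
#'   point set in nm).
#' @param window_size window side (nm).
#' @param step grid spacing (nm).
#' @param mask optional [region_mask()]; its polygon bounds the grid. When
#'   absent, the bounding box of the points is used.
#' @return a `density_map`: data.frame `cu`, `cv` (window centres, nm),
#'   `count`, `density` (localizations/um^2), with attributes `window_size`,
#'   `step`.
#' @export
sliding_window_density <- function(points2d, window_size = 2000, step = 200,
                                   mask = NULL) {
  stopifnot(window_size > 0, step > 0)
  u <- points2d$u; v <- points2d$v
  if (is.null(mask)) {
    lo <- c(min(u), min(v)); hi <- c(max(u), max(v))
    poly <- NULL
  } else {
    lo <- apply(mask$polygon, 2L, min); hi <- apply(mask$polygon, 2L, max)
    poly <- mask$polygon
  }
  if (any(hi - lo < window_size)) {
    stop("mask extent smaller than the window size")
  }
  half <- window_size / 2
  cu <- seq(lo[1L] + half, hi[1L] - half + 1e-9, by = step)
  cv <- seq(lo[2L] + half, hi[2L] - half + 1e-9, by = step)
  grid <- expand.grid(cu = cu, cv = cv)
  if (!is.null(poly)) {
    inside <- rep(TRUE, nrow(grid))
    for (du in c(-half, half)) for (dv in c(-half, half)) {
      inside <- inside & pracma::inpolygon(grid$cu + du, grid$cv + dv,
                                           poly[, 1L], poly[, 2L],
                                           boundary = TRUE)
    }
    grid <- grid[inside, , drop = FALSE]
  }
  if (nrow(grid) == 0L) stop("no window fits fully inside the mask")
  ratio <- window_size / step
  if (abs(ratio - round(ratio)) < 1e-9) {
    counts <- .window_counts_binned(u, v, grid, cu, cv, window_size, step)
  } else {
    counts <- vapply(seq_len(nrow(grid)), function(i) {
      sum(u >= grid$cu[i] - half & u < grid$cu[i] + half &
            v >= grid$cv[i] - half & v < grid$cv[i] + half)
    }, integer(1L))
  }
  area_um2 <- (window_size / 1000)^2
  structure(data.frame(cu = grid$cu, cv = grid$cv, count = counts,
                       density = counts / area_um2),
            window_size = window_size, step = step,
            class = c("density_map", "data.frame"))
}

# exact window counts via step-sized bins and a summed-area table; valid
# because window edges align with bin edges when window_size/step is integer
.window_counts_binned <- function(u, v, grid, cu, cv, window_size, step) {
  k <- as.integer(round(window_size / step))
  half <- window_size / 2
  # bin origin at the left edge of the first window
  ou <- cu[1L] - half; ov <- cv[1L] - half
  nbu <- as.integer(round((cu[length(cu)] + half - ou) / step))
  nbv <- as.integer(round((cv[length(cv)] + half - ov) / step))
  bu <- floor((u - ou) / step) + 1L
  bv <- floor((v - ov) / step) + 1L
  ok <- bu >= 1L & bu <= nbu & bv >= 1L & bv <= nbv
  h <- matrix(0L, nbu, nbv)
  if (any(ok)) {
    tab <- table(factor(bu[ok], levels = seq_len(nbu)),
                 factor(bv[ok], levels = seq_len(nbv)))
    h <- matrix(as.integer(tab), nbu, nbv)
  }
  sat <- apply(apply(h, 2L, cumsum), 1L, cumsum)  # sat[j, i] after transpose
  sat <- t(sat)
  at <- function(i, j) {
    if (i < 1L || j < 1L) return(0L)
    sat[min(i, nbu), min(j, nbv)]
  }
  iu <- as.integer(round((grid$cu - half - ou) / step))  # bins before window
  iv <- as.integer(round((grid$cv - half - ov) / step))
  vapply(seq_len(nrow(grid)), function(g) {
    i0 <- iu[g]; j0 <- iv[g]
    as.integer(at(i0 + k, j0 + k) - at(i0, j0 + k) - at(i0 + k, j0) +
                 at(i0, j0))
  }, integer(1L))
}

#' Summarize a density map
#'
#' Median, raw median absolute deviation (no normal-consistency scaling, the
#' "median +/- MAD" convention), quartiles and 1.5 x IQR whiskers (drawn to
#' the furthest datum within that range) over the window densities.
#'
#' @param map a `density_map` from [sliding_window_density()].
#' @return a `density_summary`.
#' @export
summarize_density <- function(map) {
  d <- map$density
  if (length(d) == 0L) stop("empty density map")
  med <- stats::median(d)
  mad_raw <- stats::median(abs(d - med))
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  lo_lim <- q[1L] - 1.5 * iqr; hi_lim <- q[2L] + 1.5 * iqr
  structure(list(median = med, mad = mad_raw, q1 = q[1L], q3 = q[2L],
                 whisker_lo = min(d[d >= lo_lim]),
                 whisker_hi = max(d[d <= hi_lim]),
                 n_windows = length(d)),
            class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("Density: %.0f +/- %.0f localizations/um^2 (median +/- MAD)\n",
              x$median, x$mad))
  cat(sprintf("  quartiles [%.0f, %.0f], whiskers [%.0f, %.0f], n = %d windows\n",
              x$q1, x$q3, x$whisker_lo, x$whisker_hi, x$n_windows))
  invisible(x)
}

#' @export
plot.density_map <- function(x, ...) {
  cu <- sort(unique(x$cu)); cv <- sort(unique(x$cv))
  img <- matrix(NA_real_, length(cu), length(cv))
  img[cbind(match(x$cu, cu), match(x$cv, cv))] <- x$density
  graphics::image(cu / 1000, cv / 1000, img, xlab = "u (um)",
                  ylab = "v (um)", main = "window density (loc/um^2)", ...)
  invisible(x)
}

#' Render a 2D histogram image of projected localizations
#'
#' @param points2d data.frame `u`, `v` (nm).
#' @param render_pixel pixel size of the rendering (nm).
#' @param origin c(u0, v0) of the image's low corner; defaults to the points'
#'   floor on the pixel grid.
#' @return integer matrix of counts (rows = v, cols = u) with attributes
#'   `origin` and `render_pixel`; the image total equals the point count.
#' @export
render_histogram_image <- function(points2d, render_pixel = 20,
                                   origin = NULL) {
  stopifnot(render_pixel > 0)
  u <- points2d$u; v <- points2d$v
  if (length(u) == 0L) {
    img <- matrix(0L, 1L, 1L)
    attr(img, "origin") <- c(0, 0)
    attr(img, "render_pixel") <- render_pixel
    return(img)
  }
  if (is.null(origin)) {
    origin <- c(floor(min(u) / render_pixel), floor(min(v) / render_pixel)) *
      render_pixel
  }
  iu <- floor((u - origin[1L]) / render_pixel) + 1L
  iv <- floor((v - origin[2L]) / render_pixel) + 1L
  nu <- max(iu); nv <- max(iv)
  img <- matrix(0L, nv, nu)
  for (k in seq_along(iu)) img[iv[k], iu[k]] <- img[iv[k], iu[k]] + 1L
  attr(img, "origin") <- origin
  attr(img, "render_pixel") <- render_pixel
  img
}
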