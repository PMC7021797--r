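# Single-particle tracking: Crocker-Grier linking of per-frame 3D
# localizations, time-averaged and ensemble mean square displacement, and the
# free-diffusion fit MSD(tau) = o + 2*D*tau per dimension.

#' Link localizations into trajectories
#'
#' Crocker-Grier formulation: frame to frame, the assignment between open
#' track ends and new localizations that minimizes the total squared
#' displacement, among candidate pairs closer than `max_disp`; a non-link
#' carries cost `max_disp^2`. Unmatched localizations start new tracks;
#' track ends survive gaps of up to `memory` frames. The optimal assignment
#' is solved exactly by exhaustive enumeration within connected candidate
#' subnetworks (which are small at trackable densities).
#'
#' @param table a [localization_table()] or data.frame with `frame`, `x`,
#'   `y` and optionally `z` (nm).
#' @param max_disp maximum displacement per frame link (nm).
#' @param memory frames a track end survives without a localization.
#' @param dt frame interval (s), used to fill the `t` column.
#' @param max_subnet largest subnetwork enumerated exactly; beyond it a
#'   greedy nearest-neighbour fallback is used with a warning.
#' @return a `trajectory_set`: list of data.frames `id, frame, t, x, y, z`
#'   (only tracks with >= 2 localizations), with attribute `dt`.
#' @export
link_localizations <- function(table, max_disp = 500, memory = 1L,
                               dt = 0.02, max_subnet = 10L) {
  df <- as.data.frame(table)
  if (is.null(df$z)) df$z <- 0
  df <- df[order(df$frame), , drop = FALSE]
  frames <- sort(unique(df$frame))
  # open track state
  tr_x <- numeric(0); tr_y <- numeric(0); tr_z <- numeric(0)
  tr_frame <- integer(0); tr_id <- integer(0)
  open <- integer(0)   # indices into the track state that may still link
  n_tracks <- 0L
  members <- list()    # per track: row indices of df
  for (f in frames) {
    rows <- which(df$frame == f)
    px <- df$x[rows]; py <- df$y[rows]; pz <- df$z[rows]
    open <- open[f - tr_frame[open] <= memory + 1L]
    assignment <- rep(NA_integer_, length(rows))
    if (length(open) > 0L && length(rows) > 0L) {
      dx <- outer(tr_x[open], px, "-")
      dy <- outer(tr_y[open], py, "-")
      dz <- outer(tr_z[open], pz, "-")
      cost <- dx^2 + dy^2 + dz^2
      cost[cost > max_disp^2] <- Inf
      assignment <- .assign_links(cost, max_disp^2, max_subnet)
    }
    linked_tracks <- integer(0)
    for (j in seq_along(rows)) {
      a <- assignment[j]
      if (!is.na(a)) {
        ti <- open[a]
        members[[ti]] <- c(members[[ti]], rows[j])
        tr_x[ti] <- px[j]; tr_y[ti] <- py[j]; tr_z[ti] <- pz[j]
        tr_frame[ti] <- f
        linked_tracks <- c(linked_tracks, ti)
      } else {
        n_tracks <- n_tracks + 1L
        tr_x[n_tracks] <- px[j]; tr_y[n_tracks] <- py[j]
        tr_z[n_tracks] <- pz[j]; tr_frame[n_tracks] <- f
        members[[n_tracks]] <- rows[j]
        linked_tracks <- c(linked_tracks, n_tracks)
      }
    }
    open <- sort(unique(c(open, linked_tracks)))
  }
  out <- list()
  id <- 0L
  for (ti in seq_len(n_tracks)) {
    rows <- members[[ti]]
    if (length(rows) < 2L) next
    id <- id + 1L
    out[[id]] <- data.frame(id = id, frame = df$frame[rows],
                            t = df$frame[rows] * dt,
                            x = df$x[rows], y = df$y[rows], z = df$z[rows])
  }
  structure(out, dt = dt, class = "trajectory_set")
}

# Optimal assignment of columns (new points) to rows (open tracks) of a cost
# matrix with Inf marking non-candidates; a non-link costs null_cost for each
# unmatched row and column participating in the subnetwork. Exact exhaustive
# enumeration within connected components.
.assign_links <- function(cost, null_cost, max_subnet) {
  nr <- nrow(cost); nc <- ncol(cost)
  assignment <- rep(NA_integer_, nc)
  finite <- is.finite(cost)
  if (!any(finite)) return(assignment)
  # connected components over the bipartite candidate graph
  comp_r <- rep(0L, nr); comp_c <- rep(0L, nc)
  ncomp <- 0L
  for (j in seq_len(nc)) {
    if (comp_c[j] != 0L || !any(finite[, j])) next
    ncomp <- ncomp + 1L
    stack_c <- j
    while (length(stack_c) > 0L) {
      cj <- stack_c[1L]; stack_c <- stack_c[-1L]
      if (comp_c[cj] != 0L) next
      comp_c[cj] <- ncomp
      for (ri in which(finite[, cj] & comp_r == 0L)) {
        comp_r[ri] <- ncomp
        stack_c <- c(stack_c, which(finite[ri, ] & comp_c == 0L))
      }
    }
  }
  for (cm in seq_len(ncomp)) {
    rs <- which(comp_r == cm); cs <- which(comp_c == cm)
    if (length(rs) > max_subnet || length(cs) > max_subnet) {
      warning("linking subnetwork larger than max_subnet; using greedy ",
              "fallback")
      assignment[cs] <- .assign_greedy(cost[rs, cs, drop = FALSE], rs)
      next
    }
    sub <- cost[rs, cs, drop = FALSE]
    best <- list(cost = Inf, pick = rep(NA_integer_, length(cs)))
    pick <- rep(NA_integer_, length(cs))
    used <- rep(FALSE, length(rs))
    recurse <- function(jj, acc) {
      if (acc >= best$cost) return()
      if (jj > length(cs)) {
        # unmatched rows in the subnet also pay the null cost
        total <- acc + null_cost * sum(!used)
        if (total < best$cost) best <<- list(cost = total, pick = pick)
        return()
      }
      # option: leave column jj unmatched
      pick[jj] <<- NA_integer_
      recurse(jj + 1L, acc + null_cost)
      for (ii in seq_along(rs)) {
        if (!used[ii] && is.finite(sub[ii, jj])) {
          used[ii] <<- TRUE; pick[jj] <<- ii
          recurse(jj + 1L, acc + sub[ii, jj])
          used[ii] <<- FALSE; pick[jj] <<- NA_integer_
        }
      }
    }
    recurse(1L, 0)
    assignment[cs] <- ifelse(is.na(best$pick), NA_integer_, rs[best$pick])
  }
  # map back to row indices within the original matrix: callers expect the
  # index into the open-track vector
  assignment
}

.assign_greedy <- function(sub, rs) {
  pick <- rep(NA_integer_, ncol(sub))
  repeat {
    if (!any(is.finite(sub))) break
    k <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    pick[k[2L]] <- rs[k[1L]]
    sub[k[1L], ] <- Inf
    sub[, k[2L]] <- Inf
  }
  pick
}

#' @export
print.trajectory_set <- function(x, ...) {
  lens <- vapply(x, nrow, integer(1L))
  cat(sprintf("Trajectory set: %d tracks, lengths %s (dt = %g s)\n",
              length(x),
              if (length(lens)) paste0(min(lens), "..", max(lens)) else "-",
              attr(x, "dt")))
  invisible(x)
}

# ---- mean square displacement -------------------------------------------

#' Time-averaged MSD of one trajectory
#'
#' For lag k, the mean over all (overlapping) ordered sample pairs separated
#' by k frames of the squared displacement, per dimension. Lags with no pair
#' (gaps, or exceeding the track span) are absent from the result, not zero.
#'
#' @param traj data.frame `frame`, `t`, `x`, `y`, `z` for a single track.
#' @param max_lag largest lag (frames) to evaluate; default the track span.
#' @return data.frame `lag`, `tau` (s), `msd_x`, `msd_y`, `msd_z` (nm^2),
#'   `n` (pairs per lag).
#' @export
compute_msd <- function(traj, max_lag = NULL) {
  stopifnot(nrow(traj) >= 2L)
  dt_s <- (traj$t[2L] - traj$t[1L]) / (traj$frame[2L] - traj$frame[1L])
  f0 <- min(traj$frame)
  span <- max(traj$frame) - f0
  if (is.null(max_lag)) max_lag <- span
  # frame-indexed position vectors with NA in gaps
  nslot <- span + 1L
  xs <- rep(NA_real_, nslot); ys <- xs; zs <- xs
  slot <- traj$frame - f0 + 1L
  xs[slot] <- traj$x; ys[slot] <- traj$y; zs[slot] <- traj$z
  res <- vector("list", max_lag)
  for (k in seq_len(min(max_lag, span))) {
    i <- seq_len(nslot - k)
    dx <- xs[i + k] - xs[i]; dy <- ys[i + k] - ys[i]; dz <- zs[i + k] - zs[i]
    ok <- !is.na(dx)
    if (!any(ok)) next
    res[[k]] <- data.frame(lag = k, tau = k * dt_s,
                           msd_x = mean(dx[ok]^2), msd_y = mean(dy[ok]^2),
                           msd_z = mean(dz[ok]^2), n = sum(ok))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(lag = integer(0), tau = numeric(0),
                      msd_x = numeric(0), msd_y = numeric(0),
                      msd_z = numeric(0), n = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Ensemble MSD over a trajectory set
#'
#' Tracks shorter than `min_track_len` localizations are excluded; at each
#' lag the ensemble MSD is the pair-count-weighted mean of the per-track
#' time-averaged MSDs.
#'
#' @param trajectories a `trajectory_set` (or list of track data.frames).
#' @param min_track_len minimum track length (localizations) to contribute.
#' @param max_lag largest lag to report; default the largest available.
#' @return an `msd_result`: data.frame `lag`, `tau`, `msd_x`, `msd_y`,
#'   `msd_z`, `n` with attribute `n_tracks`.
#' @export
ensemble_msd <- function(trajectories, min_track_len = 20L, max_lag = NULL) {
  keep <- Filter(function(tr) nrow(tr) >= min_track_len, trajectories)
  if (length(keep) == 0L) {
    stop("no track reaches min_track_len = ", min_track_len)
  }
  per <- lapply(keep, compute_msd, max_lag = max_lag)
  all_lags <- sort(unique(unlist(lapply(per, `[[`, "lag"))))
  rows <- lapply(all_lags, function(k) {
    parts <- lapply(per, function(m) m[m$lag == k, , drop = FALSE])
    parts <- parts[vapply(parts, nrow, integer(1L)) > 0L]
    n <- sum(vapply(parts, `[[`, numeric(1L), "n"))
    wmean <- function(col) {
      sum(vapply(parts, function(p) p[[col]] * p$n, numeric(1L))) / n
    }
    data.frame(lag = k, tau = parts[[1L]]$tau[1L], msd_x = wmean("msd_x"),
               msd_y = wmean("msd_y"), msd_z = wmean("msd_z"), n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_tracks = length(keep),
            class = c("msd_result", "data.frame"))
}

# ---- diffusion fit -------------------------------------------------------

#' Fit free-diffusion constants from an ensemble MSD
#'
#' Ordinary least squares of `MSD(tau) = o + 2 * D * tau` per dimension on
#' the first `n_fit_points` lag points (the short-lag regime where the
#' free-diffusion model is reliable). The offset `o` reflects the squared
#' localization precision and may fit negative on noisy data; it is reported
#' as-is with a warning, never clamped.
#'
#' @param msd an `msd_result` from [ensemble_msd()] (or a data.frame with
#'   `tau` and `msd_x/y/z` columns).
#' @param n_fit_points number of initial lag points to fit (>= 2).
#' @return a `diffusion_fit` with per-dimension `D` (um^2/s), `offset`
#'   (nm^2) and their standard errors.
#' @export
fit_diffusion <- function(msd, n_fit_points = 5L) {
  stopifnot(n_fit_points >= 2L)
  if (nrow(msd) < n_fit_points) {
    stop("need at least ", n_fit_points, " lag points, got ", nrow(msd))
  }
  sub <- msd[seq_len(n_fit_points), , drop = FALSE]
  dims <- c("x", "y", "z")
  est <- lapply(dims, function(r) {
    y <- sub[[paste0("msd_", r)]]
    fit <- stats::lm(y ~ sub$tau)
    cf <- stats::coef(fit)
    # a perfect fit triggers summary.lm's reliability warning; its zero
    # standard errors are exactly what we want to report
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
    list(D = cf[[2L]] / 2 / 1e6, D_se = se[[2L]] / 2 / 1e6,
         offset = cf[[1L]], offset_se = se[[1L]])
  })
  names(est) <- dims
  offs <- vapply(est, `[[`, numeric(1L), "offset")
  if (any(offs < 0)) {
    warning("negative MSD offset fitted in dimension(s) ",
            paste(dims[offs < 0], collapse = ", "),
            "; reported as-is (noisy data)")
  }
  structure(list(dims = est, n_fit_points = n_fit_points, msd = msd),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Free-diffusion fit (first %d lags, MSD = o + 2 D tau):\n",
              x$n_fit_points))
  for (r in names(x$dims)) {
    e <- x$dims[[r]]
    cat(sprintf("  D_%s = %.4f +/- %.4f um^2/s, o_%s = %.0f +/- %.0f nm^2\n",
                r, e$D, e$D_se, r, e$offset, e$offset_se))
  }
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  t(vapply(object$dims, function(e) {
    c(D = e$D, D_se = e$D_se, offset = e$offset, offset_se = e$offset_se)
  }, numeric(4L)))
}

#' @export
predict.diffusion_fit <- function(object, tau = NULL, ...) {
  if (is.null(tau)) tau <- object$msd$tau
  sapply(object$dims, function(e) e$offset + 2 * e$D * 1e6 * tau)
}

#' @export
plot.diffusion_fit <- function(x, ...) {
  m <- x$msd
  cols <- c(x = "black", y = "dodgerblue3", z = "firebrick3")
  ymax <- max(m$msd_x, m$msd_y, m$msd_z)
  graphics::plot(NA, xlim = range(m$tau), ylim = c(0, ymax),
                 xlab = "lag time (s)", ylab = "MSD (nm^2)", ...)
  for (r in names(cols)) {
    graphics::points(m$tau, m[[paste0("msd_", r)]], col = cols[[r]], pch = 3)
    e <- x$dims[[r]]
    graphics::abline(e$offset, 2 * e$D * 1e6, col = cols[[r]], lty = 2)
  }
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 3,
                   bty = "n")
  invisible(x)
}
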