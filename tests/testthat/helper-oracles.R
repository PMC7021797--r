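# Independent oracles used by the tests. These deliberately do not share
# code with the package implementation.

# Brute-force Crocker-Grier linking: per consecutive frame pair, plain
# exhaustive enumeration (no pruning) over all assignments of new points to
# open track ends within each connected candidate group (within max_disp,
# null link cost max_disp^2), minimizing total squared displacement. No gap
# closing (memory 0). Returns a per-row track label.
brute_force_link <- function(df, max_disp) {
  df <- df[order(df$frame), , drop = FALSE]
  if (is.null(df$z)) df$z <- 0
  frames <- sort(unique(df$frame))
  label <- integer(nrow(df))
  n_tracks <- 0L
  open_rows <- integer(0)  # row index of each open track's last point
  open_ids <- integer(0)
  prev_frame <- NULL
  for (f in frames) {
    rows <- which(df$frame == f)
    if (!is.null(prev_frame) && f - prev_frame > 1L) {
      open_rows <- integer(0); open_ids <- integer(0)
    }
    if (length(open_rows) == 0L) {
      for (r in rows) {
        n_tracks <- n_tracks + 1L
        label[r] <- n_tracks
      }
      open_rows <- rows; open_ids <- label[rows]
      prev_frame <- f
      next
    }
    cost <- outer(seq_along(open_rows), seq_along(rows),
                  Vectorize(function(i, j) {
                    sum((df[open_rows[i], c("x", "y", "z")] -
                           df[rows[j], c("x", "y", "z")])^2)
                  }))
    cost <- matrix(cost, length(open_rows), length(rows))
    cost[cost > max_disp^2] <- Inf
    m <- length(rows)
    pick_all <- rep(NA_integer_, m)
    # connected groups of mutually candidate tracks/points, solved separately
    grp_c <- rep(0L, m); grp_r <- rep(0L, length(open_rows)); ng <- 0L
    for (j0 in seq_len(m)) {
      if (grp_c[j0] != 0L || !any(is.finite(cost[, j0]))) next
      ng <- ng + 1L
      queue <- j0
      while (length(queue) > 0L) {
        j <- queue[1L]; queue <- queue[-1L]
        if (grp_c[j] != 0L) next
        grp_c[j] <- ng
        for (i in which(is.finite(cost[, j]) & grp_r == 0L)) {
          grp_r[i] <- ng
          queue <- c(queue, which(is.finite(cost[i, ]) & grp_c == 0L))
        }
      }
    }
    for (g in seq_len(ng)) {
      cs <- which(grp_c == g); rs <- which(grp_r == g)
      best <- list(cost = Inf, pick = NULL)
      recurse <- function(j, used, pick, acc) {
        if (j > length(cs)) {
          total <- acc + max_disp^2 * sum(!used)
          if (total < best$cost) best <<- list(cost = total, pick = pick)
          return()
        }
        recurse(j + 1L, used, c(pick, NA_integer_), acc + max_disp^2)
        for (ii in seq_along(rs)) {
          if (!used[ii] && is.finite(cost[rs[ii], cs[j]])) {
            used2 <- used; used2[ii] <- TRUE
            recurse(j + 1L, used2, c(pick, ii), acc + cost[rs[ii], cs[j]])
          }
        }
      }
      recurse(1L, rep(FALSE, length(rs)), integer(0), 0)
      pick_all[cs] <- ifelse(is.na(best$pick), NA_integer_, rs[best$pick])
    }
    new_open_rows <- integer(0); new_open_ids <- integer(0)
    for (j in seq_len(m)) {
      i <- pick_all[j]
      if (!is.na(i)) {
        label[rows[j]] <- open_ids[i]
      } else {
        n_tracks <- n_tracks + 1L
        label[rows[j]] <- n_tracks
      }
      new_open_rows <- c(new_open_rows, rows[j])
      new_open_ids <- c(new_open_ids, label[rows[j]])
    }
    open_rows <- new_open_rows; open_ids <- new_open_ids
    prev_frame <- f
  }
  label
}

# canonical form of a partition of row indices into tracks, for comparing
# two linkers independent of label numbering
partition_signature <- function(labels) {
  groups <- split(seq_along(labels), labels)
  groups <- lapply(groups, sort)
  sort(vapply(groups, paste, character(1L), collapse = ","))
}

# render a frame containing the given emitters and localize it back;
# shared by the engine accuracy tests
render_test_frame <- function(emitters, fov = c(48L, 48L),
                              cal = synthetic_calibration(),
                              photons = 2000, background = 5,
                              noise = FALSE) {
  render_frame(emitters, fov, cal, pixel_size = 103.8,
               mean_photons = photons, background = background,
               noise = noise)
}

# solve for the cap height giving a one-cell scene a prescribed basal area
scene_with_basal_area <- function(area_um2, rho_basal, cap_radius = 4000) {
  a <- sqrt(area_um2 * 1e6 / pi)
  h <- uniroot(function(h) h * (2 * cap_radius - h) - a^2,
               c(1, cap_radius))$root
  scene_spec(cap_radius = cap_radius, cap_height = h, rho_basal = rho_basal,
             rho_apical = 0, rho_interface = 0, n_cells = 1L)
}
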