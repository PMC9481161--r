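# Time-lapse motility analysis: track linking, reversal detection, speeds,
# leading/lagging pole assignment and the signed dynamic asymmetry index.

#' Construct a track
#'
#' A track is one cell followed over frames: centroids, the two persistent
#' pole anchors (identities "a"/"b" never relabel at reversals) and per-pole
#' cluster fluorescence.
#'
#' @param frames data frame with columns `frame`, `cx`, `cy`, `pole_a_row`,
#'   `pole_a_col`, `pole_b_row`, `pole_b_col`, `F_pole_a`, `F_pole_b`; frame
#'   indices strictly increasing.
#' @param frame_interval_s seconds between consecutive frames.
#' @param cell_id track identifier.
#' @param cell_width_px typical cell width, used as the default reversal
#'   displacement gate.
#' @return an object of class `pq_track`.
#' @export
pq_track <- function(frames, frame_interval_s, cell_id = 1L,
                     cell_width_px = 9) {
  need <- c("frame", "cx", "cy", "pole_a_row", "pole_a_col",
            "pole_b_row", "pole_b_col", "F_pole_a", "F_pole_b")
  assert_that(is.data.frame(frames) && all(need %in% names(frames)),
              "track frames must have columns: %s", paste(need, collapse = ", "))
  assert_that(all(diff(frames$frame) > 0),
              "frame indices must be strictly increasing")
  structure(list(frames = frames[need], frame_interval_s = frame_interval_s,
                 cell_id = as.integer(cell_id), cell_width_px = cell_width_px),
            class = "pq_track")
}

#' @export
print.pq_track <- function(x, ...) {
  cat(sprintf("track %d: %d frames every %g s\n", x$cell_id,
              nrow(x$frames), x$frame_interval_s))
  invisible(x)
}

#' Ground-truth tracks from a synthetic time-lapse
#'
#' Bypasses the image pipeline and builds one track per cell directly from
#' the generator's ground-truth table (useful for scoring the track-level
#' statistics in isolation).
#'
#' @param scene a `timelapse_scene` from [gen_timelapse()].
#' @return list of `pq_track` objects.
#' @export
tracks_from_truth <- function(scene) {
  stopifnot(inherits(scene, "timelapse_scene"))
  lapply(split(scene$tracks, scene$tracks$cell_id), function(df) {
    df <- df[order(df$frame), ]
    pq_track(df, scene$spec$frame_interval_s, cell_id = df$cell_id[1L],
             cell_width_px = scene$spec$cell_width_px)
  })
}

#' Per-frame cell observations for track linking
#'
#' Runs cell extraction and time-lapse-mode cluster detection on one frame
#' and returns the quantities the linker consumes.
#'
#' @param label_image,fluorescence_image one frame's matrices.
#' @param pole_fraction pole-region size.
#' @return data frame with one row per cell: centroid, pole anchors and
#'   per-pole cluster fluorescence totals (0 when no cluster was called).
#' @export
observe_frame <- function(label_image, fluorescence_image, pole_fraction = 0.2) {
  cells <- extract_cells(label_image, fluorescence_image)
  do.call(rbind, lapply(cells, function(cell) {
    cl <- detect_polar_clusters(cell, fluorescence_image, mode = "timelapse",
                                pole_fraction = pole_fraction)
    F_pole <- c(a = 0, b = 0)
    if (!isFALSE(attr(cl, "quantifiable"))) {
      for (x in cl) F_pole[x$pole_label] <- x$total_intensity
    }
    ctr <- colMeans(cell$pixels)
    data.frame(label = cell$cell_id, cx = ctr[2L], cy = ctr[1L],
               pole_a_row = cell$pole_a[1L], pole_a_col = cell$pole_a[2L],
               pole_b_row = cell$pole_b[1L], pole_b_col = cell$pole_b[2L],
               F_pole_a = unname(F_pole["a"]), F_pole_b = unname(F_pole["b"]))
  }))
}

#' Link per-frame observations into tracks
#'
#' Greedy nearest-centroid matching between consecutive frames with a maximum
#' displacement gate (default: half a cell length per frame). A previous-frame
#' cell with no current cell inside the gate ends its track; a current cell
#' claimed by no track starts a new one; an ambiguous match (more than one
#' candidate inside the gate on either side) terminates the tracks involved.
#' Pole identities are propagated by nearest-pole matching between
#' consecutive frames, so "a"/"b" stay fixed through reversals.
#'
#' @param observations list over frames of data frames from [observe_frame()].
#' @param frame_interval_s seconds between frames.
#' @param max_displacement gate in px/frame; default half the median pole-pole
#'   distance of the first frame.
#' @param cell_width_px stored on each track (reversal gate default).
#' @return list of `pq_track` objects (tracks spanning >= 2 frames).
#' @export
link_tracks <- function(observations, frame_interval_s,
                        max_displacement = NULL, cell_width_px = 9) {
  assert_that(length(observations) >= 2L, "need at least two frames")
  if (is.null(max_displacement)) {
    o1 <- observations[[1L]]
    len <- sqrt((o1$pole_a_row - o1$pole_b_row)^2 +
                  (o1$pole_a_col - o1$pole_b_col)^2)
    max_displacement <- stats::median(len) / 2
  }
  live <- list()      # open tracks: list(rows = data.frame, last = row)
  done <- list()
  next_id <- 1L
  as_row <- function(o, f) {
    data.frame(frame = f, cx = o$cx, cy = o$cy,
               pole_a_row = o$pole_a_row, pole_a_col = o$pole_a_col,
               pole_b_row = o$pole_b_row, pole_b_col = o$pole_b_col,
               F_pole_a = o$F_pole_a, F_pole_b = o$F_pole_b)
  }
  obs1 <- observations[[1L]]
  for (i in seq_len(nrow(obs1))) {
    live[[as.character(next_id)]] <- list(id = next_id,
                                          rows = as_row(obs1[i, ], 1L))
    next_id <- next_id + 1L
  }
  for (f in 2L:length(observations)) {
    cur <- observations[[f]]
    n_cur <- if (is.null(cur)) 0L else nrow(cur)
    closed <- character(0)
    claimed <- integer(0)
    assign_to <- stats::setNames(rep(NA_integer_, length(live)), names(live))
    if (n_cur > 0L && length(live) > 0L) {
      last <- do.call(rbind, lapply(live, function(tr) {
        tr$rows[nrow(tr$rows), c("cx", "cy")]
      }))
      d <- outer(seq_len(nrow(last)), seq_len(n_cur), Vectorize(function(i, j) {
        sqrt((last$cx[i] - cur$cx[j])^2 + (last$cy[i] - cur$cy[j])^2)
      }))
      within <- d <= max_displacement
      amb_track <- rowSums(within) > 1L
      amb_cell <- colSums(within) > 1L
      for (i in seq_along(live)) {
        if (amb_track[i]) { closed <- c(closed, names(live)[i]); next }
        j <- which(within[i, ])
        if (length(j) == 1L) {
          if (amb_cell[j]) {
            closed <- c(closed, names(live)[i])
            claimed <- c(claimed, j)   # ambiguous cell: consumed, no new track
          } else {
            assign_to[i] <- j
            claimed <- c(claimed, j)
          }
        } else {
          closed <- c(closed, names(live)[i])
        }
      }
    } else {
      closed <- names(live)
    }
    for (nm in names(live)) {
      j <- assign_to[nm]
      if (!is.na(j)) {
        prev <- live[[nm]]$rows[nrow(live[[nm]]$rows), ]
        o <- cur[j, ]
        # persistent pole identity: pair current poles with previous ones
        keep <- sqrt((prev$pole_a_row - o$pole_a_row)^2 +
                       (prev$pole_a_col - o$pole_a_col)^2) +
          sqrt((prev$pole_b_row - o$pole_b_row)^2 +
                 (prev$pole_b_col - o$pole_b_col)^2)
        swap <- sqrt((prev$pole_a_row - o$pole_b_row)^2 +
                       (prev$pole_a_col - o$pole_b_col)^2) +
          sqrt((prev$pole_b_row - o$pole_a_row)^2 +
                 (prev$pole_b_col - o$pole_a_col)^2)
        if (swap < keep) {
          o[c("pole_a_row", "pole_a_col", "pole_b_row", "pole_b_col",
              "F_pole_a", "F_pole_b")] <-
            o[c("pole_b_row", "pole_b_col", "pole_a_row", "pole_a_col",
                "F_pole_b", "F_pole_a")]
        }
        live[[nm]]$rows <- rbind(live[[nm]]$rows, as_row(o, f))
      }
    }
    for (nm in closed) {
      done[[length(done) + 1L]] <- live[[nm]]
      live[[nm]] <- NULL
    }
    if (n_cur > 0L) {
      for (j in setdiff(seq_len(n_cur), claimed)) {
        live[[as.character(next_id)]] <- list(id = next_id,
                                              rows = as_row(cur[j, ], f))
        next_id <- next_id + 1L
      }
    }
  }
  done <- c(done, unname(live))
  done <- Filter(function(tr) nrow(tr$rows) >= 2L, done)
  lapply(done, function(tr) {
    pq_track(tr$rows, frame_interval_s, cell_id = tr$id,
             cell_width_px = cell_width_px)
  })
}

#' Per-interval speeds of a track
#'
#' Euclidean centroid displacement between consecutive frames, per interval.
#'
#' @param track a `pq_track`.
#' @param unit_scale multiplier applied to pixel distances (e.g. um/px);
#'   default 1 keeps px/interval.
#' @return numeric vector of length `n_frames - 1`.
#' @export
compute_speeds <- function(track, unit_scale = 1) {
  fr <- track$frames
  sqrt(diff(fr$cx)^2 + diff(fr$cy)^2) * unit_scale
}

# Per-interval displacement projected on the cell's long axis (a -> b
# direction), plus the run decomposition used by the reversal detector:
# runs of constant projection sign (zero displacements continue the current
# run), with a cumulative-displacement gate on both sides of a sign change.
axis_projection <- function(track) {
  fr <- track$frames
  n <- nrow(fr)
  proj <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    u <- c(fr$pole_b_col[i] - fr$pole_a_col[i],
           fr$pole_b_row[i] - fr$pole_a_row[i])
    nu <- sqrt(sum(u^2))
    if (nu == 0) { proj[i] <- 0; next }
    u <- u / nu
    v <- c(fr$cx[i + 1L] - fr$cx[i], fr$cy[i + 1L] - fr$cy[i])
    proj[i] <- sum(v * u)
  }
  proj
}

reversal_runs <- function(proj, min_displacement) {
  eps <- 1e-9
  sgn <- sign(proj)
  sgn[abs(proj) < eps] <- 0
  # zeros continue the current run
  cur <- 0
  for (i in seq_along(sgn)) {
    if (sgn[i] == 0) sgn[i] <- cur else cur <- sgn[i]
  }
  # leading zeros take the first nonzero sign
  nz <- which(sgn != 0)
  if (length(nz) == 0L) {
    return(list(events = integer(0),
                runs = data.frame(start = 1L, end = length(proj),
                                  sign = 0, cum = 0)))
  }
  sgn[seq_len(nz[1L] - 1L)] <- sgn[nz[1L]]
  brk <- c(0L, which(diff(sgn) != 0), length(sgn))
  runs <- data.frame(start = utils::head(brk, -1L) + 1L, end = brk[-1L])
  runs$sign <- sgn[runs$start]
  recum <- function(runs) {
    runs$cum <- vapply(seq_len(nrow(runs)), function(r) {
      abs(sum(proj[runs$start[r]:runs$end[r]]))
    }, numeric(1))
    runs
  }
  runs <- recum(runs)
  # jitter runs (cumulative displacement below the gate) are absorbed into
  # the adjacent run that travelled further, keeping that run's direction;
  # adjacent same-direction runs are merged. What survives are runs that all
  # pass the gate, so every remaining boundary is a gated reversal.
  repeat {
    if (nrow(runs) == 1L) break
    same <- which(diff(runs$sign) == 0)
    if (length(same) > 0L) {
      i <- same[1L]
      runs$end[i] <- runs$end[i + 1L]
      runs <- recum(runs[-(i + 1L), , drop = FALSE])
      next
    }
    small <- which(runs$cum < min_displacement)
    if (length(small) == 0L) break
    i <- small[which.min(runs$cum[small])]
    nb <- intersect(c(i - 1L, i + 1L), seq_len(nrow(runs)))
    j <- nb[which.max(runs$cum[nb])]
    lo <- min(i, j); hi <- max(i, j)
    win_sign <- runs$sign[if (runs$cum[i] >= runs$cum[j]) i else j]
    runs$end[lo] <- runs$end[hi]
    runs$sign[lo] <- win_sign
    runs <- recum(runs[-hi, , drop = FALSE])
  }
  events <- if (nrow(runs) >= 2L) runs$start[-1L] + 1L else integer(0)
  list(events = as.integer(events), runs = runs)
}

#' Detect reversals along a track
#'
#' A reversal is a sign change of the axis-projected per-interval
#' displacement in which both the preceding and the following runs of
#' constant direction travel at least `min_displacement` cumulatively
#' (default: one cell width). Runs below the gate are treated as jitter and
#' absorbed. The reported event frame is the first frame moving in the new
#' direction.
#'
#' @param track a `pq_track`.
#' @param min_displacement cumulative-run gate in px; default the track's
#'   `cell_width_px`.
#' @return integer vector of event frame indices (possibly empty).
#' @export
detect_reversals <- function(track, min_displacement = NULL) {
  assert_that(nrow(track$frames) >= 3L, "need at least 3 frames")
  min_displacement <- min_displacement %||% track$cell_width_px
  proj <- axis_projection(track)
  reversal_runs(proj, min_displacement)$events
}

#' Reversal count over a reporting window
#'
#' Counts detected reversals in the first full window of the track (events
#' in tracks slightly longer than the window beyond its end are ignored; no
#' rate extrapolation).
#'
#' @param track a `pq_track`.
#' @param window_s reporting window in seconds (600 for the 10-min
#'   T4P-motility convention, 900 for the 15-min gliding convention).
#' @param min_displacement passed to [detect_reversals()].
#' @return integer count, or `NA` with a warning when the track is shorter
#'   than the window.
#' @export
reversal_frequency <- function(track, window_s, min_displacement = NULL) {
  dur <- (nrow(track$frames) - 1L) * track$frame_interval_s
  if (dur < window_s) {
    warning(sprintf("track %d (%.0f s) shorter than window (%.0f s); excluded",
                    track$cell_id, dur, window_s))
    return(NA_integer_)
  }
  ev <- detect_reversals(track, min_displacement)
  t_ev <- (ev - track$frames$frame[1L]) * track$frame_interval_s
  sum(t_ev <= window_s)
}

#' Fraction of moving cells
#'
#' A cell counts as moving when its median per-interval speed exceeds the
#' threshold.
#'
#' @param tracks list of `pq_track`s.
#' @param speed_threshold px/interval; default 0.5.
#' @return fraction in `[0, 1]`.
#' @export
fraction_moving <- function(tracks, speed_threshold = 0.5) {
  assert_that(length(tracks) >= 1L, "need at least one track")
  mean(vapply(tracks, function(tr) {
    stats::median(compute_speeds(tr)) > speed_threshold
  }, logical(1)))
}

#' Assign leading and lagging pole per frame
#'
#' The leading pole of a run is the persistent pole ("a" or "b") pointing in
#' the direction of motion; roles swap exactly at detected reversal events.
#'
#' @param track a `pq_track`.
#' @param min_displacement reversal gate, see [detect_reversals()].
#' @return character vector per frame: `"a"` or `"b"` naming the leading
#'   pole, `NA` if the track never moves.
#' @export
assign_leading_lagging <- function(track, min_displacement = NULL) {
  min_displacement <- min_displacement %||% track$cell_width_px
  n <- nrow(track$frames)
  proj <- axis_projection(track)
  rr <- reversal_runs(proj, min_displacement)
  if (all(rr$runs$sign == 0) ||
      (nrow(rr$runs) == 1L && rr$runs$cum[1L] < min_displacement)) {
    return(rep(NA_character_, n))   # track never moves beyond the gate
  }
  first_sign <- rr$runs$sign[1L]
  lead <- rep(NA_character_, n)
  sgn <- first_sign
  ev <- rr$events
  for (f in seq_len(n)) {
    if (length(ev) > 0 && f %in% ev) sgn <- -sgn
    lead[f] <- if (sgn > 0) "b" else "a"
  }
  lead
}

#' Dynamic asymmetry index along a track
#'
#' Signed per-frame asymmetry
#' `omega_dyn = (F_leading - F_lagging) / (F_leading + F_lagging)`:
#' -1 means unipolar at the lagging pole, +1 unipolar at the leading pole,
#' 0 bipolar symmetric. A frame is included only when the cell moved for
#' three or more successive frames without reversing, excluding the first
#' frame after a reversal and the last frame before a reversal; frames with
#' zero total polar fluorescence are also excluded.
#'
#' @param track a `pq_track` carrying per-pole fluorescence.
#' @param min_displacement reversal gate, see [detect_reversals()].
#' @return data frame (class `dynamic_omega_series`) with one row per frame:
#'   `frame`, `leading_pole`, `omega_dyn`, `included`.
#' @export
dynamic_omega <- function(track, min_displacement = NULL) {
  min_displacement <- min_displacement %||% track$cell_width_px
  fr <- track$frames
  n <- nrow(fr)
  lead <- assign_leading_lagging(track, min_displacement)
  ev <- detect_reversals(track, min_displacement)
  F_lead <- ifelse(lead == "a", fr$F_pole_a, fr$F_pole_b)
  F_lag <- ifelse(lead == "a", fr$F_pole_b, fr$F_pole_a)
  tot <- F_lead + F_lag
  omega <- ifelse(is.na(lead) | tot == 0, NA_real_, (F_lead - F_lag) / tot)
  included <- rep(!anyNA(lead), n)
  # run boundaries: reversal events split the track into runs of frames
  bounds <- c(1L, ev, n + 1L)
  for (r in seq_len(length(bounds) - 1L)) {
    s <- bounds[r]
    e <- bounds[r + 1L] - 1L
    run_len <- e - s + 1L
    if (run_len < 3L) {
      included[s:e] <- FALSE
      next
    }
    if (s > 1L) included[s] <- FALSE          # first frame after a reversal
    if (e < n) included[e] <- FALSE           # last frame before a reversal
  }
  included <- included & !is.na(omega)
  structure(data.frame(frame = fr$frame, leading_pole = lead,
                       omega_dyn = omega, included = included),
            class = c("dynamic_omega_series", "data.frame"))
}

#' Welch's two-sample t-test
#'
#' Two-tailed Student's t-test for samples with unequal variances: the Welch
#' statistic with Welch-Satterthwaite degrees of freedom. Implemented from
#' the defining formulas (and cross-checked against [stats::t.test()] in the
#' test suite).
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `statistic` (t), `df`, `p_value` (two-sided).
#' @export
welch_t_test <- function(sample_a, sample_b) {
  assert_that(length(sample_a) >= 2L && length(sample_b) >= 2L,
              "each sample needs n >= 2")
  n1 <- length(sample_a); n2 <- length(sample_b)
  m1 <- mean(sample_a); m2 <- mean(sample_b)
  v1 <- stats::var(sample_a); v2 <- stats::var(sample_b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    # degenerate: both samples constant
    if (m1 == m2) return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1))
    return(list(statistic = sign(m1 - m2) * Inf, df = n1 + n2 - 2,
                p_value = 0))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}
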