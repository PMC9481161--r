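# Synthetic microscopy scenes: snapshot fields and motility time-lapses with
# exact ground truth. Cells are axis-aligned rods (rectangle + semicircular
# caps) so pole anchors are known exactly; what the downstream analysis
# consumes is pole geometry, not cell curvature.

# Logical mask of a horizontal rod, W rows x L cols: pixels within W/2 of the
# medial segment.
rod_mask <- function(L, W) {
  rc <- (W + 1) / 2
  radius <- W / 2
  c1 <- 0.5 + radius
  c2 <- L + 0.5 - radius
  m <- matrix(FALSE, nrow = W, ncol = L)
  for (i in seq_len(W)) {
    for (j in seq_len(L)) {
      dx <- max(c1 - j, j - c2, 0)
      dy <- i - rc
      m[i, j] <- sqrt(dx^2 + dy^2) < radius
    }
  }
  m
}

# Pixels of `mask` ranked by distance to a pole anchor (local coords),
# restricted to within `max_axis_dist` columns of the pole tip.
pole_blob <- function(mask, anchor, n_px, max_axis_dist) {
  px <- which(mask, arr.ind = TRUE)
  keep <- abs(px[, 2L] - anchor[2L]) <= max_axis_dist
  px <- px[keep, , drop = FALSE]
  d <- sqrt((px[, 1L] - anchor[1L])^2 + (px[, 2L] - anchor[2L])^2)
  ord <- order(d, px[, 1L], px[, 2L])
  px[ord[seq_len(min(n_px, nrow(px)))], , drop = FALSE]
}

# Intended cluster layout for one cell: per-pole size and per-pixel intensity
# realizing the target asymmetry. Pole 1 of the record is whichever pole ends
# up brighter; `bright_first` randomizes which anatomical pole that is.
plan_clusters <- function(class, omega, spec, bright_first) {
  I_base <- spec$cluster_intensity_factor * spec$cytoplasm_mean
  s <- spec$cluster_size_px
  if (class == "diffuse") {
    return(list(sizes = c(0L, 0L), intens = c(0, 0)))
  }
  if (class == "unipolar") {
    sizes <- c(s, 0L); intens <- c(I_base, 0)
  } else if (class == "bipolar_asymmetric") {
    # dim pole at the guaranteed-detectable base intensity, bright pole scaled
    # up to realize the target asymmetry exactly
    F2 <- s * I_base
    F1 <- F2 * (1 + omega) / (1 - omega)
    sizes <- c(s, s); intens <- c(F1 / s, I_base)
  } else {
    F1 <- s * I_base
    F2 <- F1 * (1 - omega) / (1 + omega)
    sizes <- c(s, s); intens <- c(I_base, F2 / s)
  }
  if (!bright_first) {
    sizes <- rev(sizes); intens <- rev(intens)
  }
  list(sizes = as.integer(sizes), intens = intens)
}

#' Generate a synthetic snapshot scene with ground truth
#'
#' Places non-overlapping rod cells on a grid, draws cytoplasmic background
#' per cell, paints 0-2 polar clusters realizing each cell's intended
#' localization class and asymmetry index, and adds Gaussian pixel noise.
#' The generator is a pure function of the spec: identical specs (seed
#' included) give bit-identical images.
#'
#' @param spec a [snapshot_population_spec()].
#' @param scene_shape optional `c(rows, cols)`; if the grid of cells does not
#'   fit, generation fails with a placement error. Default sizes the image to
#'   the population.
#' @return an object of class `snapshot_scene`: list with integer `label_image`
#'   (0 background, cell ids 1..n), numeric `fluorescence_image`, a `truth`
#'   data frame (per-cell intended class, intended asymmetry index `omega_true`,
#'   pole anchors, cluster sizes/intensities) and the `spec`.
#' @export
gen_snapshot_scene <- function(spec, scene_shape = NULL) {
  stopifnot(inherits(spec, "snapshot_population_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  L <- round(spec$cell_length_px)
  W <- round(spec$cell_width_px)
  margin <- 4L
  tile_w <- L + 2L * margin
  tile_h <- W + 2L * margin
  ntx <- ceiling(sqrt(n))
  nty <- ceiling(n / ntx)
  H_img <- nty * tile_h
  W_img <- ntx * tile_w
  if (!is.null(scene_shape)) {
    if (scene_shape[1] < H_img || scene_shape[2] < W_img) {
      stop_pq("placement failure: scene %d x %d cannot hold %d cells without overlap",
              scene_shape[1], scene_shape[2], n)
    }
    H_img <- scene_shape[1]; W_img <- scene_shape[2]
  }
  # the mixture is realized as exact stratified counts (largest-remainder
  # rounding), as in a published population table of n cells; cell order is
  # shuffled so class and image position are independent
  exact <- spec$pattern_mixture * n
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  classes <- sample(rep(PATTERN_CLASSES, counts))
  mask <- rod_mask(L, W)
  rc <- (W + 1) / 2
  anchor_a <- c(rc, 1)
  anchor_b <- c(rc, L)
  pole_axis_reach <- max(2, floor(0.2 * (L - 1)))
  fluor <- matrix(0, H_img, W_img)
  label <- matrix(0L, H_img, W_img)
  truth <- vector("list", n)
  cell_px <- which(mask, arr.ind = TRUE)
  for (k in seq_len(n)) {
    tx <- (k - 1L) %% ntx
    ty <- (k - 1L) %/% ntx
    row_off <- ty * tile_h + margin
    col_off <- tx * tile_w + margin
    cls <- classes[k]
    rng <- spec$omega_target_range[[cls]]
    omega <- if (cls == "diffuse") NA_real_ else stats::runif(1, rng[1], rng[2])
    bright_first <- stats::runif(1) < 0.5
    plan <- plan_clusters(cls, omega, spec, bright_first)
    # cytoplasmic background
    vals <- pmax(stats::rnorm(nrow(cell_px), spec$cytoplasm_mean,
                              spec$cytoplasm_sd), 0)
    idx <- cbind(cell_px[, 1L] + row_off, cell_px[, 2L] + col_off)
    fluor[idx] <- vals
    label[idx] <- k
    # clusters
    for (p in 1:2) {
      if (plan$sizes[p] >= 3L) {
        anc <- if (p == 1L) anchor_a else anchor_b
        blob <- pole_blob(mask, anc, plan$sizes[p], pole_axis_reach)
        bidx <- cbind(blob[, 1L] + row_off, blob[, 2L] + col_off)
        fluor[bidx] <- plan$intens[p]
      }
    }
    truth[[k]] <- data.frame(
      cell_id = k, class = cls, omega_true = omega,
      pole_a_row = rc + row_off, pole_a_col = 1 + col_off,
      pole_b_row = rc + row_off, pole_b_col = L + col_off,
      cluster_a_px = plan$sizes[1L], cluster_b_px = plan$sizes[2L],
      cluster_a_intensity = plan$intens[1L],
      cluster_b_intensity = plan$intens[2L])
  }
  if (spec$noise_sd > 0) {
    fluor <- pmax(fluor + matrix(stats::rnorm(length(fluor), 0, spec$noise_sd),
                                 nrow(fluor)), 0)
  }
  structure(list(label_image = label, fluorescence_image = fluor,
                 truth = do.call(rbind, truth), spec = spec),
            class = "snapshot_scene")
}

#' @export
print.snapshot_scene <- function(x, ...) {
  cat(sprintf("synthetic snapshot scene: %d cells, %d x %d px\n",
              nrow(x$truth), nrow(x$label_image), ncol(x$label_image)))
  print(table(x$truth$class))
  invisible(x)
}

#' Generate a synthetic motility time-lapse with ground truth
#'
#' Each cell glides in its own lane along its long axis with Gaussian
#' per-interval speeds and reverses as a Poisson process; at each true
#' reversal the direction flips instantaneously and the leading/lagging pole
#' roles swap with no lag. Per-pole cluster fluorescence is drawn per frame
#' from the spec's leading/lagging rule.
#'
#' @param spec a [track_spec()].
#' @return an object of class `timelapse_scene`: lists of per-frame
#'   `fluorescence` and `label` matrices, a `tracks` data frame (one row per
#'   cell per frame with true centroid, persistent pole anchors, per-pole
#'   cluster fluorescence totals, direction and leading pole), a `reversals`
#'   data frame (`cell_id`, `frame` of the first frame moving in the new
#'   direction), and the `spec`.
#' @export
gen_timelapse <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  n_frames <- floor(spec$duration_s / spec$frame_interval_s) + 1L
  L <- round(spec$cell_length_px)
  W <- round(spec$cell_width_px)
  margin <- 4L
  p_rev <- min(1, spec$reversal_rate * spec$frame_interval_s / 60)

  # simulate trajectories first, then size the image
  xs <- matrix(0, n, n_frames)          # centroid x offset (continuous)
  dirs <- matrix(0L, n, n_frames)       # direction during frame f -> f+1 run
  rev_events <- vector("list", n)
  for (k in seq_len(n)) {
    d <- sample(c(-1L, 1L), 1L)
    x <- 0
    ev <- integer(0)
    for (f in seq_len(n_frames)) {
      xs[k, f] <- x
      dirs[k, f] <- d
      if (f < n_frames) {
        if (stats::runif(1) < p_rev) {
          d <- -d
          ev <- c(ev, f + 1L)  # first frame moving in the new direction
        }
        step <- max(0, stats::rnorm(1, spec$speed_mean, spec$speed_sd))
        x <- x + d * step
      }
    }
    rev_events[[k]] <- ev
  }

  span <- max(apply(xs, 1, function(v) diff(range(v)))) + 1
  # lanes are spaced so that cells in different lanes always sit further
  # apart than the linker's displacement gate (half a cell length)
  margin_y <- max(margin, as.integer(ceiling(L / 2)))
  lane_h <- W + 2L * margin_y
  W_img <- as.integer(ceiling(span) + L + 2L * margin)
  H_img <- n * lane_h
  mask <- rod_mask(L, W)
  cell_px <- which(mask, arr.ind = TRUE)
  rc <- (W + 1) / 2
  pole_axis_reach <- max(2, floor(0.2 * (L - 1)))
  blob_a <- pole_blob(mask, c(rc, 1), spec$cluster_size_px, pole_axis_reach)
  blob_b <- pole_blob(mask, c(rc, L), spec$cluster_size_px, pole_axis_reach)

  draw_pole_intensity <- function(role) {
    r <- spec$pole_fluorescence_rule[[role]]
    if (r[["mean"]] <= 0) return(0)
    max(0, stats::rnorm(1, r[["mean"]], r[["sd"]]))
  }

  frames <- vector("list", n_frames)
  labels <- vector("list", n_frames)
  rows <- vector("list", n_frames * n)
  ri <- 0L
  base_col <- vapply(seq_len(n), function(k) {
    margin + 1L - as.integer(floor(min(xs[k, ])))
  }, integer(1))
  for (f in seq_len(n_frames)) {
    fl <- matrix(0, H_img, W_img)
    lb <- matrix(0L, H_img, W_img)
    for (k in seq_len(n)) {
      row_off <- (k - 1L) * lane_h + margin_y
      col_off <- base_col[k] + as.integer(round(xs[k, f])) - 1L
      vals <- pmax(stats::rnorm(nrow(cell_px), spec$cytoplasm_mean,
                                spec$cytoplasm_sd), 0)
      idx <- cbind(cell_px[, 1L] + row_off, cell_px[, 2L] + col_off)
      fl[idx] <- vals
      lb[idx] <- k
      # pole a = left pole, persistent; leading pole depends on direction
      lead <- if (dirs[k, f] > 0) "b" else "a"
      int_a <- draw_pole_intensity(if (lead == "a") "leading" else "lagging")
      int_b <- draw_pole_intensity(if (lead == "b") "leading" else "lagging")
      if (int_a > 0) {
        fl[cbind(blob_a[, 1L] + row_off, blob_a[, 2L] + col_off)] <- int_a
      }
      if (int_b > 0) {
        fl[cbind(blob_b[, 1L] + row_off, blob_b[, 2L] + col_off)] <- int_b
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        cell_id = k, frame = f, time_s = (f - 1L) * spec$frame_interval_s,
        cx = col_off + (L + 1) / 2, cy = row_off + rc,
        direction = dirs[k, f], leading_pole = lead,
        pole_a_row = row_off + rc, pole_a_col = col_off + 1,
        pole_b_row = row_off + rc, pole_b_col = col_off + L,
        F_pole_a = int_a * nrow(blob_a), F_pole_b = int_b * nrow(blob_b))
    }
    if (spec$noise_sd > 0) {
      fl <- pmax(fl + matrix(stats::rnorm(length(fl), 0, spec$noise_sd),
                             nrow(fl)), 0)
    }
    frames[[f]] <- fl
    labels[[f]] <- lb
  }
  revs <- do.call(rbind, c(list(data.frame(cell_id = integer(0),
                                           frame = integer(0))),
                           lapply(seq_len(n), function(k) {
                             if (length(rev_events[[k]]) == 0) NULL
                             else data.frame(cell_id = k, frame = rev_events[[k]])
                           })))
  structure(list(fluorescence = frames, labels = labels,
                 tracks = do.call(rbind, rows), reversals = revs, spec = spec),
            class = "timelapse_scene")
}

#' @export
print.timelapse_scene <- function(x, ...) {
  cat(sprintf("synthetic time-lapse: %d cells, %d frames every %g s, %d true reversals\n",
              x$spec$n_cells, length(x$fluorescence), x$spec$frame_interval_s,
              nrow(x$reversals)))
  invisible(x)
}
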