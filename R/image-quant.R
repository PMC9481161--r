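# Snapshot quantification: per-cell polar cluster detection, fluorescence
# partitioning, asymmetry index and localization-pattern classification.
#
# Conventions: images are numeric matrices indexed (row, col), 1-based as
# usual in R. A cell's two pole anchors are the extremal pixels of its
# principal axis. "Pole 1" of a localization record is by definition the
# brighter pole.

#' Extract per-cell objects from a label mask
#'
#' One `labeled_cell` per positive label in `label_image`. Pole anchors are
#' the two extremal pixels of the cell's principal axis (first principal
#' component of the pixel coordinates). Cells touching the image border are
#' flagged but kept.
#'
#' @param label_image integer matrix, 0 = background, positive integers = cell
#'   ids (e.g. read from a segmentation label TIFF).
#' @param fluorescence_image numeric matrix of the same shape.
#' @param frame_id integer stored on each cell (for time-lapse bookkeeping).
#' @return list of `labeled_cell` objects: `cell_id`, `pixels` (n x 2 matrix
#'   of row/col), `pole_a`, `pole_b` (length-2 anchors), `border` flag,
#'   `frame_id`. Empty label image gives an empty list.
#' @export
extract_cells <- function(label_image, fluorescence_image, frame_id = 1L) {
  assert_that(all(dim(label_image) == dim(fluorescence_image)),
              "label and fluorescence images must have identical shape")
  ids <- sort(unique(label_image[label_image > 0]))
  lapply(ids, function(id) {
    px <- which(label_image == id, arr.ind = TRUE)
    dimnames(px) <- NULL
    ctr <- colMeans(px)
    cc <- sweep(px, 2, ctr)
    ev <- eigen(stats::cov(cc), symmetric = TRUE)$vectors[, 1L]
    proj <- cc %*% ev
    pa <- px[which.min(proj), ]
    pb <- px[which.max(proj), ]
    border <- any(px[, 1L] == 1L | px[, 1L] == nrow(label_image) |
                    px[, 2L] == 1L | px[, 2L] == ncol(label_image))
    structure(list(cell_id = as.integer(id), pixels = px,
                   pole_a = as.numeric(pa), pole_b = as.numeric(pb),
                   border = border, frame_id = as.integer(frame_id)),
              class = "labeled_cell")
  })
}

#' Split a cell into its two pole regions
#'
#' Each region contains the cell pixels whose projection onto the long axis
#' lies within `pole_fraction` of the cell length from the respective pole.
#' The regions are always disjoint: at `pole_fraction = 0.5` (or for
#' degenerate near-square cells) pixels are assigned to the nearer pole.
#'
#' @param cell a `labeled_cell`.
#' @param pole_fraction fraction of the axis length defining each pole
#'   neighbourhood, in (0, 0.5]. Default 0.2.
#' @return list with elements `a` and `b`, each an n x 2 pixel matrix.
#' @export
identify_pole_regions <- function(cell, pole_fraction = 0.2) {
  assert_that(is_num1(pole_fraction) && pole_fraction > 0 && pole_fraction <= 0.5,
              "pole_fraction must be in (0, 0.5]")
  px <- cell$pixels
  ax <- cell$pole_b - cell$pole_a
  len <- sqrt(sum(ax^2))
  if (len < 2) {
    # degenerate cell: nearest-pole assignment of every pixel
    da <- sqrt(colSums((t(px) - cell$pole_a)^2))
    db <- sqrt(colSums((t(px) - cell$pole_b)^2))
    return(list(a = px[da <= db, , drop = FALSE],
                b = px[da > db, , drop = FALSE]))
  }
  u <- ax / len
  t <- as.numeric(sweep(px, 2, cell$pole_a) %*% u)
  in_a <- t <= pole_fraction * len
  in_b <- t >= (1 - pole_fraction) * len
  both <- in_a & in_b
  if (any(both)) {          # overlapping bands (pole_fraction = 0.5): split at midpoint
    in_a[both] <- t[both] <= len / 2
    in_b[both] <- !in_a[both]
  }
  list(a = px[in_a, , drop = FALSE], b = px[in_b, , drop = FALSE])
}

#' Detect polar fluorescent clusters in one cell
#'
#' Cytoplasmic statistics (mean and SD) are computed from the cell pixels
#' outside both pole regions. In each pole region, the candidate cluster is
#' the largest 4-connected component of pixels above
#' `mu_cyto + 2 * sd_cyto`; it is accepted as a polar cluster when its mean
#' intensity exceeds `mu_cyto + 2 * sd_cyto` and it spans at least 3 pixels.
#' In `"timelapse"` mode the candidate must additionally have a mean
#' intensity above `2 * mu_cyto`. At most one cluster per pole is returned.
#'
#' @param cell a `labeled_cell`.
#' @param fluorescence_image numeric matrix.
#' @param mode `"snapshot"` or `"timelapse"` (the latter adds the two-fold
#'   intensity rule).
#' @param pole_fraction passed to [identify_pole_regions()].
#' @return list of `polar_cluster` objects (0-2 entries), each with
#'   `cell_id`, `pole_label` ("a"/"b"), `pixels`, `mean_intensity`,
#'   `total_intensity`, `size_px`. Attributes: `mu_cyto`, `sd_cyto`,
#'   `quantifiable` (FALSE when fewer than 10 cytoplasmic pixels remain, in
#'   which case no clusters are reported).
#' @export
detect_polar_clusters <- function(cell, fluorescence_image,
                                  mode = c("snapshot", "timelapse"),
                                  pole_fraction = 0.2) {
  mode <- match.arg(mode)
  regions <- identify_pole_regions(cell, pole_fraction)
  keys <- function(m) paste(m[, 1L], m[, 2L])
  pole_keys <- c(keys(regions$a), keys(regions$b))
  cyto <- cell$pixels[!(keys(cell$pixels) %in% pole_keys), , drop = FALSE]
  if (nrow(cyto) < 10L) {
    out <- list()
    attr(out, "quantifiable") <- FALSE
    attr(out, "mu_cyto") <- NA_real_
    attr(out, "sd_cyto") <- NA_real_
    return(out)
  }
  cy_vals <- fluorescence_image[cyto]
  mu <- mean(cy_vals)
  sdv <- stats::sd(cy_vals)
  thr <- mu + 2 * sdv
  clusters <- list()
  for (lab in c("a", "b")) {
    reg <- regions[[lab]]
    if (nrow(reg) == 0L) next
    vals <- fluorescence_image[reg]
    supra <- reg[vals > thr, , drop = FALSE]
    if (nrow(supra) == 0L) next
    comp <- label_components4(supra)
    sizes <- tabulate(comp)
    totals <- vapply(seq_along(sizes), function(i) {
      sum(fluorescence_image[supra[comp == i, , drop = FALSE]])
    }, numeric(1))
    best <- order(-sizes, -totals)[1L]
    cand <- supra[comp == best, , drop = FALSE]
    cvals <- fluorescence_image[cand]
    ok <- mean(cvals) > thr && nrow(cand) >= 3L
    if (ok && mode == "timelapse") ok <- mean(cvals) > 2 * mu
    if (ok) {
      clusters[[length(clusters) + 1L]] <-
        structure(list(cell_id = cell$cell_id, pole_label = lab,
                       pixels = cand, mean_intensity = mean(cvals),
                       total_intensity = sum(cvals), size_px = nrow(cand)),
                  class = "polar_cluster")
    }
  }
  attr(clusters, "quantifiable") <- TRUE
  attr(clusters, "mu_cyto") <- mu
  attr(clusters, "sd_cyto") <- sdv
  clusters
}

#' Per-cell fluorescence partition and asymmetry index
#'
#' Pole fluorescence is the summed intensity of the detected cluster at that
#' pole (0 without a cluster). Pole 1 is by definition the brighter pole. The
#' asymmetry index is
#' `omega = (F_pole1 - F_pole2) / (F_pole1 + F_pole2)`,
#' defined only when at least one cluster was detected; a cell without
#' clusters is diffuse. Fractions are taken against total cell fluorescence,
#' so `f_pole1 + f_pole2 + f_cyto = 1`.
#'
#' @param cell a `labeled_cell`.
#' @param clusters result of [detect_polar_clusters()].
#' @param fluorescence_image numeric matrix.
#' @return a `localization_record`: list with `cell_id`, `f_pole1`, `f_pole2`,
#'   `f_cyto`, `omega` (`NA` when diffuse), `n_clusters`, `pattern`,
#'   `pole1_label` (which anatomical pole is pole 1), `border`.
#' @export
compute_localization <- function(cell, clusters, fluorescence_image) {
  if (isFALSE(attr(clusters, "quantifiable"))) {
    stop_pq("cell %d is unquantifiable (fewer than 10 cytoplasmic pixels)",
            cell$cell_id)
  }
  total <- sum(fluorescence_image[cell$pixels])
  assert_that(total > 0, "cell %d has non-positive total fluorescence",
              cell$cell_id)
  F_pole <- c(a = 0, b = 0)
  for (cl in clusters) F_pole[cl$pole_label] <- cl$total_intensity
  ord <- order(-F_pole)
  F1 <- F_pole[ord[1L]]
  F2 <- F_pole[ord[2L]]
  n_cl <- length(clusters)
  omega <- if (n_cl >= 1L) (F1 - F2) / (F1 + F2) else NA_real_
  rec <- structure(list(cell_id = cell$cell_id,
                        f_pole1 = unname(F1 / total),
                        f_pole2 = unname(F2 / total),
                        f_cyto = unname(1 - (F1 + F2) / total),
                        omega = unname(omega), n_clusters = n_cl,
                        pattern = NA_character_,
                        pole1_label = names(F_pole)[ord[1L]],
                        border = cell$border),
                   class = "localization_record")
  rec$pattern <- classify_pattern(rec)
  rec
}

#' Bin a localization record into a pattern class
#'
#' Classes follow the standard asymmetry-index binning: unipolar
#' (`omega > 0.9`), bipolar asymmetric (`0.2 < omega <= 0.9`), bipolar
#' symmetric (`omega <= 0.2`); a cell with no detected polar signal is
#' diffuse. The boundary values 0.9 and 0.2 are assigned to the less extreme
#' class.
#'
#' @param record a `localization_record`, or a numeric asymmetry-index vector
#'   (then `NA` means diffuse).
#' @return character pattern class(es).
#' @export
classify_pattern <- function(record) {
  omega <- if (inherits(record, "localization_record")) {
    if (record$n_clusters == 0L) NA_real_ else record$omega
  } else {
    as.numeric(record)
  }
  out <- ifelse(is.na(omega), "diffuse",
                ifelse(omega > 0.9, "unipolar",
                       ifelse(omega > 0.2, "bipolar_asymmetric",
                              "bipolar_symmetric")))
  unname(out)
}

#' Summarize localization over a cell population
#'
#' Computes the percentage of cells in each pattern class, the mean pole
#' fractions and mean cytoplasmic fluorescence percentage among cells with
#' polar clusters, and the pole-2 versus pole-1 scatter table (per-cell
#' percentages of total fluorescence, class-coded) that underlies the
#' standard population scatter plot.
#'
#' @param records list of `localization_record`s, or the data frame from
#'   [records_table()].
#' @return a `population_summary`: `n_cells`, `percent` (named vector over
#'   the four classes, summing to 100), `mean_f_pole1`, `mean_f_pole2`,
#'   `mean_percent_cyto` (over cells with clusters), `scatter` data frame.
#' @export
summarize_population <- function(records) {
  df <- if (is.data.frame(records)) records else records_table(records)
  assert_that(nrow(df) >= 1L, "summarize_population needs at least one record")
  pct <- 100 * vapply(PATTERN_CLASSES,
                      function(cl) mean(df$pattern == cl), numeric(1))
  polar <- df[df$n_clusters >= 1L, , drop = FALSE]
  structure(list(
    n_cells = nrow(df),
    percent = pct,
    mean_f_pole1 = if (nrow(polar)) mean(polar$f_pole1) else NA_real_,
    mean_f_pole2 = if (nrow(polar)) mean(polar$f_pole2) else NA_real_,
    mean_percent_cyto = if (nrow(polar)) 100 * mean(polar$f_cyto) else NA_real_,
    scatter = data.frame(cell_id = polar$cell_id,
                         f_pole1_pct = 100 * polar$f_pole1,
                         f_pole2_pct = 100 * polar$f_pole2,
                         pattern = polar$pattern)),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population of %d cells\n", x$n_cells))
  for (cl in names(x$percent)) {
    cat(sprintf("  %-20s %5.1f %%\n", cl, x$percent[[cl]]))
  }
  if (!is.na(x$mean_percent_cyto)) {
    cat(sprintf("  mean cytoplasmic fluorescence (cells with clusters): %.1f %%\n",
                x$mean_percent_cyto))
  }
  invisible(x)
}

#' Flatten localization records to a data frame
#'
#' @param records list of `localization_record`s.
#' @return data frame with one row per cell (columns `cell_id`, `f_pole1`,
#'   `f_pole2`, `f_cyto`, `omega`, `n_clusters`, `pattern`, `border`).
#' @export
records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(cell_id = r$cell_id, f_pole1 = r$f_pole1, f_pole2 = r$f_pole2,
               f_cyto = r$f_cyto, omega = r$omega, n_clusters = r$n_clusters,
               pattern = r$pattern, border = r$border)
  }))
}

#' Run the full snapshot pipeline on an image pair
#'
#' Convenience wrapper: [extract_cells()], [detect_polar_clusters()],
#' [compute_localization()] and [summarize_population()] in one call.
#' Unquantifiable cells (too little cytoplasm) are dropped with a message.
#'
#' @param label_image,fluorescence_image matrices of identical shape.
#' @param mode cluster-calling mode, see [detect_polar_clusters()].
#' @param pole_fraction pole-region size, see [identify_pole_regions()].
#' @return list with `records` (data frame) and `summary`
#'   (`population_summary`).
#' @export
quantify_snapshot <- function(label_image, fluorescence_image,
                              mode = "snapshot", pole_fraction = 0.2) {
  cells <- extract_cells(label_image, fluorescence_image)
  recs <- list()
  dropped <- 0L
  for (cell in cells) {
    cl <- detect_polar_clusters(cell, fluorescence_image, mode = mode,
                                pole_fraction = pole_fraction)
    if (isFALSE(attr(cl, "quantifiable"))) {
      dropped <- dropped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- compute_localization(cell, cl,
                                                      fluorescence_image)
  }
  if (dropped > 0L) {
    message(sprintf("dropped %d unquantifiable cell(s)", dropped))
  }
  assert_that(length(recs) > 0L, "no quantifiable cells in image")
  df <- records_table(recs)
  list(records = df, summary = summarize_population(df))
}
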