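# Hand-built single-cell images with exactly known cytoplasmic statistics,
# used to exercise the cluster-calling arithmetic without the generator.

# A rectangular 9 x 30 px "rod" whose cytoplasm (outside the two 20% pole
# regions) has sample mean `cyto_mean` and sample SD `cyto_sd` exactly
# (alternating +/- x values). Returns label image, fluorescence image and the
# extracted cell.
make_test_cell <- function(cyto_mean = 100, cyto_sd = 10,
                           pole_fill = cyto_mean) {
  H <- 19L; W <- 44L
  rows <- 6:14; cols <- 8:37          # 9 x 30 rectangle, away from borders
  label <- matrix(0L, H, W)
  fluor <- matrix(0, H, W)
  label[rows, cols] <- 1L
  # pole regions at fraction 0.2: axis length 29, bands of 5.8 from each pole
  # -> region a = cols 8..13, region b = cols 32..37; cytoplasm = cols 14..31
  cyto_cols <- 14:31
  n_cyto <- length(rows) * length(cyto_cols)
  stopifnot(n_cyto %% 2 == 0)
  x <- cyto_sd * sqrt((n_cyto - 1) / n_cyto)
  vals <- rep(c(cyto_mean - x, cyto_mean + x), n_cyto / 2)
  fluor[rows, cols] <- pole_fill
  fluor[rows, cyto_cols] <- matrix(vals, nrow = length(rows))
  cell <- extract_cells(label, fluor)[[1L]]
  list(label = label, fluor = fluor, cell = cell,
       region_a_cols = 8:13, region_b_cols = 32:37, rows = rows)
}

# Paint a cluster of `size` pixels at constant `intensity` into pole region a
# (or b) of a make_test_cell() image; pixels are 4-connected.
paint_cluster <- function(fix, intensity, size, pole = "a") {
  cols <- if (pole == "a") fix$region_a_cols else rev(fix$region_b_cols)
  # lay pixels column-major down the first pole column(s), always 4-connected
  px <- NULL
  k <- 0L
  for (cc in cols) {
    for (rr in fix$rows) {
      if (k >= size) break
      px <- rbind(px, c(rr, cc))
      k <- k + 1L
    }
    if (k >= size) break
  }
  fix$fluor[px] <- intensity
  fix
}

# A simple straight-line track object: the cell moves along +x with the given
# per-interval displacements (vector), poles 30 px apart on the x axis.
make_line_track <- function(displacements, F_a = 0, F_b = 0,
                            frame_interval_s = 30, cell_width_px = 9) {
  x <- cumsum(c(0, displacements))
  n <- length(x)
  F_a <- rep_len(F_a, n)
  F_b <- rep_len(F_b, n)
  pq_track(data.frame(frame = seq_len(n), cx = 100 + x, cy = 50,
                      pole_a_row = 50, pole_a_col = 85 + x,
                      pole_b_row = 50, pole_b_col = 115 + x,
                      F_pole_a = F_a, F_pole_b = F_b),
           frame_interval_s = frame_interval_s, cell_width_px = cell_width_px)
}
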