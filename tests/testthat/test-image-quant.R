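# Snapshot quantification: cell extraction, pole regions, cluster calling,
# asymmetry index and pattern classification.

test_that("extract_cells finds rods and their pole anchors", {
  fix <- make_test_cell()
  cells <- extract_cells(fix$label, fix$fluor)
  expect_length(cells, 1)
  cell <- cells[[1]]
  # poles are the extremal pixels of the principal (horizontal) axis
  pole_cols <- sort(c(cell$pole_a[2], cell$pole_b[2]))
  expect_equal(pole_cols, c(8, 37))
  expect_equal(cell$pole_a[1], cell$pole_b[1], tolerance = 4)
  expect_false(cell$border)

  expect_identical(extract_cells(matrix(0L, 5, 5), matrix(0, 5, 5)), list())

  two <- matrix(0L, 20, 20)
  two[1:4, 2:12] <- 1L              # touches the image border
  two[12:15, 5:15] <- 2L
  cells2 <- extract_cells(two, matrix(1, 20, 20))
  expect_length(cells2, 2)
  k1 <- paste(cells2[[1]]$pixels[, 1], cells2[[1]]$pixels[, 2])
  k2 <- paste(cells2[[2]]$pixels[, 1], cells2[[2]]$pixels[, 2])
  expect_length(intersect(k1, k2), 0)
  expect_true(cells2[[1]]$border)
  expect_false(cells2[[2]]$border)
})

test_that("pole regions span the requested fraction and partition at 0.5", {
  fix <- make_test_cell()
  cell <- fix$cell
  reg <- identify_pole_regions(cell, 0.2)
  # 30-px axis: 20% of length 29 = 5.8 -> 6 columns per region
  expect_equal(sort(unique(reg$a[, 2])), 8:13)
  expect_equal(sort(unique(reg$b[, 2])), 32:37)
  expect_equal(nrow(reg$a), nrow(reg$b))   # symmetric cell
  # regions disjoint
  expect_length(intersect(paste(reg$a[, 1], reg$a[, 2]),
                          paste(reg$b[, 1], reg$b[, 2])), 0)
  # fraction 0.5 partitions the cell
  reg5 <- identify_pole_regions(cell, 0.5)
  expect_equal(nrow(reg5$a) + nrow(reg5$b), nrow(cell$pixels))
})

test_that("cluster acceptance follows the mean and size rules", {
  # cytoplasm mean 100, SD 10 -> threshold 120
  fix <- paint_cluster(make_test_cell(100, 10), intensity = 130, size = 5)
  cl <- detect_polar_clusters(fix$cell, fix$fluor, mode = "snapshot")
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size_px, 5)
  expect_equal(cl[[1]]$mean_intensity, 130)
  expect_equal(attr(cl, "mu_cyto"), 100, tolerance = 1e-9)
  expect_equal(attr(cl, "sd_cyto"), 10, tolerance = 1e-9)

  # same intensity, 2 px: rejected on size
  fix2 <- paint_cluster(make_test_cell(100, 10), intensity = 130, size = 2)
  expect_length(detect_polar_clusters(fix2$cell, fix2$fluor), 0)

  # sub-threshold candidate: rejected on intensity
  fix3 <- paint_cluster(make_test_cell(100, 10), intensity = 115, size = 5)
  expect_length(detect_polar_clusters(fix3$cell, fix3$fluor), 0)
})

test_that("time-lapse mode adds the two-fold cytoplasm rule", {
  # cytoplasm mean 100, SD 5: candidate at 150 passes 2-SD rule but not 2x
  fix <- paint_cluster(make_test_cell(100, 5), intensity = 150, size = 5)
  expect_length(detect_polar_clusters(fix$cell, fix$fluor, mode = "snapshot"), 1)
  expect_length(detect_polar_clusters(fix$cell, fix$fluor, mode = "timelapse"), 0)
  # at 250 (> 2 x 100) both modes accept
  fix2 <- paint_cluster(make_test_cell(100, 5), intensity = 250, size = 5)
  expect_length(detect_polar_clusters(fix2$cell, fix2$fluor, mode = "timelapse"), 1)
})

test_that("asymmetry index and fractions follow the defining formula", {
  fix <- paint_cluster(paint_cluster(make_test_cell(100, 10),
                                     intensity = 300, size = 6, pole = "a"),
                       intensity = 180, size = 5, pole = "b")
  cl <- detect_polar_clusters(fix$cell, fix$fluor)
  rec <- compute_localization(fix$cell, cl, fix$fluor)
  F1 <- 300 * 6; F2 <- 180 * 5
  expect_equal(rec$omega, (F1 - F2) / (F1 + F2))
  total <- sum(fix$fluor[fix$cell$pixels])
  expect_equal(rec$f_pole1, F1 / total)
  expect_equal(rec$f_pole2, F2 / total)
  expect_equal(rec$f_pole1 + rec$f_pole2 + rec$f_cyto, 1, tolerance = 1e-9)
  expect_gte(rec$f_pole1, rec$f_pole2)

  # single cluster: omega = 1
  fix1 <- paint_cluster(make_test_cell(100, 10), intensity = 300, size = 6)
  rec1 <- compute_localization(fix1$cell,
                               detect_polar_clusters(fix1$cell, fix1$fluor),
                               fix1$fluor)
  expect_equal(rec1$omega, 1)
  expect_equal(rec1$f_pole2, 0)

  # no clusters: diffuse, omega undefined
  fix0 <- make_test_cell(100, 10)
  rec0 <- compute_localization(fix0$cell,
                               detect_polar_clusters(fix0$cell, fix0$fluor),
                               fix0$fluor)
  expect_true(is.na(rec0$omega))
  expect_equal(rec0$pattern, "diffuse")
  expect_equal(rec0$f_cyto, 1)
})

test_that("pattern binning partitions the asymmetry range", {
  expect_equal(classify_pattern(c(0.95, 0.5, 0.1, NA)),
               c("unipolar", "bipolar_asymmetric", "bipolar_symmetric",
                 "diffuse"))
  # boundaries go to the less extreme class
  expect_equal(classify_pattern(c(0.9, 0.2)),
               c("bipolar_asymmetric", "bipolar_symmetric"))
  # totality over random values
  om <- seq(0, 1, by = 0.01)
  expect_true(all(classify_pattern(om) %in%
                    c("unipolar", "bipolar_asymmetric", "bipolar_symmetric")))
})

test_that("population summary reports percentages and cytoplasmic mean", {
  df <- data.frame(cell_id = 1:10, f_pole1 = 0.3, f_pole2 = 0.1, f_cyto = 0.6,
                   omega = 0.5, n_clusters = 2,
                   pattern = "bipolar_asymmetric", border = FALSE)
  df$pattern[1:3] <- "diffuse"; df$n_clusters[1:3] <- 0
  df$f_pole1[1:3] <- 0; df$f_pole2[1:3] <- 0; df$f_cyto[1:3] <- 1
  s <- summarize_population(df)
  expect_equal(sum(s$percent), 100, tolerance = 1e-6)
  expect_equal(unname(s$percent["diffuse"]), 30)
  expect_equal(s$mean_percent_cyto, 60)
  expect_equal(nrow(s$scatter), 7)
  expect_error(summarize_population(df[0, ]), "at least one")
})

test_that("cluster calls are invariant to affine intensity transforms", {
  spec <- snapshot_population_spec(30, c(unipolar = 0.4,
                                         bipolar_asymmetric = 0.3,
                                         bipolar_symmetric = 0.15,
                                         diffuse = 0.15),
                                   noise_sd = 4, seed = 21)
  sc <- gen_snapshot_scene(spec)
  base <- quantify_snapshot(sc$label_image, sc$fluorescence_image)$records
  shifted <- quantify_snapshot(sc$label_image,
                               2.5 * sc$fluorescence_image + 40)$records
  expect_equal(base$pattern, shifted$pattern)
  expect_equal(base$n_clusters, shifted$n_clusters)
})

test_that("classifier recovers ground truth noise-free and degrades with noise", {
  mix <- c(unipolar = 0.35, bipolar_asymmetric = 0.35,
           bipolar_symmetric = 0.15, diffuse = 0.15)
  agree <- vapply(c(0, 10, 60), function(ns) {
    spec <- snapshot_population_spec(60, mix, noise_sd = ns,
                                     cytoplasm_sd = 6, seed = 31)
    sc <- gen_snapshot_scene(spec)
    res <- quantify_snapshot(sc$label_image, sc$fluorescence_image)
    mean(res$records$pattern == sc$truth$class[res$records$cell_id])
  }, numeric(1))
  expect_equal(agree[1], 1)                 # noise-free: perfect recovery
  expect_true(all(diff(agree) <= 0))        # non-increasing with noise
  expect_lt(agree[3], 1)                    # heavy noise does hurt
})

test_that("asymmetry index is bounded and every cell gets exactly one class", {
  spec <- snapshot_population_spec(40, c(unipolar = 0.25,
                                         bipolar_asymmetric = 0.25,
                                         bipolar_symmetric = 0.25,
                                         diffuse = 0.25),
                                   noise_sd = 6, seed = 77)
  sc <- gen_snapshot_scene(spec)
  rec <- quantify_snapshot(sc$label_image, sc$fluorescence_image)$records
  defined <- !is.na(rec$omega)
  expect_true(all(rec$omega[defined] >= 0 & rec$omega[defined] <= 1))
  expect_true(all(rec$pattern %in% c("unipolar", "bipolar_asymmetric",
                                     "bipolar_symmetric", "diffuse")))
  expect_true(all(!defined == (rec$pattern == "diffuse")))
  expect_equal(rec$f_pole1 + rec$f_pole2 + rec$f_cyto, rep(1, nrow(rec)),
               tolerance = 1e-9)
})
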