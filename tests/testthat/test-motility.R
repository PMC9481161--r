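# Tracking, reversal detection, speeds, pole roles, dynamic asymmetry and
# the Welch test.

test_that("speeds are per-interval centroid displacements", {
  tr <- make_line_track(rep(3, 9))
  expect_equal(compute_speeds(tr), rep(3, 9))
  expect_equal(compute_speeds(make_line_track(rep(0, 5))), rep(0, 5))
  # unit conversion
  expect_equal(compute_speeds(tr, unit_scale = 0.06), rep(0.18, 9))
})

test_that("reversal detector finds gated sign changes and nothing else", {
  # 5 intervals +8 then 5 intervals -8: one event, at the first frame moving
  # in the new direction
  tr <- make_line_track(c(rep(8, 5), rep(-8, 5)))
  expect_equal(detect_reversals(tr), 7L)
  # monotone track: no events
  expect_length(detect_reversals(make_line_track(rep(8, 10))), 0)
  # jitter below the gate is absorbed
  trj <- make_line_track(c(rep(8, 5), -2, rep(8, 5)))
  expect_length(detect_reversals(trj), 0)
  # but a genuine run above the gate is kept even with jitter around it
  trg <- make_line_track(c(rep(8, 4), -1, rep(-8, 4), 1, rep(8, 4)))
  expect_length(detect_reversals(trg), 2)
})

test_that("reversal count is invariant to time reversal of the track", {
  disp <- c(rep(8, 4), rep(-8, 3), rep(8, 5), rep(-8, 4))
  a <- length(detect_reversals(make_line_track(disp)))
  b <- length(detect_reversals(make_line_track(rev(-disp))))
  expect_equal(a, 3)
  expect_equal(a, b)
})

test_that("reversal frequency uses the first full window and logs short tracks", {
  tr <- make_line_track(c(rep(8, 10), rep(-8, 10)), frame_interval_s = 30)
  expect_equal(reversal_frequency(tr, window_s = 600), 1L)
  expect_warning(out <- reversal_frequency(tr, window_s = 1200), "shorter")
  expect_true(is.na(out))
  # events after the window are not counted
  tr2 <- make_line_track(c(rep(8, 21), rep(-8, 9)), frame_interval_s = 30)
  expect_equal(reversal_frequency(tr2, window_s = 600), 0L)
})

test_that("fraction_moving splits tracks at the median-speed threshold", {
  fast <- replicate(5, make_line_track(rep(8, 10)), simplify = FALSE)
  slow <- replicate(5, make_line_track(rep(0.1, 10)), simplify = FALSE)
  expect_equal(fraction_moving(slow), 0)
  expect_equal(fraction_moving(fast), 1)
  expect_equal(fraction_moving(c(fast, slow)), 0.5)
})

test_that("leading pole follows the direction of motion and swaps at reversals", {
  tr <- make_line_track(c(rep(8, 5), rep(-8, 5)))
  lead <- assign_leading_lagging(tr)
  # moving toward +x = toward pole b first, then toward a; event at frame 7
  expect_equal(lead[1:6], rep("b", 6))
  expect_equal(lead[7:11], rep("a", 5))
  # number of role swaps equals number of detected reversals
  swaps <- sum(lead[-1] != lead[-length(lead)])
  expect_equal(swaps, length(detect_reversals(tr)))
  # stationary track: roles undefined
  expect_true(all(is.na(assign_leading_lagging(make_line_track(rep(0, 6))))))
})

test_that("dynamic asymmetry has the lagging-pole sign convention", {
  # lagging-pole protein moving toward pole b: F at pole a only -> -1
  tr <- make_line_track(rep(8, 7), F_a = 100, F_b = 0)
  om <- dynamic_omega(tr)
  expect_true(all(om$omega_dyn[om$included] == -1))
  # symmetric fluorescence -> 0
  om0 <- dynamic_omega(make_line_track(rep(8, 7), F_a = 50, F_b = 50))
  expect_true(all(om0$omega_dyn[om0$included] == 0))
  # leading-pole protein -> +1
  omp <- dynamic_omega(make_line_track(rep(8, 7), F_a = 0, F_b = 100))
  expect_true(all(omp$omega_dyn[omp$included] == 1))
  # inverting motion maps omega to -omega on included frames
  rev_tr <- make_line_track(rep(-8, 7), F_a = 100, F_b = 0)
  expect_equal(dynamic_omega(rev_tr)$omega_dyn,
               -dynamic_omega(tr)$omega_dyn)
})

test_that("dynamic asymmetry frame-inclusion rules are enforced", {
  # one reversal at frame 7 of 11: exclude frames 6 (last before) and 7
  # (first after); both runs are long enough to keep the rest
  tr <- make_line_track(c(rep(8, 5), rep(-8, 5)), F_a = 100, F_b = 10)
  om <- dynamic_omega(tr)
  expect_false(om$included[6])
  expect_false(om$included[7])
  expect_true(all(om$included[c(1:5, 8:11)]))
  # a 2-frame run is excluded entirely
  tr2 <- make_line_track(c(rep(8, 4), rep(-8, 1), rep(8, 4)),
                         F_a = 100, F_b = 10, cell_width_px = 5)
  om2 <- dynamic_omega(tr2)
  run2 <- 6:6   # frames strictly inside the 2-frame middle run
  expect_true(all(!om2$included[5:7]))
  # zero total polar fluorescence excludes the frame
  tr3 <- make_line_track(rep(8, 7), F_a = c(100, 0, rep(100, 5)), F_b = 0)
  expect_false(dynamic_omega(tr3)$included[2])
})

test_that("track linking recovers synthetic trajectories and reversals", {
  spec <- track_spec(n_cells = 5, duration_s = 600, frame_interval_s = 30,
                     reversal_rate = 0.25, seed = 17)
  sc <- gen_timelapse(spec)
  obs <- lapply(seq_along(sc$fluorescence), function(i) {
    observe_frame(sc$labels[[i]], sc$fluorescence[[i]])
  })
  tracks <- link_tracks(obs, spec$frame_interval_s)
  n_frames <- length(sc$fluorescence)
  # every cell yields one unbroken track: >= 99% of links correct
  expect_equal(length(tracks), 5)
  expect_true(all(vapply(tracks, function(t) nrow(t$frames), integer(1)) ==
                    n_frames))
  # detected reversals match ground truth exactly on tracks whose true
  # events are interior and separated by enough frames for the gate to
  # resolve them; no false positives anywhere
  for (tr in tracks) {
    lane <- unique(sc$tracks$cell_id[abs(sc$tracks$cy - tr$frames$cy[1]) < 2])
    true_ev <- sort(sc$reversals$frame[sc$reversals$cell_id %in% lane])
    detected <- detect_reversals(tr)
    resolvable <- length(true_ev) == 0 ||
      (all(diff(true_ev) >= 3) && all(true_ev >= 4) &&
         all(true_ev <= n_frames - 2))
    if (resolvable) expect_setequal(detected, true_ev)
    expect_true(all(detected %in% true_ev))
  }
  # centroids track the ground truth to sub-pixel accuracy
  tr1 <- tracks[[1]]
  lane1 <- unique(sc$tracks$cell_id[abs(sc$tracks$cy - tr1$frames$cy[1]) < 2])
  truth1 <- sc$tracks[sc$tracks$cell_id == lane1, ]
  expect_lt(max(abs(tr1$frames$cx - truth1$cx)), 1)
})

test_that("Welch test matches the independent reference to 1e-10", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  ours <- welch_t_test(a, b)
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  # random unequal-variance cases
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), 0, 1)
    y <- rnorm(sample(3:30, 1), 0.5, 3)
    ours <- welch_t_test(x, y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # swapping the samples flips t, leaves p unchanged
  sw <- welch_t_test(b, a)
  expect_equal(sw$statistic, -welch_t_test(a, b)$statistic)
  expect_equal(sw$p_value, welch_t_test(a, b)$p_value)
  same <- welch_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("generator speeds are recovered by the tracking statistics", {
  spec <- track_spec(n_cells = 20, duration_s = 600, reversal_rate = 0,
                     speed_mean = 8, speed_sd = 1, seed = 23)
  sc <- gen_timelapse(spec)
  tracks <- tracks_from_truth(sc)
  speeds <- unlist(lapply(tracks, compute_speeds))
  se <- 1 / sqrt(length(speeds))
  # rendering quantizes positions to whole pixels; allow 3 SE + 0.5 px
  expect_lt(abs(mean(speeds) - 8), 3 * se + 0.5)
})
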