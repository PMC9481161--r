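# GTPase assay kinetics: linear-rate fitting of NADH-coupled A340 traces,
# malachite-green standard curves and endpoints, specific-activity
# conversion, fold stimulation and saturation (titration) analysis.
#
# Units: enzyme concentrations in uM, extinction coefficient in M^-1 cm^-1,
# path length in cm, rates in GTP hydrolyzed per enzyme molecule per hour.

#' Assay context for specific-activity conversion
#'
#' @param enzyme_conc GTPase concentration in uM (assay standard: 3 uM).
#' @param epsilon_340 NADH molar extinction at 340 nm (M^-1 cm^-1).
#' @param path_length effective optical path in cm (plate-reader wells are
#'   volume-dependent; default 0.5).
#' @param background_condition label of the matched no-GTPase control.
#' @return object of class `assay_context`.
#' @export
assay_context <- function(enzyme_conc = 3, epsilon_340 = 6220,
                          path_length = 0.5,
                          background_condition = "no_enzyme") {
  assert_that(is_num1(enzyme_conc) && enzyme_conc > 0 &&
                is_num1(epsilon_340) && epsilon_340 > 0 &&
                is_num1(path_length) && path_length > 0,
              "assay context parameters must be positive")
  structure(list(enzyme_conc = enzyme_conc, epsilon_340 = epsilon_340,
                 path_length = path_length,
                 background_condition = background_condition),
            class = "assay_context")
}

#' Linear rate of an absorbance trace
#'
#' Ordinary least-squares slope of A340 against time over the fitting window
#' (default: the full trace). If the trace saturates (A340 reaches 0.05,
#' i.e. NADH exhausted), the window is truncated just before saturation.
#'
#' @param trace data frame with columns `time_s` and `a340` (an
#'   `absorbance trace`), times strictly increasing.
#' @param window optional `c(t0, t1)` in seconds.
#' @return list with `slope` (absorbance/s), `slope_se`, `n_points`,
#'   `truncated` flag.
#' @export
fit_linear_rate <- function(trace, window = NULL) {
  assert_that(all(c("time_s", "a340") %in% names(trace)),
              "trace needs columns time_s and a340")
  assert_that(all(diff(trace$time_s) > 0), "times must be strictly increasing")
  keep <- rep(TRUE, nrow(trace))
  if (!is.null(window)) {
    keep <- trace$time_s >= window[1L] & trace$time_s <= window[2L]
  }
  df <- trace[keep, ]
  truncated <- FALSE
  sat <- which(df$a340 <= 0.05)
  if (length(sat) > 0L) {
    df <- df[seq_len(min(sat) - 1L), ]
    truncated <- TRUE
  }
  assert_that(nrow(df) >= 3L, "need at least 3 points in the fitting window")
  fit <- stats::lm(a340 ~ time_s, data = df)
  # SE computed directly (summary.lm warns on exact synthetic fits)
  ssx <- sum((df$time_s - mean(df$time_s))^2)
  s2 <- sum(stats::residuals(fit)^2) / (nrow(df) - 2)
  list(slope = unname(stats::coef(fit)["time_s"]),
       slope_se = sqrt(s2 / ssx),
       n_points = nrow(df), truncated = truncated)
}

#' Convert coupled-assay slopes to specific GTPase activity
#'
#' One NADH is oxidized per GTP hydrolyzed, so the background-subtracted
#' A340 slope converts to a hydrolysis rate as
#' `rate = |slope - background_slope| / (epsilon * l) * 3600 / [E]`,
#' in GTP per enzyme per hour. With several replicate slopes the estimate is
#' their mean with its standard error. A background steeper than the sample
#' clamps the rate at 0 and flags the estimate.
#'
#' @param slope numeric vector of replicate slopes (absorbance/s; negative
#'   for NADH consumption).
#' @param context an [assay_context()].
#' @param background_slope slope of the matched control (same units);
#'   default 0.
#' @return object of class `turnover_estimate`: `rate` (GTP/enzyme/hr), `se`,
#'   `n_replicates`, `clamped` flag.
#' @export
trace_to_turnover <- function(slope, context, background_slope = 0) {
  stopifnot(inherits(context, "assay_context"))
  net <- abs(slope) - abs(background_slope)
  clamped <- any(net < 0)
  net <- pmax(net, 0)
  rates <- net / (context$epsilon_340 * context$path_length) * 3600 /
    (context$enzyme_conc * 1e-6)
  structure(list(rate = mean(rates),
                 se = if (length(rates) > 1L)
                   stats::sd(rates) / sqrt(length(rates)) else NA_real_,
                 n_replicates = length(rates), clamped = clamped),
            class = "turnover_estimate")
}

#' @export
print.turnover_estimate <- function(x, ...) {
  cat(sprintf("specific GTPase activity: %.3g GTP/enzyme/hr", x$rate))
  if (!is.na(x$se)) cat(sprintf(" +/- %.3g (SE, n = %d)", x$se, x$n_replicates))
  if (x$clamped) cat(" [clamped at 0: background exceeded sample]")
  cat("\n")
  invisible(x)
}

#' Fit a malachite-green phosphate standard curve
#'
#' Ordinary least squares of A590 against phosphate concentration.
#'
#' @param standards data frame with columns `pi_uM` and `a590`, at least 3
#'   standards including the 0 blank.
#' @return object of class `standard_curve`: `slope` (absorbance/uM),
#'   `intercept`, `r_squared`, `max_standard` (top concentration).
#' @export
malachite_standard_fit <- function(standards) {
  assert_that(all(c("pi_uM", "a590") %in% names(standards)),
              "standards need columns pi_uM and a590")
  assert_that(nrow(standards) >= 3L, "need at least 3 standards")
  assert_that(any(standards$pi_uM == 0), "standards must include a 0 blank")
  fit <- stats::lm(a590 ~ pi_uM, data = standards)
  slope <- unname(stats::coef(fit)["pi_uM"])
  assert_that(slope > 0, "non-positive standard-curve slope")
  sst <- sum((standards$a590 - mean(standards$a590))^2)
  sse <- sum(stats::residuals(fit)^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = if (sst > 0) 1 - sse / sst else 1,
                 max_standard = max(standards$pi_uM)),
            class = "standard_curve")
}

#' Convert a malachite endpoint to specific GTPase activity
#'
#' Released phosphate is read off the standard curve,
#' `[Pi] = (A590 - intercept) / slope` (uM), and converted to
#' `rate = [Pi] / [E] / incubation_h` in GTP per enzyme per hour.
#'
#' @param a590 numeric vector of replicate endpoint absorbances.
#' @param curve a [malachite_standard_fit()] result.
#' @param context an [assay_context()].
#' @param incubation_h incubation time in hours (assay standard: 1 h).
#' @return a `turnover_estimate`; `extrapolated` is TRUE when any A590 lies
#'   above the top standard.
#' @export
endpoint_to_turnover <- function(a590, curve, context, incubation_h = 1) {
  stopifnot(inherits(curve, "standard_curve"), inherits(context, "assay_context"))
  pi_uM <- (a590 - curve$intercept) / curve$slope
  extrapolated <- any(pi_uM > curve$max_standard)
  rates <- pi_uM / context$enzyme_conc / incubation_h
  out <- structure(list(rate = mean(rates),
                        se = if (length(rates) > 1L)
                          stats::sd(rates) / sqrt(length(rates)) else NA_real_,
                        n_replicates = length(rates), clamped = FALSE),
                   class = "turnover_estimate")
  out$extrapolated <- extrapolated
  out
}

#' Fold stimulation between two activities
#'
#' @param rate_condition,rate_reference rates (or `turnover_estimate`s); the
#'   reference must be positive.
#' @return ratio condition / reference.
#' @export
fold_stimulation <- function(rate_condition, rate_reference) {
  r1 <- if (inherits(rate_condition, "turnover_estimate"))
    rate_condition$rate else rate_condition
  r0 <- if (inherits(rate_reference, "turnover_estimate"))
    rate_reference$rate else rate_reference
  assert_that(is_num1(r0) && r0 > 0, "reference rate must be > 0")
  r1 / r0
}

#' Hyperbolic titration analysis
#'
#' Fits `activity(x) = A0 + Amax * x / (K + x)` to a titration series by
#' nonlinear least squares and reports the saturation concentration: the
#' smallest tested concentration whose fitted activity reaches 95% of the
#' fitted plateau `A0 + Amax` (reported as `NA` with `saturated = FALSE`
#' when no tested concentration reaches it, e.g. `K` far above the highest
#' concentration).
#'
#' @param concentration titrant concentrations (uM), non-negative and
#'   strictly increasing, at least 4 values.
#' @param activity activities (e.g. percent of the reference condition).
#' @return object of class `titration_fit`: `A0`, `Amax`, `K` (uM),
#'   `saturation_conc`, `saturated`, `fitted` (per-concentration values).
#' @export
titration_analysis <- function(concentration, activity) {
  assert_that(length(concentration) >= 4L &&
                length(concentration) == length(activity),
              "need >= 4 matched concentrations and activities")
  assert_that(all(concentration >= 0) && all(diff(concentration) > 0),
              "concentrations must be non-negative and strictly increasing")
  if (stats::cor(concentration, activity) < 0) {
    stop_pq("activity decreases with concentration; hyperbolic saturation model does not apply")
  }
  a0_start <- min(activity)
  amax_start <- max(activity) - a0_start
  if (amax_start <= 0) amax_start <- max(abs(activity)) + 1
  half <- a0_start + amax_start / 2
  k_start <- concentration[which.min(abs(activity - half))]
  if (k_start <= 0) k_start <- max(concentration) / 10
  df <- data.frame(x = concentration, y = activity)
  fit <- minpack.lm::nlsLM(y ~ A0 + Amax * x / (K + x), data = df,
                           start = list(A0 = a0_start, Amax = amax_start,
                                        K = k_start),
                           lower = c(-Inf, 0, 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  fitted_vals <- p["A0"] + p["Amax"] * concentration / (p["K"] + concentration)
  plateau <- p["A0"] + p["Amax"]
  reached <- fitted_vals >= 0.95 * plateau
  structure(list(A0 = unname(p["A0"]), Amax = unname(p["Amax"]),
                 K = unname(p["K"]),
                 saturation_conc = if (any(reached))
                   concentration[which(reached)[1L]] else NA_real_,
                 saturated = any(reached),
                 fitted = unname(fitted_vals)),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("hyperbolic fit: A0 = %.3g, Amax = %.3g, K = %.3g uM\n",
              x$A0, x$Amax, x$K))
  if (x$saturated) {
    cat(sprintf("saturation (>= 95%% of plateau) reached at %.3g uM\n",
                x$saturation_conc))
  } else {
    cat("saturation not reached within the tested range\n")
  }
  invisible(x)
}

#' Generate a synthetic coupled-assay absorbance trace
#'
#' Pure function of its spec:
#' `A340(t) = a340_start - r * [E] * eps * l * t / 3600 - background_rate * t + noise`,
#' where `r` is the true turnover (GTP per enzyme per hour) and NADH
#' consumption equals GTP hydrolysis 1:1 (regenerating system in excess).
#'
#' @param spec a [coupled_assay_spec()].
#' @return data frame of class `absorbance_trace` with columns `time_s`,
#'   `a340`; the spec is attached as attribute `spec`.
#' @export
gen_coupled_trace <- function(spec) {
  stopifnot(inherits(spec, "coupled_assay_spec"))
  set.seed(spec$seed)
  t <- seq(0, spec$duration_s, by = spec$sample_interval_s)
  nadh_rate <- spec$true_turnover * spec$enzyme_conc * 1e-6 / 3600  # M/s
  a <- spec$a340_start -
    nadh_rate * spec$epsilon_340 * spec$path_length * t -
    spec$background_rate * t
  if (spec$noise_sd > 0) a <- a + stats::rnorm(length(t), 0, spec$noise_sd)
  structure(data.frame(time_s = t, a340 = a),
            class = c("absorbance_trace", "data.frame"), spec = spec)
}

#' Generate a synthetic malachite-green plate
#'
#' Linear colorimetric response with Gaussian noise for standards and
#' samples.
#'
#' @param spec a [malachite_plate_spec()].
#' @return list with `standards` (well, pi_uM, a590), `samples`
#'   (well, a590, pi_uM_true) and the `spec`.
#' @export
gen_malachite_plate <- function(spec) {
  stopifnot(inherits(spec, "malachite_plate_spec"))
  set.seed(spec$seed)
  ns <- length(spec$standard_concs)
  std_a <- spec$true_intercept + spec$true_slope * spec$standard_concs
  if (spec$noise_sd > 0) std_a <- std_a + stats::rnorm(ns, 0, spec$noise_sd)
  standards <- data.frame(well = sprintf("S%02d", seq_len(ns)),
                          pi_uM = spec$standard_concs, a590 = std_a)
  nsmp <- length(spec$sample_true_pi)
  samples <- data.frame(well = character(0), a590 = numeric(0),
                        pi_uM_true = numeric(0))
  if (nsmp > 0L) {
    smp_a <- spec$true_intercept + spec$true_slope * spec$sample_true_pi
    if (spec$noise_sd > 0) smp_a <- smp_a + stats::rnorm(nsmp, 0, spec$noise_sd)
    samples <- data.frame(well = sprintf("X%02d", seq_len(nsmp)),
                          a590 = smp_a, pi_uM_true = spec$sample_true_pi)
  }
  list(standards = standards, samples = samples, spec = spec)
}
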