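#' Locate perturbation events and their analysis windows
#'
#' For every perturbation pulse, determines the unperturbed pre-pulse
#' window (used for variance and autocorrelation) and the post-pulse
#' window (used for the exponential recovery fit), dropping events whose
#' windows would cross the spiking onset, the bifurcation crossing, or a
#' neighbouring pulse.
#'
#' For model-unit trajectories the defaults are 5000 pre-pulse samples and
#' 5000 (saddle-node) or 500 (Hopf) post-pulse samples, the post window
#' starting at the pulse sample itself.  For emulated recordings the
#' pre-window is the 1 s of subthreshold voltage ending at pulse onset and
#' the post-window is 4800 samples (192 ms at 25 kHz) starting at pulse
#' offset, and only pulses strictly before the detected onset yield events.
#'
#' @param x a `csd_trajectory` or `csd_recording`.
#' @param ... passed to methods.
#' @return A data.frame of class `csd_events` with columns `pulse_time`,
#'   `pulse_idx`, `pre_start`, `pre_end`, `post_start`, `post_end`
#'   (1-based sample indices, windows inclusive).  The number of dropped
#'   events is attached as attribute `n_dropped`.
#' @export
locate_perturbations <- function(x, ...) UseMethod("locate_perturbations")

#' @rdname locate_perturbations
#' @param pre_samples,post_samples window lengths in samples (trajectories).
#' @export
locate_perturbations.csd_trajectory <- function(x, pre_samples = 5000,
                                                post_samples = NULL, ...) {
  sn <- x$config$bifurcation_kind == "saddle_node"
  if (is.null(post_samples)) post_samples <- if (sn) 5000 else 500
  n_eff <- length(x$V)
  # analysis stops at the deterministic crossing even if the path survived
  before_tc <- x$times < x$t_c
  if (any(!before_tc)) n_eff <- min(n_eff, which(!before_tc)[1] - 1L)

  p <- x$pulse_idx
  if (length(p) == 0L)
    csd_error("empty_series", "trajectory contains no perturbation pulses")
  pre_start <- p - pre_samples
  post_end <- p + post_samples - 1L
  prev_post_end <- c(-Inf, post_end[-length(p)])
  next_p <- c(p[-1], Inf)
  ok <- pre_start >= 1L & pre_start > prev_post_end &
    post_end <= n_eff & post_end < next_p
  ev <- data.frame(pulse_time = x$pulse_times[ok], pulse_idx = p[ok],
                   pre_start = pre_start[ok], pre_end = p[ok] - 1L,
                   post_start = p[ok], post_end = post_end[ok])
  if (nrow(ev) == 0L)
    csd_error("empty_series", "no perturbation event has complete analysis windows")
  structure(ev, class = c("csd_events", "data.frame"),
            n_dropped = sum(!ok))
}

#' @rdname locate_perturbations
#' @param pre_seconds pre-window duration in seconds (recordings).
#' @param post_samples_rec post-window length in samples (recordings).
#' @export
locate_perturbations.csd_recording <- function(x, pre_seconds = 1,
                                               post_samples_rec = 4800, ...) {
  fs <- x$v_hz
  proto <- x$provenance$protocol
  width <- if (!is.null(proto)) proto$pulse_width_ms / 1000 else 0.005
  n <- length(x$voltage)
  onset_idx <- if (is.na(x$onset_time)) Inf else round(x$onset_time * fs) + 1L

  p <- round(x$pulse_times * fs) + 1L
  keep <- x$pulse_times < ifelse(is.na(x$onset_time), Inf, x$onset_time)
  if (!any(keep))
    csd_error("empty_series", "no perturbation pulse precedes the onset")
  p <- p[keep]
  pt <- x$pulse_times[keep]

  pre_n <- round(pre_seconds * fs)
  post_start <- p + round(width * fs)
  post_end <- post_start + post_samples_rec - 1L
  pre_start <- p - pre_n
  prev_post_end <- c(-Inf, post_end[-length(p)])
  next_p <- c(p[-1], Inf)
  ok <- pre_start >= 1L & pre_start > prev_post_end &
    post_end <= n & post_end < next_p & post_end < onset_idx
  ev <- data.frame(pulse_time = pt[ok], pulse_idx = p[ok],
                   pre_start = pre_start[ok], pre_end = p[ok] - 1L,
                   post_start = post_start[ok], post_end = post_end[ok])
  if (nrow(ev) == 0L)
    csd_error("empty_series", "no perturbation event has complete analysis windows")
  structure(ev, class = c("csd_events", "data.frame"),
            n_dropped = sum(!ok) + sum(!keep))
}

#' Fit an exponential decay to a post-perturbation voltage segment
#'
#' Fits \eqn{V(t) = a e^{-\lambda t} + b} by nonlinear least squares, with
#' \eqn{t = 0} at the segment start.  The segment mean is subtracted before
#' fitting.  Start values are scale-free: `b` from the mean of the last
#' tenth of the window, `a` from the first sample, `lambda` from a fifth of
#' the window length; `lambda` is constrained to `(0, sampling_rate / 2)`.
#'
#' @param segment numeric vector of voltage samples.
#' @param sampling_rate samples per unit time; `lambda` is returned in
#'   inverse units of the implied time axis.
#' @return A list of class `recovery_fit` with elements `a`, `lambda`, `b`,
#'   `r_squared` and `converged`.  Non-convergence is reported through
#'   `converged = FALSE` (with `lambda = NA`), not as an error.
#' @export
fit_recovery <- function(segment, sampling_rate) {
  if (length(segment) < 20L)
    csd_error("insufficient_data", "recovery fit needs at least 20 samples")
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  seg <- segment - mean(segment)
  if (all(abs(seg) < .Machine$double.eps * 100))
    csd_error("degenerate_fit", "segment is constant; no decay to fit")
  n <- length(seg)
  tt <- (seq_len(n) - 1) / sampling_rate
  b0 <- mean(seg[(n - max(1L, n %/% 10L) + 1L):n])
  a0 <- seg[1] - b0
  if (a0 == 0) a0 <- .Machine$double.eps
  l0 <- 5 / (n / sampling_rate)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      seg ~ a * exp(-lambda * tt) + b,
      start = list(a = a0, lambda = l0, b = b0),
      lower = c(-Inf, 1e-12, -Inf),
      upper = c(Inf, sampling_rate / 2, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(a = NA_real_, lambda = NA_real_, b = NA_real_,
                r_squared = NA_real_, converged = FALSE)
  } else {
    co <- stats::coef(fit)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((seg - mean(seg))^2)
    out <- list(a = unname(co["a"]), lambda = unname(co["lambda"]),
                b = unname(co["b"]),
                r_squared = 1 - ss_res / ss_tot,
                converged = isTRUE(fit$convInfo$isConv))
    if (!out$converged) out$lambda <- NA_real_
  }
  structure(out, class = "recovery_fit")
}

#' Population variance of a voltage segment
#'
#' Sample variance with the population convention (divide by N), matching
#' the normalization used inside the autocorrelation estimator.
#'
#' @param segment numeric vector, length >= 2.
#' @return The variance.
#' @export
segment_variance <- function(segment) {
  if (length(segment) < 2L)
    csd_error("insufficient_data", "variance needs at least 2 samples")
  mean((segment - mean(segment))^2)
}

#' Lag-1-normalized autocorrelation of a voltage segment
#'
#' Computes the raw autocorrelation
#' \deqn{ACF^*(s) = \sum_{t=1}^{N-s} (F(t)-\mu)(F(t+s)-\mu) / v}
#' (with \eqn{\mu} the mean and \eqn{v} the population variance) and
#' returns it normalized by its value at lag 1:
#' \eqn{ACF(s) = ACF^*(s)/ACF^*(1)}, so that \eqn{ACF(1) = 1} by
#' construction.  On white-noise-dominated segments \eqn{ACF^*(1)} can sit
#' near zero, making this normalization unstable; such segments are
#' rejected rather than silently amplified.
#'
#' @param segment numeric vector of length \eqn{N \ge 2\,\mathrm{lag}}.
#' @param lag lag in samples, `1 <= lag <= N/2`.
#' @return The normalized autocorrelation value at `lag`.
#' @export
autocorrelation <- function(segment, lag) {
  n <- length(segment)
  lag <- as.integer(lag)
  if (lag < 1L || lag > n / 2 || n < 2L * lag)
    csd_error("config", "need 1 <= lag <= N/2")
  mu <- mean(segment)
  v <- mean((segment - mu)^2)
  if (v == 0)
    csd_error("undefined_acf", "segment has zero variance; ACF undefined")
  f <- segment - mu
  acf_star <- function(s) sum(f[1:(n - s)] * f[(1 + s):n]) / v
  a1 <- acf_star(1L)
  if (abs(a1) < 1e-12 * n)
    csd_error("unstable_normalization",
              "lag-1 autocorrelation is too close to zero to normalize by")
  acf_star(lag) / a1
}

#' Detect spiking onset in a recording
#'
#' @param recording a `csd_recording`.
#' @param threshold_mV detection level; defaults to the protocol's
#'   `spike_threshold_mV` (0 mV).
#' @return Time (s) of the first upward crossing of the threshold, or `NA`
#'   if the voltage never crosses it.
#' @export
detect_onset <- function(recording, threshold_mV = NULL) {
  v <- recording$voltage
  if (is.null(threshold_mV)) {
    proto <- recording$provenance$protocol
    threshold_mV <- if (!is.null(proto)) proto$spike_threshold_mV else 0
  }
  above <- v >= threshold_mV
  cross <- which(above & !c(TRUE, above[-length(above)]))
  if (length(cross) == 0L) {
    if (above[1]) return(0) else return(NA_real_)
  }
  (cross[1] - 1) / recording$v_hz
}

#' Critical current at spiking onset
#'
#' The critical current \eqn{I_c} is the average injected current over the
#' one-second interval before the first spike.
#'
#' @param recording a `csd_recording`.
#' @param onset onset time in seconds (>= 1 s into the recording).
#' @return \eqn{I_c} in pA.
#' @export
critical_current <- function(recording, onset) {
  if (is.na(onset) || onset < 1)
    csd_error("insufficient_baseline",
              "onset must be at least 1 s into the recording")
  ti <- (seq_along(recording$current) - 1) / recording$i_hz
  sel <- ti >= onset - 1 & ti < onset
  mean(recording$current[sel])
}

#' Compute the marker series of a trajectory or recording
#'
#' Per perturbation event: the recovery rate \eqn{\lambda} from an
#' exponential fit to the post-pulse window, the variance and
#' lag-normalized autocorrelation of the unperturbed pre-pulse window, the
#' mean voltage before the pulse and the distance to the bifurcation
#' \eqn{\Delta I}.  For recordings \eqn{\Delta I = I_c - I} with \eqn{I}
#' the mean injected current over the pre-window; for model trajectories
#' \eqn{\Delta I} is the distance \eqn{|y|} of the control parameter at
#' the pulse time.  Saddle-node trajectories are detrended along the
#' stable branch first (if not already); the Hopf observable needs no
#' detrending (its equilibrium is the origin).
#'
#' Non-converged recovery fits keep their event (with `lambda = NA`) so
#' the variance and autocorrelation series retain full length.
#'
#' @param x a `csd_trajectory` or `csd_recording`.
#' @param events optional `csd_events` from [locate_perturbations()];
#'   computed with default windows when omitted.
#' @param acf_lag autocorrelation lag in samples; defaults to 100 for
#'   model data and 50 ms worth of samples for recordings.
#' @param I_c override for the critical current (used for no-bifurcation
#'   control recordings, where no onset exists; defaults to the nominal
#'   critical current in the recording's provenance).
#' @return An object of class `marker_series`: `samples` (a data.frame
#'   with columns `pulse_time`, `delta_I`, `lambda`, `r_squared`,
#'   `converged`, `variance`, `acf`, `mean_voltage`), `I_c`, `V_cm`,
#'   `onset_time`, `acf_lag`, `acf_lag_time`, `units` and `kind`.
#' @export
compute_markers <- function(x, events = NULL, acf_lag = NULL, I_c = NULL) {
  UseMethod("compute_markers")
}

event_loop <- function(observable, voltage, events, rate, acf_lag) {
  out <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    pre <- observable[ev$pre_start:ev$pre_end]
    post <- observable[ev$post_start:ev$post_end]
    fit <- withCallingHandlers(
      tryCatch(fit_recovery(post, rate), csd_error = function(e) {
        csd_error("event", sprintf("event %d: %s", i, conditionMessage(e)))
      }),
      warning = function(w) invokeRestart("muffleWarning"))
    v <- tryCatch(segment_variance(pre), csd_error = function(e) {
      csd_error("event", sprintf("event %d: %s", i, conditionMessage(e)))
    })
    ac <- tryCatch(autocorrelation(pre, acf_lag), csd_error = function(e) {
      csd_error("event", sprintf("event %d: %s", i, conditionMessage(e)))
    })
    data.frame(pulse_time = ev$pulse_time, lambda = fit$lambda,
               r_squared = fit$r_squared, converged = fit$converged,
               variance = v, acf = ac,
               mean_voltage = mean(voltage[ev$pre_start:ev$pre_end]))
  })
  do.call(rbind, out)
}

#' @export
compute_markers.csd_trajectory <- function(x, events = NULL, acf_lag = NULL,
                                           I_c = NULL) {
  sn <- x$config$bifurcation_kind == "saddle_node"
  if (sn && is.null(x$Vd)) x <- detrend_saddle_node(x)
  observable <- if (sn) x$Vd else x$V
  if (is.null(events)) events <- locate_perturbations(x)
  if (nrow(events) == 0L) csd_error("empty_series", "no events to analyze")
  if (is.null(acf_lag)) acf_lag <- 100L
  rate <- 1 / x$config$dt

  samples <- event_loop(observable, x$V, events, rate, acf_lag)
  samples$delta_I <- abs(x$y[events$pulse_idx])
  samples <- samples[order(samples$pulse_time),
                     c("pulse_time", "delta_I", "lambda", "r_squared",
                       "converged", "variance", "acf", "mean_voltage")]

  onset <- x$escape_time
  V_cm <- NA_real_
  if (!is.na(onset)) {
    pre_n <- min(5000L, length(x$V))
    V_cm <- mean(x$V[(length(x$V) - pre_n + 1L):length(x$V)])
  }
  structure(list(
    samples = samples, I_c = NA_real_, V_cm = V_cm, onset_time = onset,
    acf_lag = acf_lag, acf_lag_time = acf_lag * x$config$dt,
    units = "model", kind = x$config$bifurcation_kind,
    n_dropped = attr(events, "n_dropped")
  ), class = "marker_series")
}

#' @export
compute_markers.csd_recording <- function(x, events = NULL, acf_lag = NULL,
                                          I_c = NULL) {
  if (is.null(events)) events <- locate_perturbations(x)
  if (nrow(events) == 0L) csd_error("empty_series", "no events to analyze")
  fs <- x$v_hz
  if (is.null(acf_lag)) acf_lag <- as.integer(round(0.05 * fs))

  onset <- x$onset_time
  if (is.null(I_c)) {
    I_c <- if (!is.na(onset)) critical_current(x, onset)
           else x$provenance$nominal_I_c
  }
  if (is.null(I_c) || is.na(I_c))
    csd_error("config",
              "no onset and no nominal critical current: supply I_c explicitly")

  samples <- event_loop(x$voltage, x$voltage, events, fs, acf_lag)
  ti <- (seq_along(x$current) - 1) / x$i_hz
  samples$delta_I <- vapply(seq_len(nrow(events)), function(i) {
    t0 <- (events$pre_start[i] - 1) / fs
    t1 <- (events$pre_end[i]) / fs
    I_c - mean(x$current[ti >= t0 & ti < t1])
  }, numeric(1))
  samples <- samples[order(samples$pulse_time),
                     c("pulse_time", "delta_I", "lambda", "r_squared",
                       "converged", "variance", "acf", "mean_voltage")]

  V_cm <- NA_real_
  if (!is.na(onset) && onset >= 1) {
    tv <- (seq_along(x$voltage) - 1) / fs
    V_cm <- mean(x$voltage[tv >= onset - 1 & tv < onset])
  }
  structure(list(
    samples = samples, I_c = I_c, V_cm = V_cm, onset_time = onset,
    acf_lag = acf_lag, acf_lag_time = acf_lag / fs,
    units = "physical", kind = x$provenance$sde$bifurcation_kind,
    n_dropped = attr(events, "n_dropped")
  ), class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series: %d events (%s units, %s)>\n",
              nrow(x$samples), x$units, x$kind))
  if (!is.na(x$I_c)) cat(sprintf("  I_c = %.4g pA", x$I_c))
  if (!is.na(x$V_cm)) cat(sprintf("  V_cm = %.4g", x$V_cm))
  if (!is.na(x$onset_time)) cat(sprintf("  onset = %.4g", x$onset_time))
  cat(sprintf("\n  acf lag = %d samples (%.4g time units)\n",
              x$acf_lag, x$acf_lag_time))
  print(utils::head(x$samples, 4))
  if (nrow(x$samples) > 4) cat("  ...\n")
  invisible(x)
}
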