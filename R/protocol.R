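#' Patch-clamp step-current stimulation protocol
#'
#' Describes the stimulation and acquisition protocol used to drive a
#' neuron slowly towards its spiking threshold: a step current that
#' increases by `step_increment` pA every `step_duration` seconds, with two
#' brief perturbation pulses (`pulse_amplitude_pA` for `pulse_width_ms`)
#' delivered at fixed offsets within every step, voltage sampled at
#' `v_sampling_hz` and current at `i_sampling_hz`.  The defaults are
#' 3 pA / 4.01 s steps, 50 pA / 5 ms pulses at 1800 ms and 3805 ms into
#' each step, 25 kHz voltage and 2.5 kHz current sampling.
#'
#' The remaining fields bind normal-form dynamics to physical units when
#' the protocol is used by [emulate_patch_recording()]:
#' \describe{
#'   \item{current_scale, current_offset}{affine map between injected
#'     current and the control parameter: step \eqn{k} carries
#'     \eqn{I_k = \mathrm{offset} + k\cdot\mathrm{increment}} pA and the
#'     model sits at \eqn{y_k = y_0 - k\cdot\mathrm{increment}/\mathrm{scale}},
#'     i.e. `current_scale` is pA per model-parameter unit, so
#'     \eqn{\Delta I \propto y} exactly.}
#'   \item{voltage_scale, voltage_offset}{gain (mV per model state unit)
#'     applied to the detrended model fluctuations and the resting
#'     potential (mV) at the baseline current.}
#'   \item{input_resistance}{ohmic gain (mV/pA) of the mean subthreshold
#'     depolarization: the recorded mean voltage rises linearly with
#'     injected current, as in a passive membrane, while the
#'     fluctuations riding on it carry the normal-form statistics.}
#'   \item{time_scale}{model time units per second; sets how fast the
#'     normal-form dynamics run relative to the acquisition clock.}
#'   \item{parabolic_range}{half-width (model state units) of the
#'     parabolic region of the emulated subthreshold I-V curve.  The fold
#'     normal form is the local approximation of the membrane's
#'     nonmonotonic I-V curve near its maximum; farther below threshold a
#'     real membrane's slope conductance approaches the passive leak, so
#'     the recovery rate saturates instead of growing without bound.  The
#'     emulator continues the parabola linearly below
#'     `-parabolic_range`, which confines the square-root scaling of the
#'     recovery rate to roughly the last decade of \eqn{\Delta I}, as
#'     observed.  `Inf` recovers the pure normal form.}
#'   \item{spike_threshold_mV, spike_peak_mV}{onset-detection level and the
#'     peak of the stereotyped spike inserted when the model escapes
#'     (normal forms diverge rather than produce an action potential).}
#' }
#'
#' @param step_increment current step size, pA.
#' @param step_duration seconds per step.
#' @param pulse_amplitude_pA,pulse_width_ms perturbation-pulse height and
#'   duration (they shape the current trace; the state receives the
#'   configured model-unit kick).
#' @param pulse_offsets_ms pulse onset times within each step, ms.
#' @param v_sampling_hz,i_sampling_hz voltage / current sampling rates.
#' @param voltage_scale,voltage_offset,input_resistance,current_scale,current_offset,time_scale,parabolic_range
#'   unit maps and I-V shape, see Details.
#' @param spike_threshold_mV,spike_peak_mV onset detection and spike mark.
#' @return An object of class `patch_protocol`.
#' @export
patch_protocol <- function(step_increment = 3,
                           step_duration = 4.01,
                           pulse_amplitude_pA = 50,
                           pulse_width_ms = 5,
                           pulse_offsets_ms = c(1800, 3805),
                           v_sampling_hz = 25000,
                           i_sampling_hz = 2500,
                           voltage_scale = 10,
                           voltage_offset = -70,
                           input_resistance = 0.55,
                           current_scale = 100,
                           current_offset = 100,
                           time_scale = 100,
                           parabolic_range = Inf,
                           spike_threshold_mV = 0,
                           spike_peak_mV = 30) {
  stopifnot_scalar(v_sampling_hz, "v_sampling_hz", positive = TRUE)
  stopifnot_scalar(i_sampling_hz, "i_sampling_hz", positive = TRUE)
  stopifnot_scalar(step_increment, "step_increment", positive = TRUE)
  stopifnot_scalar(step_duration, "step_duration", positive = TRUE)
  stopifnot_scalar(time_scale, "time_scale", positive = TRUE)
  if (voltage_scale == 0 || current_scale == 0)
    csd_error("config", "voltage_scale and current_scale must be non-zero (affine maps must be invertible)")
  if (any(pulse_offsets_ms < 0 | pulse_offsets_ms >= step_duration * 1000))
    csd_error("config", "pulse_offsets_ms must lie within [0, step_duration * 1000)")
  structure(list(
    step_increment = step_increment, step_duration = step_duration,
    pulse_amplitude_pA = pulse_amplitude_pA, pulse_width_ms = pulse_width_ms,
    pulse_offsets_ms = sort(pulse_offsets_ms),
    v_sampling_hz = v_sampling_hz, i_sampling_hz = i_sampling_hz,
    voltage_scale = voltage_scale, voltage_offset = voltage_offset,
    input_resistance = input_resistance,
    current_scale = current_scale, current_offset = current_offset,
    time_scale = time_scale, parabolic_range = parabolic_range,
    spike_threshold_mV = spike_threshold_mV, spike_peak_mV = spike_peak_mV
  ), class = "patch_protocol")
}

# stable equilibrium of the emulated I-V curve: parabolic within
# parabolic_range of the fold, linear (passive) continuation below
composite_branch <- function(y, rho, v_par) {
  yy <- pmax(y, 0)
  y_par <- rho * v_par^2
  ifelse(yy <= y_par, -sqrt(yy / rho), -(yy / rho + v_par^2) / (2 * v_par))
}

#' Emulate a patch-clamp recording from normal-form dynamics
#'
#' Binds a normal-form system to the stimulation protocol: the current
#' staircase maps onto a per-step-constant control parameter (so
#' \eqn{\Delta I = I_c - I} is proportional to the distance \eqn{|y|} to
#' the bifurcation), the state is integrated at the voltage sampling rate,
#' and the recorded voltage is composed as
#' \deqn{V(t) = V_\mathrm{rest} + R_\mathrm{in}\,(I(t) - I_0) + g\,V_d(t),}
#' an ohmic mean depolarization plus the detrended model fluctuations
#' \eqn{V_d} scaled by `voltage_scale` \eqn{g}.  Perturbation pulses kick
#' the model state instantaneously and appear as rectangles on the current
#' trace.  When the model state escapes its basin, a stereotyped spike
#' sample (`spike_peak_mV`) is written and the recording is truncated at
#' that onset.
#'
#' With `control = TRUE` the control parameter is held fixed at `y0` for
#' the whole recording while the current staircase still ramps: the
#' no-bifurcation control in which every signature of slowing down is
#' absent by construction (the analogue of blocking the spiking mechanism
#' pharmacologically).  No onset occurs; downstream analyses use the
#' nominal critical current stored in the provenance.
#'
#' @param protocol a [patch_protocol()].
#' @param sde an [sde_config()] supplying the model kind, `y0`, noise and
#'   kick amplitudes (its `epsilon`, `dt`, `pulse_spacing` and `t_end` are
#'   ignored: drift and timing come from the protocol).
#' @param control logical; hold `y` fixed (no-bifurcation control mode).
#' @param n_steps number of current steps; defaults to two steps past the
#'   nominal crossing of `y = 0`.
#' @param seed RNG seed for this recording (defaults to `sde$seed`).
#' @return An object of class `csd_recording` with elements `voltage`
#'   (mV, at `v_sampling_hz`), `current` (pA, at `i_sampling_hz`),
#'   `v_hz`, `i_hz`, `pulse_times` (s), `onset_time` (s or `NA`) and
#'   `provenance` (protocol, sde, seed, control flag, the nominal critical
#'   current `nominal_I_c` and the step containing the nominal crossing).
#' @export
emulate_patch_recording <- function(protocol = patch_protocol(),
                                    sde = sde_config(y0 = 0.5, sigma1 = 0.0015),
                                    control = FALSE,
                                    n_steps = NULL,
                                    seed = NULL) {
  if (!inherits(protocol, "patch_protocol"))
    csd_error("config", "`protocol` must be a patch_protocol")
  if (!inherits(sde, "sde_config"))
    csd_error("config", "`sde` must be an sde_config")
  if (is.null(seed)) seed <- sde$seed
  sn <- sde$bifurcation_kind == "saddle_node"

  dy <- protocol$step_increment / abs(protocol$current_scale)
  n_cross <- ceiling(abs(sde$y0) / dy)  # step index at which y crosses 0
  if (is.null(n_steps)) n_steps <- n_cross + 2L
  step_ids <- 0:(n_steps - 1L)
  y_steps <- if (control) rep(sde$y0, n_steps)
             else if (sn) sde$y0 - step_ids * dy
             else sde$y0 + step_ids * dy

  fs <- protocol$v_sampling_hz
  spst <- round(protocol$step_duration * fs)
  dt_model <- protocol$time_scale / fs
  n_total <- n_steps * spst

  # pulse onsets on the voltage grid, 1-based
  off_idx <- round(protocol$pulse_offsets_ms / 1000 * fs)
  pulse_idx <- as.integer(outer(off_idx, step_ids * spst, `+`) + 1L)
  pulse_idx <- sort(pulse_idx[pulse_idx >= 1L & pulse_idx <= n_total])
  pulse_times <- (pulse_idx - 1L) / fs

  # the emulated cell starts at rest: on the stable branch for the first
  # step's control value (saddle-node) or at the origin (Hopf)
  state0 <- if (sn) {
    composite_branch(max(y_steps[1], 1e-12), sde$rho, protocol$parabolic_range)
  } else c(0, 0)

  set.seed(seed)
  if (sn) {
    res <- staircase_sn_cpp(y_steps, spst, state0[1], sde$rho, sde$sigma1,
                            sde$pulse_amplitude, pulse_idx, dt_model,
                            sde$escape_bound, protocol$parabolic_range)
    vd <- res$Vd
  } else {
    res <- staircase_hopf_cpp(y_steps, spst, state0[1], state0[2],
                              sde$sigma1, sde$sigma2, sde$pulse_amplitude,
                              pulse_idx, dt_model, sde$escape_bound)
    vd <- res$V1
  }
  if (!is.na(res$bad_idx))
    csd_error("integration_failure",
              sprintf("state became non-finite at sample %d", res$bad_idx))

  n <- length(vd)
  samp_step <- pmin((seq_len(n) - 1L) %/% spst, n_steps - 1L)
  i_level <- protocol$current_offset + samp_step * protocol$step_increment
  voltage <- protocol$voltage_offset +
    protocol$input_resistance * (i_level - protocol$current_offset) +
    protocol$voltage_scale * vd

  onset_time <- NA_real_
  if (!is.na(res$escape_idx)) {
    voltage[res$escape_idx] <- protocol$spike_peak_mV
    onset_time <- (res$escape_idx - 1L) / fs
  }

  t_end <- (n - 1L) / fs
  fi <- protocol$i_sampling_hz
  ti <- seq(0, t_end, by = 1 / fi)
  cur_step <- pmin(floor(ti / protocol$step_duration), n_steps - 1L)
  current <- protocol$current_offset + cur_step * protocol$step_increment
  # pulse rectangles on the current trace
  w <- protocol$pulse_width_ms / 1000
  for (tp in pulse_times) {
    current[ti >= tp & ti < tp + w] <- current[ti >= tp & ti < tp + w] +
      protocol$pulse_amplitude_pA
  }

  # current at which the mapped control parameter crosses the bifurcation
  nominal_I_c <- protocol$current_offset + abs(sde$y0) * abs(protocol$current_scale)

  structure(list(
    voltage = voltage, v_hz = fs,
    current = current, i_hz = fi,
    pulse_times = pulse_times[pulse_times <= t_end],
    onset_time = onset_time,
    provenance = list(protocol = protocol, sde = sde, seed = seed,
                      control = control, nominal_I_c = nominal_I_c,
                      crossing_step = n_cross, n_steps = n_steps)
  ), class = "csd_recording")
}

#' Simulate a batch of recording trials with cell-to-cell variability
#'
#' Generates `n_trials` independent emulated recordings, jittering three
#' cell properties multiplicatively (uniform within `1 +/- jitter`) across
#' trials, emulating the spread seen across recorded neurons:
#' \describe{
#'   \item{`y0_jitter` (rheobase spread)}{how far above the resting
#'     current the critical current sits; the dominant source of
#'     across-trial variation in the voltage span of the subthreshold
#'     approach.}
#'   \item{`rin_jitter` (input resistance)}{the mV-per-pA slope, which
#'     sets the voltage spacing of perturbation pulses and thereby the
#'     measured distance of the last usable recovery from threshold.}
#'   \item{`sigma_jitter` (intrinsic noise)}{the amplitude of the
#'     subthreshold voltage fluctuations.}
#' }
#' Each trial gets its own derived seed (`seed + i`), so a batch is fully
#' reproducible from `seed`.
#'
#' @param n_trials number of trials.
#' @param protocol a [patch_protocol()] template shared by all trials.
#' @param sde an [sde_config()] template.
#' @param seed base seed; trial `i` uses `seed + i`.
#' @param y0_jitter,rin_jitter,sigma_jitter relative jitter half-widths.
#' @param control generate no-bifurcation control trials instead.
#' @return A list of `csd_recording` objects.
#' @export
simulate_trial_batch <- function(n_trials = 25,
                                 protocol = patch_protocol(),
                                 sde = sde_config(y0 = 0.5, sigma1 = 0.0015),
                                 seed = 1L,
                                 y0_jitter = 0.5,
                                 rin_jitter = 0.25,
                                 sigma_jitter = 0.3,
                                 control = FALSE) {
  lapply(seq_len(n_trials), function(i) {
    trial_seed <- as.integer(seed + i)
    set.seed(trial_seed)
    jit <- stats::runif(3, -1, 1)
    sde_i <- sde
    sde_i$y0 <- sde$y0 * (1 + y0_jitter * jit[1])
    sde_i$sigma1 <- sde$sigma1 * (1 + sigma_jitter * jit[3])
    proto_i <- protocol
    proto_i$input_resistance <- protocol$input_resistance * (1 + rin_jitter * jit[2])
    emulate_patch_recording(proto_i, sde_i, control = control,
                            seed = trial_seed)
  })
}

#' @export
print.csd_recording <- function(x, ...) {
  n <- length(x$voltage)
  cat("<csd_recording>\n")
  cat(sprintf("  %.2f s of voltage at %g Hz, current at %g Hz\n",
              (n - 1) / x$v_hz, x$v_hz, x$i_hz))
  cat(sprintf("  %d perturbation pulses; onset %s\n", length(x$pulse_times),
              if (is.na(x$onset_time)) "not reached"
              else sprintf("at %.3f s", x$onset_time)))
  if (isTRUE(x$provenance$control))
    cat("  no-bifurcation control mode (y held fixed)\n")
  invisible(x)
}
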