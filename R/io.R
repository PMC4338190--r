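# File round-tripping: tidy CSV/TSV for series, JSON sidecars for
# configuration and metadata.  Floats are written with 9 significant
# digits so identical runs produce byte-identical files.

fmt9 <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "NA"
  out
}

write_formatted <- function(df, path, sep = ",", header_lines = character()) {
  txt <- vapply(df, function(col) {
    if (is.numeric(col)) fmt9(col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) txt <- matrix(txt, nrow = 1)
  lines <- c(header_lines,
             paste(names(df), collapse = sep),
             apply(txt, 1, paste, collapse = sep))
  writeLines(lines, path)
}

config_as_list <- function(x) {
  out <- unclass(x)
  out[!vapply(out, is.function, logical(1))]
}

#' Write / read a simulated trajectory
#'
#' The trajectory goes to `<stem>.csv` (columns `time`, `V`, optionally
#' `V2`, and `y`, 9 significant digits) with a `<stem>.json` sidecar
#' carrying the configuration, pulse times, `t_c` and escape time.
#'
#' @param traj a `csd_trajectory`.
#' @param stem output path without extension.
#' @return `write_trajectory` returns `stem` invisibly; `read_trajectory`
#'   returns the reconstructed `csd_trajectory`.
#' @export
write_trajectory <- function(traj, stem) {
  df <- data.frame(time = traj$times, V = traj$V)
  if (!is.null(traj$V2)) df$V2 <- traj$V2
  df$y <- traj$y
  write_formatted(df, paste0(stem, ".csv"))
  meta <- list(
    config = config_as_list(traj$config),
    pulse_times = traj$pulse_times,
    t_c = if (is.finite(traj$t_c)) traj$t_c else NULL,
    escape_time = if (is.na(traj$escape_time)) NULL else traj$escape_time,
    detrended = !is.null(traj$Vd)
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(stem) {
  csv <- paste0(stem, ".csv")
  df <- tryCatch(
    utils::read.csv(csv, colClasses = "numeric"),
    error = function(e) csd_error("parse",
      sprintf("cannot parse %s: %s", csv, conditionMessage(e)))
  )
  if (anyNA(df$time) || anyNA(df$V)) {
    bad <- which(is.na(df$time) | is.na(df$V))[1]
    csd_error("parse", sprintf("non-numeric value in %s at data row %d", csv, bad))
  }
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  cfg <- meta$config
  config <- sde_config(
    bifurcation_kind = cfg$bifurcation_kind, epsilon = cfg$epsilon,
    rho = cfg$rho, sigma1 = cfg$sigma1, sigma2 = cfg$sigma2,
    pulse_amplitude = cfg$pulse_amplitude, pulse_spacing = cfg$pulse_spacing,
    y0 = cfg$y0, state0 = unlist(cfg$state0), dt = cfg$dt, seed = cfg$seed,
    escape_bound = cfg$escape_bound, t_end = cfg$t_end
  )
  out <- list(
    times = df$time, V = df$V, y = df$y,
    pulse_times = as.numeric(meta$pulse_times),
    pulse_idx = as.integer(round(as.numeric(meta$pulse_times) / config$dt)) + 1L,
    t_c = if (is.null(meta$t_c)) Inf else meta$t_c,
    escape_time = if (is.null(meta$escape_time)) NA_real_ else meta$escape_time,
    config = config
  )
  if (!is.null(df$V2)) out$V2 <- df$V2
  structure(out, class = "csd_trajectory")
}

#' Write / read an emulated patch-clamp recording
#'
#' Voltage and current run at different sampling rates, so they go to
#' separate tidy CSVs, `<stem>_voltage.csv` (`time_s`, `voltage_mV`) and
#' `<stem>_current.csv` (`time_s`, `current_pA`), with a `<stem>.json`
#' sidecar carrying pulse times, onset, sampling rates and provenance.
#'
#' @param rec a `csd_recording`.
#' @param stem output path without extension.
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   the reconstructed `csd_recording`.
#' @export
write_recording <- function(rec, stem) {
  tv <- (seq_along(rec$voltage) - 1) / rec$v_hz
  ti <- (seq_along(rec$current) - 1) / rec$i_hz
  write_formatted(data.frame(time_s = tv, voltage_mV = rec$voltage),
                  paste0(stem, "_voltage.csv"))
  write_formatted(data.frame(time_s = ti, current_pA = rec$current),
                  paste0(stem, "_current.csv"))
  prov <- rec$provenance
  meta <- list(
    v_hz = rec$v_hz, i_hz = rec$i_hz,
    pulse_times = rec$pulse_times,
    onset_time = if (is.na(rec$onset_time)) NULL else rec$onset_time,
    provenance = list(
      protocol = config_as_list(prov$protocol),
      sde = config_as_list(prov$sde),
      seed = prov$seed, control = prov$control,
      nominal_I_c = prov$nominal_I_c, crossing_step = prov$crossing_step,
      n_steps = prov$n_steps
    )
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  vdf <- utils::read.csv(paste0(stem, "_voltage.csv"))
  idf <- utils::read.csv(paste0(stem, "_current.csv"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  p <- meta$provenance
  protocol <- do.call(patch_protocol, p$protocol)
  sde <- sde_config(
    bifurcation_kind = p$sde$bifurcation_kind, epsilon = p$sde$epsilon,
    rho = p$sde$rho, sigma1 = p$sde$sigma1, sigma2 = p$sde$sigma2,
    pulse_amplitude = p$sde$pulse_amplitude,
    pulse_spacing = p$sde$pulse_spacing, y0 = p$sde$y0,
    state0 = unlist(p$sde$state0), dt = p$sde$dt, seed = p$sde$seed,
    escape_bound = p$sde$escape_bound, t_end = p$sde$t_end
  )
  structure(list(
    voltage = vdf$voltage_mV, v_hz = meta$v_hz,
    current = idf$current_pA, i_hz = meta$i_hz,
    pulse_times = as.numeric(meta$pulse_times),
    onset_time = if (is.null(meta$onset_time)) NA_real_ else meta$onset_time,
    provenance = list(protocol = protocol, sde = sde, seed = p$seed,
                      control = isTRUE(p$control), nominal_I_c = p$nominal_I_c,
                      crossing_step = p$crossing_step, n_steps = p$n_steps)
  ), class = "csd_recording")
}

#' Write / read a marker series
#'
#' Tab-separated values with one row per perturbation event and `#`
#' header comments carrying `I_c`, `V_cm`, the autocorrelation lag, the
#' onset time and the unit system.
#'
#' @param series a `marker_series`.
#' @param path output TSV path.
#' @return `write_marker_series` returns `path` invisibly;
#'   `read_marker_series` the reconstructed `marker_series`.
#' @export
write_marker_series <- function(series, path) {
  hdr <- c(
    sprintf("# I_c\t%s", fmt9(series$I_c)),
    sprintf("# V_cm\t%s", fmt9(series$V_cm)),
    sprintf("# onset_time\t%s", fmt9(series$onset_time)),
    sprintf("# acf_lag\t%d", series$acf_lag),
    sprintf("# acf_lag_time\t%s", fmt9(series$acf_lag_time)),
    sprintf("# units\t%s", series$units),
    sprintf("# kind\t%s", series$kind),
    sprintf("# n_dropped\t%d", as.integer(series$n_dropped %||% 0L))
  )
  s <- series$samples
  df <- data.frame(pulse_time_s = s$pulse_time, delta_I_pA = s$delta_I,
                   lambda_per_s = s$lambda, r_squared = s$r_squared,
                   converged = s$converged, variance_mV2 = s$variance,
                   acf = s$acf, mean_voltage_mV = s$mean_voltage)
  write_formatted(df, path, sep = "\t", header_lines = hdr)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_marker_series
#' @export
read_marker_series <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  num <- function(k) suppressWarnings(as.numeric(meta[[k]]))
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  samples <- data.frame(pulse_time = df$pulse_time_s, delta_I = df$delta_I_pA,
                        lambda = df$lambda_per_s, r_squared = df$r_squared,
                        converged = as.logical(df$converged),
                        variance = df$variance_mV2, acf = df$acf,
                        mean_voltage = df$mean_voltage_mV)
  structure(list(
    samples = samples, I_c = num("I_c"), V_cm = num("V_cm"),
    onset_time = num("onset_time"), acf_lag = as.integer(num("acf_lag")),
    acf_lag_time = num("acf_lag_time"),
    units = unname(meta[["units"]]), kind = unname(meta[["kind"]]),
    n_dropped = as.integer(num("n_dropped"))
  ), class = "marker_series")
}

#' Write exponent estimates and classification
#'
#' Per-cutoff fits go to `<stem>.tsv` (`marker`, `symbol`, `delta_I_min`,
#' `exponent`, `intercept`, `r_squared`, `accepted`); the aggregate
#' means/sds and the bifurcation classification go to `<stem>.json`.
#'
#' @param estimates a named list of `exponent_estimate` objects.
#' @param classification optional `bifurcation_class` (or a character
#'   label such as `"rejected"` when classification was impossible).
#' @param stem output path without extension.
#' @return `stem`, invisibly.
#' @export
write_exponents <- function(estimates, classification = NULL, stem) {
  rows <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(marker = e$marker, symbol = e$symbol,
               delta_I_min = e$per_cutoff$delta_I_min,
               exponent = e$per_cutoff$exponent,
               intercept = e$per_cutoff$intercept,
               r_squared = e$per_cutoff$r_squared,
               accepted = e$per_cutoff$accepted)
  }))
  write_formatted(rows, paste0(stem, ".tsv"), sep = "\t")
  summary <- lapply(estimates, function(e) {
    list(symbol = e$symbol, mean_exponent = e$mean_exponent,
         sd_exponent = e$sd_exponent, n_accepted = e$n_accepted)
  })
  cls <- if (inherits(classification, "bifurcation_class")) {
    list(label = classification$label, distance = classification$distance)
  } else if (!is.null(classification)) {
    list(label = as.character(classification))
  }
  jsonlite::write_json(list(exponents = summary, classification = cls),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(stem)
}

#' Write per-trial tipping predictions and the cross-trial regression
#'
#' @param predictions list of `tipping_prediction` objects.
#' @param correlation optional `prediction_correlation`.
#' @param stem output path without extension (TSV + JSON).
#' @return `stem`, invisibly.
#' @export
write_predictions <- function(predictions, correlation = NULL, stem) {
  df <- do.call(rbind, lapply(seq_along(predictions), function(i) {
    p <- predictions[[i]]
    data.frame(trial = i, V_cp = p$V_cp, V_last = p$V_last,
               delta_V_p = p$delta_V_p, delta_V_m = p$delta_V_m,
               theta = p$theta_used, r_squared = p$fit_r_squared,
               n_points = p$n_points)
  }))
  write_formatted(df, paste0(stem, ".tsv"), sep = "\t")
  corr <- if (!is.null(correlation)) {
    list(r = correlation$r, p_value = correlation$p_value,
         slope = correlation$slope, intercept = correlation$intercept,
         n_trials = correlation$n_trials, theta_used = correlation$theta_used)
  }
  jsonlite::write_json(list(regression = corr),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(stem)
}
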