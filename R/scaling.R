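#' Fit a power law to a marker versus the distance to the bifurcation
#'
#' Ordinary least squares of \eqn{\log x} on \eqn{\log \Delta I} over the
#' samples with \eqn{\Delta I} above a minimal cutoff:
#' \eqn{\log x = A \log \Delta I + B}.  Samples with \eqn{\Delta I \le 0},
#' missing \eqn{\lambda}, or a non-positive marker value are excluded
#' before taking logs.  Fits with \eqn{R^2 < 0.1} are flagged `rejected`
#' and excluded from exponent averaging downstream.
#'
#' @param series a `marker_series` from [compute_markers()].
#' @param marker which marker to fit: `"lambda"`, `"variance"` or `"acf"`.
#' @param delta_I_min samples with `delta_I <= delta_I_min` are discarded.
#' @param r2_threshold rejection threshold on \eqn{R^2} (default 0.1).
#' @return A list of class `power_law_fit`: `exponent_A`, `intercept_B`,
#'   `r_squared`, `n_points`, `delta_I_min`, `marker`, `rejected`.
#' @export
fit_power_law <- function(series, marker = c("lambda", "variance", "acf"),
                          delta_I_min = 0, r2_threshold = 0.1) {
  marker <- match.arg(marker)
  s <- series$samples
  x <- s[[marker]]
  ok <- is.finite(x) & x > 0 & is.finite(s$delta_I) & s$delta_I > delta_I_min
  if (sum(ok) < 5L)
    csd_error("insufficient_data",
              sprintf("only %d usable samples above delta_I_min = %g (need 5)",
                      sum(ok), delta_I_min))
  fit <- stats::lm(log(x[ok]) ~ log(s$delta_I[ok]))
  # summary.lm warns on numerically perfect fits; the R^2 itself is fine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    exponent_A = unname(stats::coef(fit)[2]),
    intercept_B = unname(stats::coef(fit)[1]),
    r_squared = r2, n_points = sum(ok), delta_I_min = delta_I_min,
    marker = marker, rejected = r2 < r2_threshold
  ), class = "power_law_fit")
}

marker_symbol <- c(lambda = "theta", variance = "tau", acf = "kappa")

#' Sweep the minimal-distance cutoff and aggregate the exponent
#'
#' Repeats [fit_power_law()] over a grid of minimal \eqn{\Delta I} values
#' and reports the mean and standard deviation of the exponent over the
#' accepted (non-rejected) fits, giving an exponent estimate robust to the
#' choice of fit interval.  The default grid is 8 logarithmically spaced
#' cutoffs between the 5th and 60th percentile of the observed positive
#' \eqn{\Delta I} values.
#'
#' @inheritParams fit_power_law
#' @param grid cutoff values; computed from the data when omitted.
#' @return A list of class `exponent_estimate`: `marker`, `symbol`
#'   (`theta`, `tau` or `kappa`), `mean_exponent`, `sd_exponent`,
#'   `per_cutoff` (data.frame over the grid), `grid`, `n_accepted`.
#' @export
sweep_exponents <- function(series, marker = c("lambda", "variance", "acf"),
                            grid = NULL, r2_threshold = 0.1) {
  marker <- match.arg(marker)
  s <- series$samples
  x <- s[[marker]]
  pos <- s$delta_I[is.finite(x) & x > 0 & is.finite(s$delta_I) & s$delta_I > 0]
  if (length(pos) < 5L)
    csd_error("insufficient_data", "fewer than 5 usable samples in the series")
  if (is.null(grid)) {
    q <- stats::quantile(pos, c(0.05, 0.60), names = FALSE)
    grid <- exp(seq(log(q[1]), log(q[2]), length.out = 8))
  }
  if (length(grid) == 0L) csd_error("config", "cutoff grid is empty")

  fits <- lapply(grid, function(g) {
    tryCatch(fit_power_law(series, marker, delta_I_min = g,
                           r2_threshold = r2_threshold),
             csd_insufficient_data = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep))
    csd_error("insufficient_data", "no cutoff left enough samples to fit")
  per <- do.call(rbind, lapply(fits[keep], function(f) {
    data.frame(delta_I_min = f$delta_I_min, exponent = f$exponent_A,
               intercept = f$intercept_B, r_squared = f$r_squared,
               n_points = f$n_points, accepted = !f$rejected)
  }))
  if (!any(per$accepted))
    csd_error("all_fits_rejected",
              sprintf("all %s fits were rejected (R^2 < %g): no scaling present",
                      marker, r2_threshold))
  acc <- per$exponent[per$accepted]
  structure(list(
    marker = marker, symbol = unname(marker_symbol[marker]),
    mean_exponent = mean(acc),
    sd_exponent = if (length(acc) > 1L) stats::sd(acc) else 0,
    per_cutoff = per, grid = grid, n_accepted = length(acc)
  ), class = "exponent_estimate")
}

#' @export
print.exponent_estimate <- function(x, ...) {
  cat(sprintf("<exponent_estimate: %s (%s) = %.3f +/- %.3f over %d/%d cutoffs>\n",
              x$symbol, x$marker, x$mean_exponent, x$sd_exponent,
              x$n_accepted, nrow(x$per_cutoff)))
  invisible(x)
}

#' Classify the governing bifurcation from fitted exponents
#'
#' Nearest-template classification of the recovery-rate and variance
#' exponents \eqn{(\theta, \tau)} against the theoretical pairs
#' \eqn{(0.5, -0.5)} for a saddle-node and \eqn{(1, -1)} for a subcritical
#' Hopf bifurcation.  The result is `"indeterminate"` when both templates
#' are farther than `max_distance` (Euclidean, in exponent space), when
#' the two templates are equidistant, or when \eqn{\theta} and \eqn{\tau}
#' individually point at different templates.  The autocorrelation
#' exponent \eqn{\kappa} is never used for classification: it depends on
#' the lag at which the autocorrelation is measured.
#'
#' @param theta an `exponent_estimate` for the `lambda` marker.
#' @param tau an `exponent_estimate` for the `variance` marker.
#' @param max_distance template-acceptance radius (default 0.35).
#' @return A list of class `bifurcation_class`: `label` (`"saddle_node"`,
#'   `"hopf"` or `"indeterminate"`), `distance` to the nearest template,
#'   `theta`, `tau`.
#' @export
classify_bifurcation <- function(theta, tau, max_distance = 0.35) {
  for (est in list(theta, tau)) {
    if (!inherits(est, "exponent_estimate"))
      csd_error("unclassifiable", "inputs must be accepted exponent_estimate objects")
  }
  if (theta$marker != "lambda" || tau$marker != "variance")
    csd_error("unclassifiable",
              "classification needs the lambda (theta) and variance (tau) estimates")
  th <- theta$mean_exponent
  ta <- tau$mean_exponent
  templates <- list(saddle_node = c(0.5, -0.5), hopf = c(1, -1))
  d <- vapply(templates, function(tp) sqrt((th - tp[1])^2 + (ta - tp[2])^2),
              numeric(1))
  nearest_th <- names(which.min(abs(th - c(saddle_node = 0.5, hopf = 1))))
  nearest_ta <- names(which.min(abs(ta - c(saddle_node = -0.5, hopf = -1))))
  label <- names(which.min(d))
  if (min(d) > max_distance || abs(diff(d)) < 1e-12 ||
      !identical(nearest_th, nearest_ta))
    label <- "indeterminate"
  structure(list(label = label, distance = unname(min(d)), theta = th,
                 tau = ta), class = "bifurcation_class")
}

#' @export
print.bifurcation_class <- function(x, ...) {
  cat(sprintf("<bifurcation_class: %s (theta = %.3f, tau = %.3f, distance = %.3f)>\n",
              x$label, x$theta, x$tau, x$distance))
  invisible(x)
}
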