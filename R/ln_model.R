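#' Model neuron for forward simulation
#'
#' Parameterizes a linear-nonlinear (LN) cascade neuron: a Gaussian spatial
#' receptive field, a biphasic temporal filter, raised-cosine direction
#' tuning of strength \code{dsi_true}, ON/OFF contrast preference of
#' strength \code{csi_true}, a threshold-linear rectifier, and
#' single-exponential calcium-indicator dynamics. These are the planted
#' ground-truth parameters that the analysis pipeline estimates.
#'
#' @param rf_center receptive-field center \code{c(azimuth, elevation)} in
#'   degrees
#' @param rf_sigma spatial Gaussian sigma in degrees
#' @param temporal_filter filter taps at the stimulus rate (use
#'   \code{\link{biphasic_filter}})
#' @param pref_direction preferred motion direction in degrees
#' @param dsi_true planted direction selectivity in [0, 1]
#' @param contrast_pref \code{"ON"} or \code{"OFF"}
#' @param csi_true planted contrast selectivity in [0, 1]
#' @param rectifier_threshold threshold of the output rectifier
#'   \code{max(x - threshold, 0)}; \code{-Inf} disables rectification
#'   (linear readout)
#' @param calcium_tau indicator decay time constant in seconds; 0 disables
#'   calcium filtering
#' @param gain output gain (dF/F units per unit drive)
#' @return a \code{neuron_model} list
#' @export
neuron_model <- function(rf_center = c(30, 27.5), rf_sigma = 6,
                         temporal_filter = biphasic_filter(),
                         pref_direction = 0, dsi_true = 0,
                         contrast_pref = c("ON", "OFF"), csi_true = 0,
                         rectifier_threshold = 0, calcium_tau = 0.25,
                         gain = 1) {
  contrast_pref <- match.arg(contrast_pref)
  if (dsi_true < 0 || dsi_true > 1) stop("dsi_true must be in [0,1]", call. = FALSE)
  if (csi_true < 0 || csi_true > 1) stop("csi_true must be in [0,1]", call. = FALSE)
  if (calcium_tau < 0) stop("calcium_tau must be >= 0", call. = FALSE)
  if (!all(is.finite(temporal_filter)))
    stop("temporal_filter must be finite", call. = FALSE)
  structure(list(rf_center = rf_center, rf_sigma = rf_sigma,
                 temporal_filter = temporal_filter,
                 pref_direction = pref_direction, dsi_true = dsi_true,
                 contrast_pref = contrast_pref, csi_true = csi_true,
                 rectifier_threshold = rectifier_threshold,
                 calcium_tau = calcium_tau, gain = gain),
            class = "neuron_model")
}

#' Biphasic temporal filter
#'
#' A fast positive (ON) lobe followed by a delayed negative (OFF) lobe,
#' each a gamma-shaped bump, sampled at \code{rate}. Peak amplitude of the
#' ON lobe is normalized to 1.
#'
#' @param rate sampling rate in Hz
#' @param t_peak_on,t_peak_off lobe peak times in seconds
#' @param off_amplitude amplitude of the negative lobe relative to the ON
#'   lobe (positive number)
#' @param span filter length in seconds
#' @param shape gamma shape parameter (larger = narrower lobes)
#' @return numeric vector of filter taps
#' @export
biphasic_filter <- function(rate = 20, t_peak_on = 0.2, t_peak_off = 0.6,
                            off_amplitude = 0.5, span = 2, shape = 4) {
  t <- seq(0, span - 1 / rate, by = 1 / rate)
  bump <- function(tp) {
    y <- (t / tp)^shape * exp(shape * (1 - t / tp))
    y[t < 0] <- 0
    y
  }
  f <- bump(t_peak_on) - off_amplitude * bump(t_peak_off)
  f / max(f)
}

#' @noRd
calcium_kernel <- function(tau, rate) {
  if (tau <= 0) return(1)
  n <- max(2L, ceiling(5 * tau * rate))
  k <- exp(-(seq_len(n) - 1) / (tau * rate))
  k / sum(k)
}

# causal FIR convolution with zero padding on the left
causal_conv <- function(x, f) {
  p <- length(f)
  if (p == 1L) return(x * f)
  y <- stats::filter(c(rep(0, p - 1), x), f, method = "convolution", sides = 1)
  as.numeric(y[p:(p + length(x) - 1)])
}

#' @noRd
rectify_drive <- function(x, threshold) {
  if (!is.finite(threshold)) return(x)
  pmax(x - threshold, 0)
}

#' Bar-center positions of a ternary-noise stimulus, in degrees
#' @param noise a \code{ternary_noise}
#' @return numeric vector of bar centers along the tilt axis
#' @export
noise_bar_centers <- function(noise) {
  n_bars <- ncol(noise$values)
  bar_w <- noise$bar_size[1]
  (seq_len(n_bars) - 0.5) * bar_w
}

# Gaussian spatial receptive field sampled at bar centers; the coordinate
# along the bar axis is azimuth for vertical bars and elevation for
# horizontal bars.
spatial_rf_weights <- function(model, noise) {
  centers <- noise_bar_centers(noise)
  mu <- if (noise$orientation == "vertical") model$rf_center[1] else model$rf_center[2]
  exp(-(centers - mu)^2 / (2 * model$rf_sigma^2))
}

#' Raised-cosine direction modulation
#'
#' Multiplicative gain of the drive as a function of motion direction:
#' 1 at the preferred direction, \code{1 - dsi_true} at the null
#' direction, interpolated by a raised cosine of angular distance.
#'
#' @param model a \code{neuron_model}
#' @param direction_deg motion direction(s) in degrees
#' @return modulation factor(s) in [1 - dsi_true, 1]
#' @export
direction_modulation <- function(model, direction_deg) {
  d <- (direction_deg - model$pref_direction) * pi / 180
  1 - model$dsi_true * (1 - cos(d)) / 2
}

#' @noRd
contrast_modulation <- function(model, contrast) {
  pref_sign <- if (model$contrast_pref == "ON") 1 else -1
  ifelse(sign(contrast) == pref_sign, 1, 1 - model$csi_true)
}

#' Simulate the calcium response of an LN model neuron
#'
#' Forward model: a linear drive (spatial receptive field applied to the
#' temporally filtered stimulus, or an epoch-timed transient for moving
#' stimuli scaled by direction/contrast modulation), passed through a
#' threshold-linear rectifier, convolved with the calcium-indicator
#' kernel, plus optional Gaussian pixel noise. Output is a dF/F trace at
#' the stimulus rate.
#'
#' For a \code{ternary_noise} stimulus the full space-time convolution is
#' computed. For a moving edge/bar stimulus (the epoch list returned by
#' \code{\link{make_motion_stimuli}} together with its \code{spec}) each
#' epoch contributes a raised-cosine transient centered on the time the
#' edge front crosses the receptive-field center, with amplitude
#' \code{gain * direction_modulation * contrast_modulation}. For a flash
#' epoch table, ON (or OFF, per \code{contrast_pref}) epochs drive a step
#' transient.
#'
#' @param model a \code{neuron_model}
#' @param stimulus a \code{ternary_noise}, or the list returned by
#'   \code{make_motion_stimuli} with element \code{spec} attached
#' @param frame_rate output rate in Hz (moving/flash stimuli); ternary
#'   noise responses are generated at the noise update rate
#' @param noise_sd standard deviation of additive Gaussian noise (dF/F
#'   units); 0 = noiseless
#' @param seed seed for the noise draw
#' @param transient_width width of the moving-stimulus response transient
#'   in seconds
#' @return list with \code{response} (dF/F), \code{time} (s), \code{rate}
#' @export
simulate_ln_response <- function(model, stimulus, frame_rate = 15,
                                 noise_sd = 0, seed = NULL,
                                 transient_width = 0.4) {
  stopifnot(inherits(model, "neuron_model"))
  if (inherits(stimulus, "ternary_noise")) {
    rate <- stimulus$update_rate
    w <- spatial_rf_weights(model, stimulus)
    if (length(w) != ncol(stimulus$values))
      stop("spatial receptive field does not match stimulus bar grid",
           call. = FALSE)
    filtered <- apply(stimulus$values, 2, causal_conv, f = model$temporal_filter)
    lin <- model$gain * as.numeric(filtered %*% w)
  } else if (is.list(stimulus) && !is.null(stimulus$epochs)) {
    rate <- frame_rate
    lin <- epoch_drive(model, stimulus, rate, transient_width)
  } else {
    stop("unsupported stimulus type", call. = FALSE)
  }
  y <- rectify_drive(lin, model$rectifier_threshold)
  y <- causal_conv(y, calcium_kernel(model$calcium_tau, rate))
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  list(response = y, time = (seq_along(y) - 1) / rate, rate = rate)
}

# per-epoch transient drive for moving-edge/bar and flash stimuli
epoch_drive <- function(model, stimulus, rate, transient_width) {
  ep <- stimulus$epochs
  total <- max(ep$t_end)
  t <- seq(0, total, by = 1 / rate)
  drive <- numeric(length(t))
  for (i in seq_len(nrow(ep))) {
    if (identical(ep$kind[i], "on") || identical(ep$kind[i], "off")) {
      # flash: step drive, attenuated by (1 - csi) for the non-preferred
      # polarity via the contrast modulation
      amp <- model$gain * contrast_modulation(model, ep$contrast[i])
      idx <- t >= ep$t_start[i] & t < ep$t_end[i]
      drive[idx] <- drive[idx] + amp
    } else {
      theta <- ep$direction_deg[i]
      amp <- model$gain * direction_modulation(model, theta) *
        contrast_modulation(model, ep$contrast[i])
      tc <- ep$t_start[i] + edge_crossing_time(model, theta,
                                               stimulus$traversal %||%
                                                 (ep$t_end[i] - ep$t_start[i]))
      u <- (t - tc) / transient_width
      bump <- ifelse(abs(u) < 0.5, cos(pi * u)^2, 0)
      drive <- drive + amp * bump
    }
  }
  drive
}

# time for an edge moving along direction theta to reach the RF center,
# as a fraction of the traversal time; the front sweeps the projection of
# the screen onto the motion axis
edge_crossing_time <- function(model, theta_deg, traversal) {
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th))
  corners <- rbind(c(0, 0), c(SCREEN_AZIMUTH, 0), c(0, SCREEN_ELEVATION),
                   c(SCREEN_AZIMUTH, SCREEN_ELEVATION))
  proj <- corners %*% u
  s <- sum(model$rf_center * u)
  frac <- (s - min(proj)) / (max(proj) - min(proj))
  frac * traversal
}

#' Effective ground-truth STRF of a model neuron
#'
#' The linear filter that reverse correlation of the calcium signal can
#' recover: the temporal filter convolved with the calcium-indicator
#' kernel (the measured signal is the calcium-filtered drive), times the
#' bar-sampled spatial Gaussian, scaled by the gain.
#'
#' @param model a \code{neuron_model}
#' @param noise the \code{ternary_noise} stimulus defining the bar grid
#'   and update rate
#' @param n_lags number of lags (default 2 s at the update rate)
#' @return matrix [n_lags x n_bars]
#' @export
strf_ground_truth <- function(model, noise, n_lags = 2 * noise$update_rate) {
  rate <- noise$update_rate
  eff <- causal_conv(c(model$temporal_filter,
                       numeric(max(0, n_lags - length(model$temporal_filter)))),
                     calcium_kernel(model$calcium_tau, rate))[seq_len(n_lags)]
  model$gain * outer(eff, spatial_rf_weights(model, noise))
}
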