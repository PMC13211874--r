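#' Flash-response metrics
#'
#' ON/OFF step amplitudes and time to peak for a full-field flash: the
#' step is the difference between the peak response within
#' \code{window_s} after light onset (offset) and the mean over
#' \code{window_s} before it; time to peak is the delay from light onset
#' to the response maximum within the ON epoch.
#'
#' @param trace a \code{response_trace} or numeric vector
#' @param t_on,t_off light onset and offset times in seconds
#' @param rate sampling rate (bare vectors)
#' @param window_s pre/post window length in seconds
#' @return list: on_step, off_step (dF/F), time_to_peak (s)
#' @export
flash_metrics <- function(trace, t_on, t_off, rate = NULL, window_s = 2) {
  tr <- as_trace(trace, rate)
  t <- tr$time; v <- tr$values
  if (min(t) > t_on - window_s || max(t) < t_off + window_s)
    stop("trace does not cover the required flash windows", call. = FALSE)
  step_at <- function(t0) {
    post <- v[t >= t0 & t <= t0 + window_s]
    pre <- v[t >= t0 - window_s & t < t0]
    max(post) - mean(pre)
  }
  on_epoch <- t >= t_on & t <= t_off
  list(on_step = step_at(t_on), off_step = step_at(t_off),
       time_to_peak = t[on_epoch][which.max(v[on_epoch])] - t_on)
}

#' Exponential decay constant of the flash response
#'
#' Least-squares fit of A * exp(b * t) to the response decay after light
#' onset; the fit window runs from the ON-peak time (default) or from
#' onset to \code{t_on + fit_horizon}. The rate is reported only if
#' negative (a non-negative fit marks a noisy/non-decaying response and
#' returns NA).
#'
#' @param trace a \code{response_trace} or numeric vector
#' @param t_on light onset in seconds
#' @param rate sampling rate (bare vectors)
#' @param fit_horizon window end, seconds after onset
#' @param anchor \code{"peak"} (fit starts at the post-onset maximum) or
#'   \code{"onset"}
#' @return decay rate b (1/s, negative) or NA
#' @export
fit_decay_constant <- function(trace, t_on, rate = NULL, fit_horizon = 3,
                               anchor = c("peak", "onset")) {
  anchor <- match.arg(anchor)
  tr <- as_trace(trace, rate)
  t <- tr$time; v <- tr$values
  upto <- t_on + fit_horizon
  win <- t >= t_on & t <= upto
  if (sum(win) < 5) stop("fewer than 5 samples in the decay-fit window",
                         call. = FALSE)
  t_start <- if (anchor == "peak") t[win][which.max(v[win])] else t_on
  sel <- t >= t_start & t <= upto
  if (sum(sel) < 5) {
    # peak at the window's end: the trace is still rising, nothing decays
    message("response does not decay within the fit window; returning NA")
    return(NA_real_)
  }
  ts <- t[sel] - t_start; vs <- v[sel]
  # log-linear start when feasible, else crude endpoint slope
  b0 <- if (all(vs > 0)) unname(stats::coef(stats::lm(log(vs) ~ ts))[2])
        else (vs[length(vs)] - vs[1]) / (max(ts) * max(abs(vs), 1))
  if (!is.finite(b0)) b0 <- -1
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(vs ~ A * exp(b * ts),
                 start = list(A = vs[1], b = b0),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    message("decay fit did not converge; returning NA")
    return(NA_real_)
  }
  b <- unname(stats::coef(fit)["b"])
  if (is.finite(b) && b < 0) b else NA_real_
}

#' Direction tuning from per-direction responses
#'
#' The circular tuning statistic L_dir = |sum_k R(theta_k) exp(i theta_k)
#' / sum_k R(theta_k)|: the response-weighted resultant of unit vectors
#' at the stimulus directions. Its magnitude (1 minus the circular
#' variance) measures tuning sharpness and its angle the preferred
#' direction. Negative responses are clipped to 0 before the vector sum.
#' DSI = (PD - ND)/PD is also reported from the peak responses.
#'
#' @param responses per-direction responses R(theta_k) (dF/F)
#' @param angles_deg direction angles theta_k in degrees
#' @return list: ldir_magnitude, tuning_angle (deg, [0, 360)), dsi,
#'   responses (clipped), angles_deg; or NULL if all responses are <= 0
#' @export
direction_tuning <- function(responses, angles_deg) {
  if (length(responses) < 2 || length(responses) != length(angles_deg))
    stop("need >= 2 aligned responses and angles", call. = FALSE)
  if (!all(is.finite(responses))) stop("non-finite responses", call. = FALSE)
  R <- pmax(responses, 0)
  if (sum(R) == 0) {
    message("all responses <= 0: tuning undefined")
    return(NULL)
  }
  z <- sum(R * exp(1i * angles_deg * pi / 180)) / sum(R)
  pd_i <- which.max(R)
  nd_angle <- (angles_deg[pd_i] + 180) %% 360
  d <- abs(angles_deg - nd_angle)
  nd_i <- which.min(pmin(d, 360 - d))
  list(ldir_magnitude = Mod(z),
       tuning_angle = (Arg(z) * 180 / pi) %% 360,
       dsi = (R[pd_i] - R[nd_i]) / R[pd_i],
       responses = R, angles_deg = angles_deg)
}

#' @noRd
as_trace <- function(trace, rate) {
  if (inherits(trace, "response_trace")) return(trace)
  if (is.null(rate)) stop("`rate` required for a bare vector", call. = FALSE)
  list(values = as.numeric(trace),
       time = (seq_along(trace) - 1) / rate, rate = rate)
}
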