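#' Aggregate turning traces across epochs and flies
#'
#' Velocities in the direction of stimulus motion are positive:
#' responses to leftward epochs are sign-inverted and pooled with the
#' rightward ones, then trial-averaged per fly on a window aligned to
#' motion onset. Flies with mean forward speed below \code{min_forward}
#' or with negative mean signed turning over the motion windows
#' (turning against the stimulus) are rejected, with reasons logged.
#'
#' @param recordings list of \code{behavior_recording}s
#' @param min_forward forward-speed threshold in mm/s
#' @param window_s aligned-window length in seconds (default: longest
#'   motion epoch + 0.25 s)
#' @return list: \code{traces} (matrix fly x samples of trial-averaged
#'   signed yaw), \code{time} (s from motion onset), \code{fly_ids},
#'   \code{rejections} (data.frame fly_id, reason)
#' @export
aggregate_turning <- function(recordings, min_forward = 3,
                              window_s = NULL) {
  if (!length(recordings)) stop("no recordings", call. = FALSE)
  rate <- recordings[[1]]$sample_rate
  ep0 <- recordings[[1]]$epochs
  window_s <- window_s %||% (max(ep0$t_end - ep0$t_start) + 0.25)
  len <- floor(window_s * rate)
  rej <- list(); rows <- list(); ids <- c()
  for (rec in recordings) {
    ep <- rec$epochs
    # signed yaw: positive = with the stimulus
    signed <- lapply(seq_len(nrow(ep)), function(e) {
      i0 <- round(ep$t_start[e] * rate) + 1
      ep$direction[e] * rec$yaw[i0:(i0 + len - 1)]
    })
    mat <- do.call(rbind, signed)
    motion_mean <- mean(vapply(seq_len(nrow(ep)), function(e) {
      i0 <- round(ep$t_start[e] * rate) + 1
      i1 <- round(ep$t_end[e] * rate)
      mean(ep$direction[e] * rec$yaw[i0:i1])
    }, 0))
    if (mean(rec$forward) < min_forward) {
      rej[[length(rej) + 1L]] <- data.frame(fly_id = rec$fly_id,
                                            reason = "forward")
    } else if (motion_mean < 0) {
      rej[[length(rej) + 1L]] <- data.frame(fly_id = rec$fly_id,
                                            reason = "opposite_turning")
    } else {
      rows[[length(rows) + 1L]] <- colMeans(mat)
      ids <- c(ids, rec$fly_id)
    }
  }
  if (!length(rows))
    stop("no flies survive quality control", call. = FALSE)
  rejections <- if (length(rej)) do.call(rbind, rej)
    else data.frame(fly_id = integer(0), reason = character(0))
  list(traces = do.call(rbind, rows),
       time = (seq_len(len) - 1) / rate,
       fly_ids = ids, rejections = rejections, sample_rate = rate)
}

#' Slope of the declining phase of the turning response
#'
#' Ordinary least-squares slope of the trial-averaged yaw trace over a
#' window after motion onset (0.45-0.75 s by default), the statistic
#' used to compare how fast the turning response declines.
#'
#' @param trace trial-averaged yaw vector aligned to motion onset
#' @param rate sampling rate in Hz
#' @param window \code{c(t0, t1)} seconds from motion onset
#' @return slope in velocity units per second
#' @export
deceleration_slope <- function(trace, rate, window = c(0.45, 0.75)) {
  t <- (seq_along(trace) - 1) / rate
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 3) stop("fewer than 3 samples in the slope window",
                         call. = FALSE)
  unname(stats::coef(stats::lm(trace[sel] ~ t[sel]))[2])
}

#' Percent recovery between paired edges
#'
#' V_peak is the mean of the \code{n_extreme} highest trial-averaged
#' instantaneous yaw velocities over the first edge [0, D]; V_lowest is
#' the mean of the \code{n_extreme} lowest velocities over the first
#' 0.25 s of the second edge [D, D + 0.25]. Percent recovery =
#' (V_peak - V_lowest) / V_peak x 100, computed per fly before any
#' cross-fly averaging.
#'
#' @param trace trial-averaged yaw vector aligned to the first-edge
#'   onset
#' @param rate sampling rate in Hz
#' @param edge_duration D in seconds (0.75 or 0.5)
#' @param n_extreme number of extreme samples averaged
#' @param dip_window_s length of the V_lowest window in seconds
#' @return list: v_peak, v_lowest, percent_recovery, windows; NULL (with
#'   a message) if v_peak <= 0
#' @export
percent_recovery <- function(trace, rate, edge_duration = 0.75,
                             n_extreme = 8, dip_window_s = 0.25) {
  t <- (seq_along(trace) - 1) / rate
  peak_win <- trace[t >= 0 & t < edge_duration]
  dip_win <- trace[t >= edge_duration & t < edge_duration + dip_window_s]
  if (length(peak_win) < n_extreme || length(dip_win) < n_extreme)
    stop("too few samples for the extreme-value windows", call. = FALSE)
  v_peak <- mean(sort(peak_win, decreasing = TRUE)[seq_len(n_extreme)])
  v_lowest <- mean(sort(dip_win)[seq_len(n_extreme)])
  if (v_peak <= 0) {
    message("non-positive V_peak; recovery undefined, fly excluded")
    return(NULL)
  }
  list(v_peak = v_peak, v_lowest = v_lowest,
       percent_recovery = (v_peak - v_lowest) / v_peak * 100,
       windows = c(peak = edge_duration, dip = dip_window_s))
}

#' Cohort percent recovery
#'
#' Applies \code{\link{percent_recovery}} to each fly's trial-averaged
#' trace and returns the per-fly values (the unit on which group
#' statistics are computed).
#'
#' @param aggregated output of \code{\link{aggregate_turning}}
#' @param edge_duration,n_extreme,dip_window_s see
#'   \code{\link{percent_recovery}}
#' @return data.frame: fly_id, v_peak, v_lowest, percent_recovery
#' @export
cohort_recovery <- function(aggregated, edge_duration = 0.75,
                            n_extreme = 8, dip_window_s = 0.25) {
  out <- lapply(seq_len(nrow(aggregated$traces)), function(i) {
    r <- percent_recovery(aggregated$traces[i, ], aggregated$sample_rate,
                          edge_duration, n_extreme, dip_window_s)
    if (is.null(r)) return(NULL)
    data.frame(fly_id = aggregated$fly_ids[i], v_peak = r$v_peak,
               v_lowest = r$v_lowest, percent_recovery = r$percent_recovery)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Two-control significance test
#'
#' Two independent two-tailed Student's t tests (pooled variance) of the
#' experimental per-fly values against each genetic control; the
#' difference counts as significant only when the experimental group
#' differs from both controls at \code{alpha}.
#'
#' @param experimental,control1,control2 per-fly values
#' @param alpha significance level
#' @return list: significant (logical), p (named vector), alpha
#' @export
controls_ttest <- function(experimental, control1, control2, alpha = 0.05) {
  for (g in list(experimental, control1, control2))
    if (length(g) < 2) stop("need >= 2 flies per group", call. = FALSE)
  pooled_p <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) return(1)    # identical constants: no evidence
      stop("zero variance in both groups with different means: t test undefined",
           call. = FALSE)
    }
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  p1 <- pooled_p(experimental, control1)
  p2 <- pooled_p(experimental, control2)
  list(significant = is.finite(p1) && is.finite(p2) &&
         p1 < alpha && p2 < alpha,
       p = c(control1 = p1, control2 = p2), alpha = alpha)
}
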