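#' Turning-response kernel
#'
#' Impulse response of the fly's turning to a moving-edge onset. The
#' \code{"control"} kernel is a compact-support raised-cosine bump
#' (onset latency then a bump of \code{width} seconds) that genuinely
#' returns to zero, emulating a fast-decaying optomotor response; the
#' \code{"sustained"} kernel shares the rise but decays with a long
#' exponential tail, emulating the slowed response decline seen when
#' feedback neurons are silenced.
#'
#' @param type \code{"control"} or \code{"sustained"}
#' @param rate sampling rate in Hz
#' @param latency response latency in seconds
#' @param width bump width in seconds (control support = latency + width)
#' @param tail_tau sustained-tail time constant in seconds
#' @param amplitude peak yaw velocity (deg/s)
#' @param span kernel length in seconds
#' @return numeric vector of kernel samples at \code{rate}
#' @export
turning_kernel <- function(type = c("control", "sustained"), rate = 120,
                           latency = 0.1, width = 0.5, tail_tau = 1.5,
                           amplitude = 20, span = 6) {
  type <- match.arg(type)
  t <- seq(0, span - 1 / rate, by = 1 / rate)
  u <- (t - latency) / width
  bump <- ifelse(u > 0 & u < 1, sin(pi * u)^2, 0)
  if (type == "sustained") {
    t_peak <- latency + width / 2
    tail <- ifelse(t > t_peak, exp(-(t - t_peak) / tail_tau), 0)
    k <- pmax(bump, tail)
  } else {
    k <- bump
  }
  amplitude * k
}

#' Epoch design for treadmill experiments
#'
#' Builds the epoch table for open-loop edge experiments: single ON edges
#' (0.75 s at 192 deg/s) or paired ON edges presented back-to-back
#' (2 x 0.75 s or 2 x 0.5 s at 240 deg/s), interleaved with 1.5 s dark
#' screens and alternating mirror-symmetric directions (+1 rightward,
#' -1 leftward).
#'
#' @param kind \code{"single"} or \code{"paired"}
#' @param edge_duration duration of one edge in seconds (0.75 or 0.5)
#' @param n_epochs number of motion epochs (even, to balance directions)
#' @param dark_s dark interleave duration in seconds
#' @return data.frame: epoch, t_start, t_end, direction (+1/-1), kind,
#'   with attribute \code{edge_onsets} (list of per-epoch edge onset
#'   times) and \code{edge_duration}
#' @export
behavior_epoch_design <- function(kind = c("single", "paired"),
                                  edge_duration = 0.75, n_epochs = 40,
                                  dark_s = 1.5) {
  kind <- match.arg(kind)
  n_edges <- if (kind == "paired") 2L else 1L
  motion_s <- n_edges * edge_duration
  starts <- dark_s + (seq_len(n_epochs) - 1) * (motion_s + dark_s)
  ep <- data.frame(
    epoch = seq_len(n_epochs),
    t_start = starts,
    t_end = starts + motion_s,
    direction = rep(c(1, -1), length.out = n_epochs),
    kind = kind
  )
  attr(ep, "edge_onsets") <- lapply(starts, function(s)
    s + (seq_len(n_edges) - 1) * edge_duration)
  attr(ep, "edge_duration") <- edge_duration
  ep
}

#' Simulate treadmill turning traces for a fly cohort
#'
#' yaw(t) = direction x sum over edge onsets of kernel(t - onset) + noise;
#' forward speed is drawn per fly, with configurable fractions of planted
#' quality-control violators (slow walkers below 3 mm/s, flies turning
#' against the stimulus).
#'
#' @param kernel turning kernel vector at \code{sample_rate} (see
#'   \code{\link{turning_kernel}})
#' @param epochs epoch table from \code{\link{behavior_epoch_design}}
#' @param n_flies cohort size
#' @param sample_rate sampling rate in Hz
#' @param noise_sd yaw noise standard deviation (deg/s)
#' @param forward_range range of per-fly mean forward speed (mm/s)
#' @param frac_slow fraction of flies planted with forward speed below
#'   3 mm/s
#' @param frac_opposite fraction of flies planted turning against the
#'   stimulus (negated kernel)
#' @param genotype label stored on each recording
#' @param seed integer seed
#' @return list of \code{behavior_recording}s: yaw, forward,
#'   sample_rate, epochs, fly_id, genotype, and planted flags
#'   \code{planted_slow}, \code{planted_opposite}
#' @export
simulate_turning_traces <- function(kernel, epochs, n_flies = 10,
                                    sample_rate = 120, noise_sd = 0,
                                    forward_range = c(6, 14),
                                    frac_slow = 0, frac_opposite = 0,
                                    genotype = "control", seed = NULL) {
  onsets <- attr(epochs, "edge_onsets")
  total_s <- max(epochs$t_end) + 2
  n <- round(total_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  with_seed(seed, {
    n_slow <- round(frac_slow * n_flies)
    n_opp <- round(frac_opposite * n_flies)
    slow_ids <- sample(n_flies, n_slow)
    opp_ids <- sample(setdiff(seq_len(n_flies), slow_ids), n_opp)
    lapply(seq_len(n_flies), function(f) {
      sign_f <- if (f %in% opp_ids) -1 else 1
      yaw <- numeric(n)
      for (e in seq_len(nrow(epochs))) {
        for (on in onsets[[e]]) {
          i0 <- round(on * sample_rate) + 1
          idx <- i0:min(n, i0 + length(kernel) - 1)
          yaw[idx] <- yaw[idx] + epochs$direction[e] * kernel[seq_along(idx)]
        }
      }
      yaw <- sign_f * yaw
      if (noise_sd > 0) yaw <- yaw + stats::rnorm(n, sd = noise_sd)
      fwd_mean <- if (f %in% slow_ids) stats::runif(1, 0.5, 2.5)
                  else stats::runif(1, forward_range[1], forward_range[2])
      forward <- rep(fwd_mean, n)
      if (noise_sd > 0) forward <- forward + stats::rnorm(n, sd = noise_sd / 4)
      structure(list(yaw = yaw, forward = forward,
                     sample_rate = sample_rate, epochs = epochs,
                     fly_id = f, genotype = genotype,
                     planted_slow = f %in% slow_ids,
                     planted_opposite = f %in% opp_ids),
                class = "behavior_recording")
    })
  })
}

#' Write / read behavior recordings as CSV pairs
#'
#' Trace CSV columns: time_s, yaw, forward. Epoch CSV columns: t_start,
#' t_end, direction, kind.
#'
#' @param rec a \code{behavior_recording}
#' @param trace_path,epoch_path output files
#' @export
write_behavior_csv <- function(rec, trace_path, epoch_path) {
  n <- length(rec$yaw)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate,
                              yaw = rec$yaw, forward = rec$forward),
                   trace_path, row.names = FALSE)
  utils::write.csv(rec$epochs[, c("t_start", "t_end", "direction", "kind")],
                   epoch_path, row.names = FALSE)
  invisible(trace_path)
}

#' @rdname write_behavior_csv
#' @param sample_rate sampling rate of the stored trace in Hz
#' @param fly_id,genotype metadata to attach
#' @export
read_behavior_csv <- function(trace_path, epoch_path, sample_rate = 120,
                              fly_id = NA, genotype = NA_character_) {
  tr <- utils::read.csv(trace_path)
  ep <- utils::read.csv(epoch_path)
  structure(list(yaw = tr$yaw, forward = tr$forward,
                 sample_rate = sample_rate, epochs = ep,
                 fly_id = fly_id, genotype = genotype,
                 planted_slow = NA, planted_opposite = NA),
            class = "behavior_recording")
}
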