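#' Fractional fluorescence change (dF/F)
#'
#' Computes dF/F = (F - F0) / F0 after background subtraction, with the
#' three baseline conventions used in this pipeline: F0 from a
#' pre-stimulus (non-stimulus) epoch, from the whole-trace mean, or from
#' gray-interleave epochs of a noise stimulus.
#'
#' @param F raw fluorescence vector
#' @param rate sampling rate in Hz
#' @param background background signal to subtract (scalar or vector)
#' @param f0_mode one of \code{"prestim_epoch"},
#'   \code{"whole_trace_mean"}, \code{"gray_interleaves"}
#' @param epochs epoch table (t_start, t_end, ...) — required for
#'   \code{prestim_epoch} (baseline = samples before the first epoch
#'   start, or within \code{prestim_window}) and
#'   \code{gray_interleaves} (rows with \code{kind == "gray"})
#' @param prestim_window optional \code{c(t0, t1)} seconds overriding the
#'   default pre-stimulus window
#' @param trace_name label used in error messages
#' @return a \code{response_trace}: list(values, time, rate, f0, f0_mode)
#' @export
compute_dff <- function(F, rate, background = 0,
                        f0_mode = c("whole_trace_mean", "prestim_epoch",
                                    "gray_interleaves"),
                        epochs = NULL, prestim_window = NULL,
                        trace_name = "trace") {
  f0_mode <- match.arg(f0_mode)
  assert_positive(rate, "rate")
  Fb <- F - background
  time <- (seq_along(Fb) - 1) / rate
  f0 <- switch(f0_mode,
    whole_trace_mean = mean(Fb),
    prestim_epoch = {
      win <- prestim_window %||% {
        if (is.null(epochs)) stop("prestim_epoch mode needs `epochs` or `prestim_window`",
                                  call. = FALSE)
        c(0, min(epochs$t_start))
      }
      idx <- time >= win[1] & time < win[2]
      if (!any(idx)) stop("empty pre-stimulus window", call. = FALSE)
      mean(Fb[idx])
    },
    gray_interleaves = {
      if (is.null(epochs)) stop("gray_interleaves mode needs `epochs`",
                                call. = FALSE)
      gray <- epochs[epochs$kind == "gray", , drop = FALSE]
      if (nrow(gray) == 0) stop("no gray epochs in epoch table", call. = FALSE)
      idx <- Reduce(`|`, lapply(seq_len(nrow(gray)), function(i)
        time >= gray$t_start[i] & time < gray$t_end[i]))
      mean(Fb[idx])
    })
  if (!is.finite(f0) || f0 <= 0)
    stop(sprintf("degenerate baseline (F0 = %g) for %s", f0, trace_name),
         call. = FALSE)
  structure(list(values = (Fb - f0) / f0, time = time, rate = rate,
                 f0 = f0, f0_mode = f0_mode),
            class = "response_trace")
}

#' Resample a trace onto a uniform grid
#'
#' Linear interpolation onto a grid at \code{target_rate} spanning the
#' original support; \code{extrapolate_hold} repeats edge values outside
#' the support (used when extrapolating imaging traces to the 20 Hz
#' stimulus update rate).
#'
#' @param trace a \code{response_trace} or numeric vector
#' @param target_rate target rate in Hz
#' @param mode \code{"interpolate"} (grid confined to the support) or
#'   \code{"extrapolate_hold"}
#' @param rate original rate, if \code{trace} is a bare vector
#' @param span optional total duration in seconds for
#'   \code{extrapolate_hold} (defaults to the original span)
#' @return a \code{response_trace} at \code{target_rate} (metadata field
#'   \code{resample_mode} records the mode)
#' @export
resample_trace <- function(trace, target_rate,
                           mode = c("interpolate", "extrapolate_hold"),
                           rate = NULL, span = NULL) {
  mode <- match.arg(mode)
  assert_positive(target_rate, "target_rate")
  if (inherits(trace, "response_trace")) {
    x <- trace$time; y <- trace$values
  } else {
    if (is.null(rate)) stop("`rate` required for a bare vector", call. = FALSE)
    y <- as.numeric(trace); x <- (seq_along(y) - 1) / rate
  }
  if (length(y) < 2) stop("need >= 2 samples to resample", call. = FALSE)
  span <- span %||% (max(x) - min(x))
  new_t <- min(x) + seq(0, span, by = 1 / target_rate)
  out <- stats::approx(x, y, xout = new_t, method = "linear", rule = 2)$y
  structure(list(values = out, time = new_t, rate = target_rate,
                 resample_mode = mode),
            class = "response_trace")
}

#' Trial averaging with the per-ROI, per-fly hierarchy
#'
#' Averages aligned repeats elementwise; with grouping vectors the
#' averaging proceeds repeats -> ROIs within fly -> flies, the order used
#' before population summaries.
#'
#' @param traces numeric matrix, one row per repeat (aligned, equal
#'   length), or a list of equal-length vectors
#' @param roi,fly optional grouping vectors (length = number of rows):
#'   ROI id and fly id per trace
#' @return list: \code{mean} (averaged trace), \code{n} (named counts at
#'   each level)
#' @export
trial_average <- function(traces, roi = NULL, fly = NULL) {
  if (is.list(traces) && !is.data.frame(traces))
    traces <- do.call(rbind, traces)
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  if (nrow(traces) == 0) stop("no repeats to average", call. = FALSE)
  if (is.null(roi) && is.null(fly))
    return(list(mean = colMeans(traces), n = c(repeats = nrow(traces))))
  roi <- roi %||% rep(1L, nrow(traces))
  fly <- fly %||% rep(1L, nrow(traces))
  key <- paste(fly, roi, sep = "\r")
  # rowsum orders groups by sorted key; table() uses the same order
  roi_means <- rowsum(traces, key) / as.vector(table(key))
  roi_fly <- vapply(strsplit(rownames(roi_means), "\r"), `[`, "", 1)
  fly_counts <- as.vector(table(roi_fly))
  fly_means <- rowsum(roi_means, roi_fly) / fly_counts
  list(mean = colMeans(fly_means),
       n = c(repeats = nrow(traces), rois = nrow(roi_means),
             flies = nrow(fly_means)))
}

#' Slice and average repeats of an epoch from a trace
#'
#' Extracts equal-length windows aligned to each epoch start and averages
#' them (the per-pixel/ROI repeat average used throughout segmentation
#' and response quantification).
#'
#' @param values trace vector
#' @param rate sampling rate in Hz
#' @param starts epoch start times in seconds
#' @param duration window length in seconds
#' @return list: \code{mean} (averaged window), \code{repeats}
#'   (matrix repeats x samples)
#' @export
epoch_average <- function(values, rate, starts, duration) {
  len <- floor(duration * rate)
  reps <- t(vapply(starts, function(s) {
    i0 <- round(s * rate) + 1
    values[i0:(i0 + len - 1)]
  }, numeric(len)))
  list(mean = colMeans(reps), repeats = reps)
}
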