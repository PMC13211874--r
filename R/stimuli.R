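#' Ternary white-noise stimulus
#'
#' Generates the bar-noise stimulus used for receptive-field mapping: a
#' frame-by-bar matrix whose entries are drawn independently and uniformly
#' from \{-1, 0, 1\} (dark, gray, bright), each bar updating at
#' \code{update_rate}. The default geometry is 12 bars of 5 x 60 degrees
#' updating at 20 Hz for 500 s.
#'
#' @param n_bars number of bars (>= 1)
#' @param update_rate contrast update rate in Hz
#' @param duration stimulus duration in seconds
#' @param orientation \code{"horizontal"} or \code{"vertical"} (bar tilt)
#' @param bar_size bar dimensions in degrees, \code{c(width, length)}
#' @param seed integer seed for reproducibility
#' @return an object of class \code{ternary_noise}: list with \code{values}
#'   (\code{round(duration * update_rate)} x \code{n_bars} matrix in
#'   \{-1,0,1\}), \code{update_rate}, \code{orientation}, \code{bar_size},
#'   \code{seed}
#' @examples
#' tn <- make_ternary_noise(12, 20, 1, seed = 1)
#' dim(tn$values)
#' @export
make_ternary_noise <- function(n_bars, update_rate = 20, duration = 500,
                               orientation = c("horizontal", "vertical"),
                               bar_size = c(5, 60), seed = NULL) {
  orientation <- match.arg(orientation)
  if (!is.numeric(n_bars) || length(n_bars) != 1L || n_bars < 1)
    stop("`n_bars` must be >= 1", call. = FALSE)
  assert_positive(update_rate, "update_rate")
  assert_positive(duration, "duration")
  n_frames <- round(duration * update_rate)
  if (n_frames < 1) stop("duration * update_rate must be >= 1", call. = FALSE)
  vals <- with_seed(seed, {
    matrix(sample(c(-1, 0, 1), n_frames * n_bars, replace = TRUE),
           nrow = n_frames, ncol = n_bars)
  })
  structure(list(values = vals, update_rate = update_rate,
                 orientation = orientation, bar_size = bar_size, seed = seed),
            class = "ternary_noise")
}

#' Stimulus specification
#'
#' Bundles the parameters of a visual stimulus epoch sequence. Angles are
#' counterclockwise with 0 degrees = rightward motion, used consistently
#' throughout the package.
#'
#' @param kind one of \code{"flash"}, \code{"edge"}, \code{"bar"},
#'   \code{"ternary_noise"}, \code{"behavior_edge"}
#' @param duration total duration in seconds
#' @param frame_rate presentation rate in Hz
#' @param geometry bar width / edge extent in degrees
#' @param speed motion speed in degrees per second
#' @param directions motion directions in degrees, each in [0, 360)
#' @param contrast_values contrasts in [-1, 1]
#' @param n_repeats repeats per direction/contrast combination
#' @param seed integer seed for pseudo-random ordering
#' @return a \code{stimulus_spec} list
#' @export
stimulus_spec <- function(kind, duration, frame_rate,
                          geometry = 5, speed = 20,
                          directions = numeric(0),
                          contrast_values = c(-1, 1),
                          n_repeats = 1L, seed = NULL) {
  kind <- match.arg(kind,
                    c("flash", "edge", "bar", "ternary_noise", "behavior_edge"))
  assert_positive(duration, "duration")
  assert_positive(frame_rate, "frame_rate")
  if (length(directions) && (any(directions < 0) || any(directions >= 360)))
    stop("`directions` must lie in [0, 360)", call. = FALSE)
  if (any(abs(contrast_values) > 1))
    stop("`contrast_values` must lie in [-1, 1]", call. = FALSE)
  structure(list(kind = kind, duration = duration, frame_rate = frame_rate,
                 geometry = geometry, speed = speed, directions = directions,
                 contrast_values = contrast_values,
                 n_repeats = as.integer(n_repeats), seed = seed),
            class = "stimulus_spec")
}

# Screen geometry: rear-projection screen of ~80 deg azimuth x ~55 deg
# elevation, discretized at 1 deg/cell by default.
SCREEN_AZIMUTH <- 80
SCREEN_ELEVATION <- 55

#' Motion / flash stimulus with epoch timing table
#'
#' Builds the epoch table (and, for motion stimuli, a coarse space-time
#' luminance array) for flash, moving-edge and moving-bar stimuli. Flash
#' epochs alternate ON 5 s / OFF 5 s; edge and bar epochs present each
#' direction x contrast combination \code{n_repeats} times in a
#' pseudo-randomized (seeded uniform shuffle per repeat block) order.
#' Moving edges traverse the screen azimuth extent at \code{spec$speed}.
#'
#' @param spec a \code{stimulus_spec}
#' @param screen_extent screen extent along the motion axis in degrees
#' @param grid_step spatial discretization in degrees per cell
#' @return list with \code{epochs} (data.frame: epoch, t_start, t_end,
#'   direction_deg, contrast, kind) and, for \code{edge}/\code{bar} kinds,
#'   \code{luminance} (time x position matrix along the motion axis for the
#'   first epoch, as a rendering reference)
#' @export
make_motion_stimuli <- function(spec, screen_extent = SCREEN_AZIMUTH,
                                grid_step = 1) {
  stopifnot(inherits(spec, "stimulus_spec"))
  switch(spec$kind,
    flash = make_flash_epochs(spec),
    edge = ,
    bar = make_moving_epochs(spec, screen_extent, grid_step),
    behavior_edge = make_moving_epochs(spec, screen_extent, grid_step),
    stop(sprintf("unknown stimulus kind '%s'", spec$kind), call. = FALSE)
  )
}

make_flash_epochs <- function(spec, flash_s = 5) {
  n_epochs <- floor(spec$duration / (2 * flash_s))
  if (n_epochs < 1) stop("duration too short for one ON/OFF flash epoch",
                         call. = FALSE)
  starts <- (seq_len(2 * n_epochs) - 1) * flash_s
  epochs <- data.frame(
    epoch = seq_along(starts),
    t_start = starts,
    t_end = starts + flash_s,
    direction_deg = NA_real_,
    contrast = rep(c(1, -1), n_epochs),
    kind = rep(c("on", "off"), n_epochs)
  )
  list(epochs = epochs, luminance = NULL)
}

make_moving_epochs <- function(spec, screen_extent, grid_step) {
  if (!length(spec$directions))
    stop("moving stimuli need at least one direction", call. = FALSE)
  traversal <- screen_extent / spec$speed
  combos <- expand.grid(direction_deg = spec$directions,
                        contrast = spec$contrast_values)
  order_idx <- with_seed(spec$seed, {
    unlist(lapply(seq_len(spec$n_repeats),
                  function(i) sample.int(nrow(combos))))
  })
  n <- length(order_idx)
  starts <- (seq_len(n) - 1) * traversal
  epochs <- data.frame(
    epoch = seq_len(n),
    t_start = starts,
    t_end = starts + traversal,
    direction_deg = combos$direction_deg[order_idx],
    contrast = combos$contrast[order_idx],
    kind = spec$kind
  )
  # 1-D luminance profile along the motion axis for the first epoch: a
  # full-contrast edge (step) or bar (stripe of spec$geometry width)
  # advancing at spec$speed.
  pos <- seq(0, screen_extent, by = grid_step)
  times <- seq(0, traversal, by = 1 / spec$frame_rate)
  front <- times * spec$speed
  lum <- outer(front, pos, function(f, p) {
    if (spec$kind == "bar") as.numeric(p <= f & p > f - spec$geometry)
    else as.numeric(p <= f)
  }) * epochs$contrast[1]
  list(epochs = epochs, luminance = lum, traversal = traversal)
}
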