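#' Place square terminal footprints on a pixel grid
#'
#' Samples non-overlapping square pixel blocks (axon-terminal footprints)
#' with a minimum gap between block centers, for planting model neurons in
#' a rendered movie.
#'
#' @param n number of terminals
#' @param dim_px image size \code{c(height, width)} in pixels
#' @param side block side length in pixels (area = side^2 pixels)
#' @param min_gap_px minimum center-to-center distance in pixels
#' @param seed integer seed
#' @return list of n two-column matrices (x = column, y = row) of pixel
#'   coordinates
#' @export
place_terminals <- function(n, dim_px = c(48, 48), side = 3, min_gap_px = 8,
                            seed = NULL) {
  with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 2)
    half <- (side - 1) / 2
    tries <- 0
    while (nrow(centers) < n) {
      tries <- tries + 1
      if (tries > 20000)
        stop("could not place terminals without overlap; image too small",
             call. = FALSE)
      cand <- c(sample(seq(1 + ceiling(half), dim_px[2] - ceiling(half)), 1),
                sample(seq(1 + ceiling(half), dim_px[1] - ceiling(half)), 1))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_gap_px))
        centers <- rbind(centers, cand)
    }
    lapply(seq_len(n), function(i) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      offs <- seq(-floor(half), ceiling(half))
      as.matrix(expand.grid(x = cx + offs, y = cy + offs))
    })
  })
}

#' Render an imaging movie with planted model-neuron terminals
#'
#' Builds a fluorescence movie F(pixel, t) = baseline_f0 * (1 + dF/F of
#' the owning terminal) + Gaussian noise on terminal pixels, and
#' baseline_f0 + noise elsewhere; frames are clipped at 0. The planted
#' pixel sets, models and layer labels are stored as ground truth.
#'
#' @param models list of \code{neuron_model}s, one per terminal
#' @param placements list of pixel-coordinate matrices as returned by
#'   \code{\link{place_terminals}}; must be pairwise disjoint
#' @param stimulus stimulus accepted by \code{\link{simulate_ln_response}}
#' @param frame_rate acquisition rate in Hz
#' @param pixel_size micrometers per pixel
#' @param dim_px image size \code{c(height, width)}
#' @param baseline_f0 baseline fluorescence of terminal pixels (arbitrary
#'   units)
#' @param background_level fluorescence of non-terminal pixels (defaults
#'   to \code{baseline_f0}; set lower to emulate dark neuropil around
#'   bright terminals)
#' @param noise_sigma pixel noise standard deviation (fluorescence units)
#' @param layers layer labels (A-D) per terminal, or NA
#' @param seed integer seed for the noise
#' @return a \code{terminal_movie}: list with \code{frames}
#'   (H x W x T array), \code{frame_rate}, \code{pixel_size},
#'   \code{terminals} (list of pixels/model/layer/dff), \code{epochs}
#'   (stimulus epoch table if present), \code{baseline_f0},
#'   \code{noise_sigma}
#' @export
render_terminal_movie <- function(models, placements, stimulus,
                                  frame_rate = 15, pixel_size = 0.5,
                                  dim_px = c(48, 48), baseline_f0 = 100,
                                  background_level = baseline_f0,
                                  noise_sigma = 0, layers = NULL,
                                  seed = NULL) {
  if (length(models) != length(placements))
    stop("one placement per model required", call. = FALSE)
  if (length(placements) > 1) {
    keys <- lapply(placements, function(p) paste(p[, 1], p[, 2]))
    if (anyDuplicated(unlist(keys)) > 0)
      stop("terminal placements overlap", call. = FALSE)
  }
  layers <- layers %||% rep(NA_character_, length(models))
  dffs <- lapply(models, simulate_ln_response, stimulus = stimulus,
                 frame_rate = frame_rate, noise_sd = 0)
  n_t <- if (length(dffs)) length(dffs[[1]]$response) else
    round((if (inherits(stimulus, "ternary_noise"))
      nrow(stimulus$values) / stimulus$update_rate
      else max(stimulus$epochs$t_end)) * frame_rate) + 1
  frames <- array(background_level, dim = c(dim_px[1], dim_px[2], n_t))
  for (i in seq_along(models)) {
    px <- placements[[i]]
    trace <- baseline_f0 * (1 + dffs[[i]]$response)
    for (j in seq_len(nrow(px)))
      frames[px[j, 2], px[j, 1], ] <- trace
  }
  if (noise_sigma > 0) {
    frames <- frames + with_seed(seed,
      array(stats::rnorm(length(frames), sd = noise_sigma), dim = dim(frames)))
  }
  frames <- pmax(frames, 0)
  terminals <- lapply(seq_along(models), function(i) {
    list(pixels = placements[[i]], model = models[[i]], layer = layers[i],
         area_um2 = nrow(placements[[i]]) * pixel_size^2,
         dff = dffs[[i]]$response)
  })
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size, terminals = terminals,
                 epochs = if (!inherits(stimulus, "ternary_noise"))
                   stimulus$epochs else NULL,
                 baseline_f0 = baseline_f0, noise_sigma = noise_sigma,
                 seed = seed),
            class = "terminal_movie")
}

#' Write / read a movie as multi-page TIFF
#'
#' Frames are scaled to [0, 1] by \code{scale_max} for storage (TIFF
#' float precision retained).
#'
#' @param movie a \code{terminal_movie} or plain H x W x T array
#' @param path output file
#' @param scale_max intensity mapped to 1.0 in the file
#' @return \code{path}, invisibly
#' @export
write_movie_tiff <- function(movie, path, scale_max = NULL) {
  frames <- if (inherits(movie, "terminal_movie")) movie$frames else movie
  scale_max <- scale_max %||% max(frames)
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(t) frames[, , t] / scale_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale_max = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                             length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * scale_max
  frames
}
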