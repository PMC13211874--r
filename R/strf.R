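#' Spatiotemporal receptive field by reverse correlation
#'
#' The response-weighted stimulus average: for each lag tau (0 ..
#' n_lags - 1, where n_lags = window x update rate, 2 s by default) and
#' bar b,
#' \deqn{STRF[\tau, b] = \frac{1}{T - \tau} \sum_{t = \tau + 1}^{T}
#'   r_t \, s_{t - \tau, b},}
#' with the response mean-centered first. Under white-noise stimulation
#' this recovers the linear filter of an LN cascade up to the stimulus
#' variance.
#'
#' @param response response trace at the noise update rate (vector or
#'   \code{response_trace}); centered around its mean internally
#' @param noise a \code{ternary_noise} aligned with the response
#' @param window filter length in seconds (2 s -> 40 lags at 20 Hz)
#' @param cell_id optional label
#' @return an object of class \code{strf}: list(weights
#'   [n_lags x n_bars], lag_step, orientation, r2 = NA, cell_id)
#' @export
reverse_correlate <- function(response, noise, window = 2, cell_id = NA) {
  r <- if (inherits(response, "response_trace")) response$values
       else as.numeric(response)
  s <- noise$values
  if (length(r) != nrow(s))
    stop("response and stimulus are not aligned (length mismatch)",
         call. = FALSE)
  n_lags <- round(window * noise$update_rate)
  T_ <- length(r)
  if (T_ <= n_lags)
    stop("response shorter than the correlation window", call. = FALSE)
  r <- r - mean(r)
  w <- matrix(0, n_lags, ncol(s))
  for (tau in 0:(n_lags - 1)) {
    w[tau + 1, ] <- colSums(r[(tau + 1):T_] * s[1:(T_ - tau), , drop = FALSE]) /
      (T_ - tau)
  }
  structure(list(weights = w, lag_step = 1 / noise$update_rate,
                 orientation = noise$orientation, r2 = NA_real_,
                 cell_id = cell_id),
            class = "strf")
}

#' Linear prediction from an STRF
#'
#' prediction(t) = sum over lags and bars of weights[tau, b] *
#' s[t - tau, b], defined for t past the first full window.
#'
#' @param strf an \code{strf}
#' @param noise the \code{ternary_noise} stimulus
#' @return list: \code{prediction}, \code{valid_idx} (time indices of the
#'   prediction within the stimulus)
#' @export
strf_predict <- function(strf, noise) {
  s <- noise$values
  n_lags <- nrow(strf$weights)
  T_ <- nrow(s)
  if (T_ < n_lags) stop("stimulus shorter than the filter", call. = FALSE)
  pred <- numeric(T_ - n_lags + 1)
  for (b in seq_len(ncol(s))) {
    E <- stats::embed(s[, b], n_lags)     # row t: s[t], s[t-1], ..., s[t-n_lags+1]
    pred <- pred + as.numeric(E %*% strf$weights[, b])
  }
  list(prediction = pred, valid_idx = n_lags:T_)
}

#' Prediction R-squared of an STRF
#'
#' The STRF is convolved with the stimulus and the prediction is
#' correlated with the measured response over the valid range (first
#' window discarded); R^2 is the squared Pearson correlation. Used with
#' the 0.26 threshold to discard receptive fields that do not predict
#' their cell's response.
#'
#' @param strf an \code{strf}
#' @param noise the \code{ternary_noise} stimulus
#' @param response measured response (vector or \code{response_trace})
#' @return r2 in [0, 1] (0, with a warning, if prediction or response
#'   has zero variance)
#' @export
strf_prediction_r2 <- function(strf, noise, response) {
  r <- if (inherits(response, "response_trace")) response$values
       else as.numeric(response)
  if (length(r) != nrow(noise$values))
    stop("response and stimulus are not aligned (length mismatch)",
         call. = FALSE)
  p <- strf_predict(strf, noise)
  rv <- r[p$valid_idx]
  if (stats::sd(p$prediction) == 0 || stats::sd(rv) == 0) {
    warning("zero-variance prediction or response; R^2 set to 0")
    return(0)
  }
  stats::cor(p$prediction, rv)^2
}

#' R^2-weighted average STRF
#'
#' STRFs below \code{r2_min} are discarded; survivors are averaged with
#' weights proportional to their R^2, optionally after shifting each
#' along the bar axis so its maximal-|weight| bar sits at the center bar
#' (zero-padded), the alignment used for population-average receptive
#' fields.
#'
#' @param strfs list of \code{strf}s with their \code{r2} fields set
#' @param r2_min validity threshold
#' @param align center each STRF on its peak bar before averaging
#' @return an \code{strf} (attribute \code{n_used} = survivor count), or
#'   NULL if none survive
#' @export
weighted_average_strf <- function(strfs, r2_min = 0.26, align = FALSE) {
  r2 <- vapply(strfs, function(s) s$r2, 0)
  keep <- which(is.finite(r2) & r2 >= r2_min)
  if (!length(keep)) {
    message(sprintf("0 of %d STRFs pass R^2 >= %g", length(strfs), r2_min))
    return(NULL)
  }
  mats <- lapply(strfs[keep], function(s) {
    w <- s$weights
    if (align) {
      n_bars <- ncol(w)
      center <- ceiling((n_bars + 1) / 2)
      peak_bar <- which.max(apply(abs(w), 2, max))
      shift <- center - peak_bar
      out <- matrix(0, nrow(w), n_bars)
      src <- seq_len(n_bars)
      dst <- src + shift
      ok <- dst >= 1 & dst <= n_bars
      out[, dst[ok]] <- w[, src[ok]]
      out
    } else w
  })
  wts <- r2[keep] / sum(r2[keep])
  avg <- Reduce(`+`, Map(`*`, mats, wts))
  out <- strfs[[keep[1]]]
  out$weights <- avg
  out$r2 <- mean(r2[keep])
  out$cell_id <- "weighted_average"
  attr(out, "n_used") <- length(keep)
  out
}

#' Temporal filter of an STRF and its ON-peak time
#'
#' \code{center_bar} mode returns the time course at the maximal-|weight|
#' bar (the slice also used for the spatial fit); \code{bar_average}
#' returns the mean over bars. The ON-peak time is the lag of the
#' maximal positive correlation times the lag step.
#'
#' @param strf an \code{strf}
#' @param mode \code{"center_bar"} or \code{"bar_average"}
#' @return list: values (over lags), on_peak_time (s; NA with a warning
#'   if the filter has no positive part), mode
#' @export
temporal_filter_metrics <- function(strf, mode = c("center_bar",
                                                   "bar_average")) {
  mode <- match.arg(mode)
  w <- strf$weights
  values <- if (mode == "center_bar") {
    w[, which.max(apply(abs(w), 2, max))]
  } else rowMeans(w)
  if (max(values) <= 0) {
    warning("temporal filter has no positive lobe; ON peak undefined")
    on_peak <- NA_real_
  } else {
    on_peak <- (which.max(values) - 1) * strf$lag_step
  }
  list(values = values, on_peak_time = on_peak, mode = mode)
}

#' Spatial profile and Gaussian FWHM of an STRF
#'
#' Takes the spatial slice at the lag of the global maximal |weight|,
#' fits a Gaussian a * exp(-(x - mu)^2 / (2 sigma^2)) in degree
#' coordinates (bar centers at \code{bar_width} spacing), and reports
#' FWHM = 2 sqrt(2 ln 2) sigma. Profiles narrower than one bar are
#' flagged sub-resolution.
#'
#' @param strf an \code{strf}
#' @param bar_width bar width in degrees
#' @return list: values (slice), degrees (bar centers), fwhm (deg; NA
#'   with a message on fit failure), amplitude, center, sigma,
#'   sub_resolution flag
#' @export
spatial_fwhm <- function(strf, bar_width = 5) {
  w <- strf$weights
  if (ncol(w) < 4) stop("need >= 4 bars for a spatial fit", call. = FALSE)
  peak <- which(abs(w) == max(abs(w)), arr.ind = TRUE)[1, ]
  slice <- w[peak[1], ]
  if (slice[peak[2]] < 0) slice <- -slice   # fit the dominant lobe upright
  x <- (seq_along(slice) - 0.5) * bar_width
  a0 <- max(slice)
  mu0 <- x[which.max(slice)]
  pos <- pmax(slice, 0)
  s0 <- sqrt(max(sum(pos * (x - mu0)^2) / sum(pos), (bar_width / 4)^2))
  # warnOnly keeps the best iterate on zero-residual (exact) slices,
  # where nls cannot shrink the convergence criterion further
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(slice ~ a * exp(-(x - mu)^2 / (2 * sigma^2)),
                 start = list(a = a0, mu = mu0, sigma = s0),
                 control = stats::nls.control(warnOnly = TRUE,
                                              maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    message("spatial Gaussian fit failed; FWHM unavailable")
    return(list(values = slice, degrees = x, fwhm = NA_real_,
                amplitude = NA_real_, center = NA_real_, sigma = NA_real_,
                sub_resolution = NA))
  }
  cf <- stats::coef(fit)
  sigma <- abs(unname(cf["sigma"]))
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  list(values = slice, degrees = x, fwhm = fwhm,
       amplitude = unname(cf["a"]), center = unname(cf["mu"]),
       sigma = sigma, sub_resolution = fwhm <= bar_width)
}

#' Keep only contrast-selective pixels for receptive-field mapping
#'
#' Convenience pre-filter: pixels (or clusters) whose CSI does not exceed
#' \code{csi_min} are excluded from STRF estimation; values are never
#' altered, rows are only removed.
#'
#' @param features table with a \code{csi} column
#' @param csi_min exclusive threshold (keep csi > csi_min)
#' @return filtered table
#' @export
csi_filter <- function(features, csi_min = 0.5) {
  features[features$csi > csi_min, , drop = FALSE]
}
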