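#' Otsu threshold over a 256-bin histogram
#'
#' Threshold maximizing between-class variance over \code{n_bins}
#' equal-width bins spanning the observed range; ties are broken by the
#' lowest qualifying bin edge. Returned value is the upper edge of the
#' last background bin: values strictly greater are foreground.
#'
#' @param values numeric sample (e.g. image intensities)
#' @param n_bins number of histogram bins
#' @return threshold intensity
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || diff(rng) == 0)
    stop("degenerate image: constant intensity", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                     n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  p <- h / sum(h)
  omega <- cumsum(p)                       # background weight per cut
  mu <- cumsum(p * mids)                   # background first moment
  mu_total <- mu[n_bins]
  # between-class variance for a cut after each bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1)
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- ifelse(denom > 0, (mu_total * omega[k] - mu[k])^2 / denom, -Inf)
  best <- which.max(sigma_b)               # which.max takes the first tie
  edges[best + 1]
}

#' Foreground mask from the time-averaged image
#'
#' The movie's time-mean image is Gaussian filtered (sigma = 1.5 px) and
#' thresholded with \code{\link{otsu_threshold}}; pixels above threshold
#' are foreground.
#'
#' @param movie a \code{terminal_movie} or H x W x T array
#' @param sigma Gaussian smoothing sigma in pixels
#' @return logical H x W matrix
#' @export
foreground_mask <- function(movie, sigma = 1.5) {
  frames <- if (inherits(movie, "terminal_movie")) movie$frames else movie
  if (length(frames) == 0) stop("empty movie", call. = FALSE)
  avg <- apply(frames, c(1, 2), mean)
  if (diff(range(avg)) == 0)
    stop("degenerate image: constant intensity", call. = FALSE)
  smoothed <- as.matrix(EBImage::gblur(EBImage::as.Image(avg), sigma = sigma))
  smoothed > otsu_threshold(as.numeric(smoothed))
}

#' Per-pixel selectivity features from four-direction ON/OFF edges
#'
#' A background signal — the mean intensity of the non-foreground region
#' — is subtracted before baselining, and foreground pixels whose
#' baseline does not exceed the background by more than three standard
#' errors of the background time-mean are dropped as degenerate (their
#' dF/F is ill-conditioned; these are mask-bleed pixels with no real
#' signal). For each remaining pixel: dF/F is computed, responses are averaged
#' across repeats of each direction x contrast epoch, and pixels whose
#' peak response does not exceed mean + \code{k_sd} x SD of the full
#' trial-averaged trace are dropped (responsiveness filter). Survivors
#' get a preferred direction (PD, argmax over directions at the preferred
#' contrast), null direction (ND, PD + 180 deg), preferred/non-preferred
#' contrast (PC/NC), DSI = (PD - ND)/PD and CSI = (PC - NC)/PC (negative
#' ND/NC peaks are clipped at 0 so both indices stay in [0, 1]), the
#' frame of the PD-epoch peak, and a layer label from an optional region
#' mask. Pixels with PD <= 0 or PC <= 0 are dropped and counted.
#'
#' @param movie a \code{terminal_movie} with an edge epoch table
#'   (direction_deg, contrast per epoch)
#' @param k_sd responsiveness threshold in SD units (2, or 3 for
#'   receptive-field mapping)
#' @param f0_mode baseline convention for \code{\link{compute_dff}}
#' @param layer_mask optional H x W matrix of layer labels ("A".."D")
#' @param sigma foreground-smoothing sigma in pixels
#' @return data.frame (one row per surviving pixel): x, y, dsi, csi,
#'   pd_angle, t_pd_peak, contrast_class, layer, peak_response; with
#'   attributes \code{n_dropped} (named counts: degenerate_baseline,
#'   unresponsive, undefined_index) and \code{foreground} (the mask)
#' @export
pixel_selectivity <- function(movie, k_sd = 2,
                              f0_mode = "prestim_epoch",
                              layer_mask = NULL, sigma = 1.5) {
  stopifnot(inherits(movie, "terminal_movie"))
  ep <- movie$epochs
  if (is.null(ep) || !all(c("direction_deg", "contrast") %in% names(ep)))
    stop("movie lacks a direction/contrast epoch table", call. = FALSE)
  fg <- foreground_mask(movie, sigma)
  idx <- which(fg, arr.ind = TRUE)          # rows: (row=y, col=x)
  rate <- movie$frame_rate
  n_t <- dim(movie$frames)[3]
  avg <- apply(movie$frames, c(1, 2), mean)
  background <- mean(avg[!fg])
  # floor: baseline must exceed the background by > 3 SE of a pixel's
  # time-mean, or dF/F is division by (near) zero
  f0_floor <- background + 3 * stats::sd(avg[!fg])
  combos <- unique(ep[, c("direction_deg", "contrast")])
  combos <- combos[order(combos$contrast, combos$direction_deg), ]
  ep_len <- floor(min(ep$t_end - ep$t_start) * rate)
  dropped <- c(degenerate_baseline = 0L, unresponsive = 0L,
               undefined_index = 0L)
  rows <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    y <- idx[i, 1]; x <- idx[i, 2]
    F <- movie$frames[y, x, ]
    if (mean(F) <= f0_floor) {
      dropped["degenerate_baseline"] <- dropped["degenerate_baseline"] + 1L
      next
    }
    dff <- compute_dff(F, rate, background = background,
                       f0_mode = f0_mode, epochs = ep)$values
    avg_epochs <- lapply(seq_len(nrow(combos)), function(j) {
      sel <- ep$direction_deg == combos$direction_deg[j] &
        ep$contrast == combos$contrast[j]
      epoch_average(dff, rate, ep$t_start[sel],
                    ep_len / rate)$mean
    })
    full <- unlist(avg_epochs)
    if (max(full) <= mean(full) + k_sd * stats::sd(full)) {
      dropped["unresponsive"] <- dropped["unresponsive"] + 1L
      next
    }
    peaks <- vapply(avg_epochs, max, 0)
    by_contrast <- tapply(peaks, combos$contrast, max)
    pc_contrast <- as.numeric(names(by_contrast))[which.max(by_contrast)]
    PC <- max(by_contrast)
    NC <- max(by_contrast[as.numeric(names(by_contrast)) != pc_contrast], 0)
    at_pc <- combos$contrast == pc_contrast
    dir_peaks <- peaks[at_pc]
    dirs <- combos$direction_deg[at_pc]
    pd_i <- which.max(dir_peaks)
    PD <- dir_peaks[pd_i]
    pd_angle <- dirs[pd_i]
    nd_angle <- (pd_angle + 180) %% 360
    nd_i <- which.min(pmin(abs(dirs - nd_angle), 360 - abs(dirs - nd_angle)))
    ND <- dir_peaks[nd_i]
    if (PD <= 0 || PC <= 0) {
      dropped["undefined_index"] <- dropped["undefined_index"] + 1L
      next
    }
    t_pd <- which.max(avg_epochs[[which(at_pc)[pd_i]]])
    rows[[i]] <- data.frame(
      x = x, y = y,
      dsi = (PD - max(ND, 0)) / PD,
      csi = (PC - max(NC, 0)) / PC,
      pd_angle = pd_angle, t_pd_peak = t_pd,
      contrast_class = if (pc_contrast > 0) "ON" else "OFF",
      layer = if (is.null(layer_mask)) "unassigned" else layer_mask[y, x],
      peak_response = PD
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(x = integer(0), y = integer(0), dsi = numeric(0),
                      csi = numeric(0), pd_angle = numeric(0),
                      t_pd_peak = integer(0), contrast_class = character(0),
                      layer = character(0), peak_response = numeric(0))
  if (sum(dropped) > 0)
    message(sprintf("pixel_selectivity: dropped %d degenerate-baseline, %d unresponsive, %d undefined-index pixel(s)",
                    dropped["degenerate_baseline"], dropped["unresponsive"],
                    dropped["undefined_index"]))
  attr(out, "n_dropped") <- dropped
  attr(out, "foreground") <- fg
  out
}

#' Area-constrained hierarchical clustering of selective pixels
#'
#' Within each (contrast class, layer) group, pixels are clustered by
#' average-linkage agglomerative clustering on the feature vector
#' (x, y, time_weight * t_pd_peak). Candidate cut heights are the merge
#' heights of the dendrogram; the chosen height maximizes the number of
#' clusters whose area (pixel count x pixel_size^2) lies in
#' \code{area_range}, ties going to the largest height (the coarsest of
#' the equally good partitions, which keeps terminals whole rather than
#' fragmenting them into equally many in-range pieces). Clusters outside
#' the range are discarded.
#'
#' @param features pixel feature table from
#'   \code{\link{pixel_selectivity}}
#' @param pixel_size micrometers per pixel
#' @param area_range retained-cluster area range in square micrometers
#' @param time_weight weight of t_pd_peak (frames) relative to pixel
#'   coordinates in the clustering distance
#' @return list: \code{clusters} (list of \code{roi_cluster}: pixels
#'   (x,y matrix), area_um2, centroid, contrast_class, layer, id),
#'   \code{cut_heights} (chosen height per group)
#' @export
cluster_terminals <- function(features, pixel_size,
                              area_range = c(1, 6.5), time_weight = 1) {
  px_area <- pixel_size^2
  in_range <- function(n_px) {
    a <- n_px * px_area
    a >= area_range[1] & a <= area_range[2]
  }
  groups <- split(features,
                  list(features$contrast_class, features$layer), drop = TRUE)
  clusters <- list()
  cut_heights <- numeric(0)
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (nrow(g) == 0) next
    if (nrow(g) == 1) {
      labels <- 1L
      cut_heights[gname] <- 0
    } else {
      feat <- cbind(g$x, g$y, time_weight * g$t_pd_peak)
      hc <- stats::hclust(stats::dist(feat), method = "average")
      heights <- sort(unique(hc$height))
      n_good <- vapply(heights, function(h) {
        sum(in_range(table(stats::cutree(hc, h = h))))
      }, 0)
      # ties go to the largest height: among cuts yielding equally many
      # in-range clusters, the coarsest partition keeps terminals whole
      # instead of counting equally many of their fragments
      best_h <- heights[max(which(n_good == max(n_good)))]
      labels <- stats::cutree(hc, h = best_h)
      cut_heights[gname] <- best_h
    }
    sizes <- table(labels)
    keep <- as.integer(names(sizes)[in_range(sizes)])
    if (length(keep) == 0) {
      warning(sprintf("group %s: all clusters outside area range", gname))
      next
    }
    for (lab in keep) {
      px <- as.matrix(g[labels == lab, c("x", "y")])
      clusters[[length(clusters) + 1L]] <- structure(list(
        pixels = px,
        area_um2 = nrow(px) * px_area,
        centroid = colMeans(px),
        contrast_class = g$contrast_class[1],
        layer = g$layer[1],
        id = NA_integer_), class = "roi_cluster")
    }
  }
  # deterministic ids independent of pixel input order
  if (length(clusters)) {
    ord <- order(vapply(clusters, function(cl) cl$contrast_class, ""),
                 vapply(clusters, function(cl) cl$layer, ""),
                 vapply(clusters, function(cl) cl$centroid[1], 0),
                 vapply(clusters, function(cl) cl$centroid[2], 0))
    clusters <- clusters[ord]
    for (i in seq_along(clusters)) clusters[[i]]$id <- i
  }
  list(clusters = clusters, cut_heights = cut_heights)
}

#' Re-apply saved cluster masks to a second recording
#'
#' Cluster pixel masks are matched to a later recording of the same cells
#' by pixel identity (identical grid geometry required) and a report of
#' cluster pixels falling outside the second recording's foreground is
#' returned.
#'
#' @param clusters list of \code{roi_cluster}s
#' @param movie2 the second \code{terminal_movie}
#' @param sigma foreground-smoothing sigma for the report
#' @return list: \code{clusters} (unchanged masks), \code{outside_report}
#'   (data.frame cluster_id, n_pixels, n_outside_foreground)
#' @export
match_clusters <- function(clusters, movie2, sigma = 1.5) {
  dims <- dim(movie2$frames)[1:2]
  bad <- vapply(clusters, function(cl)
    any(cl$pixels[, "x"] > dims[2] | cl$pixels[, "y"] > dims[1]), TRUE)
  if (any(bad))
    stop("grid geometry mismatch: cluster pixels outside the second recording",
         call. = FALSE)
  fg <- foreground_mask(movie2, sigma)
  report <- do.call(rbind, lapply(clusters, function(cl) {
    outside <- sum(!fg[cbind(cl$pixels[, "y"], cl$pixels[, "x"])])
    data.frame(cluster_id = cl$id, n_pixels = nrow(cl$pixels),
               n_outside_foreground = outside)
  }))
  list(clusters = clusters, outside_report = report)
}

#' Mean dF/F trace of each cluster
#'
#' Averages raw fluorescence over each cluster's pixels, then computes
#' dF/F with the requested baseline convention.
#'
#' @param movie a \code{terminal_movie}
#' @param clusters list of \code{roi_cluster}s
#' @param f0_mode,epochs passed to \code{\link{compute_dff}}
#' @return matrix [n_clusters x T] of dF/F traces
#' @export
extract_cluster_traces <- function(movie, clusters,
                                   f0_mode = "whole_trace_mean",
                                   epochs = NULL) {
  t(vapply(clusters, function(cl) {
    F <- apply(cl$pixels, 1, function(p) movie$frames[p["y"], p["x"], ])
    compute_dff(rowMeans(F), movie$frame_rate, f0_mode = f0_mode,
                epochs = epochs %||% movie$epochs,
                trace_name = paste0("cluster ", cl$id))$values
  }, numeric(dim(movie$frames)[3])))
}

#' Save cluster masks as a labeled TIFF and a pixel-table CSV
#'
#' @param clusters list of \code{roi_cluster}s
#' @param dim_px image size \code{c(height, width)}
#' @param tiff_path,csv_path output files
#' @export
save_cluster_masks <- function(clusters, dim_px, tiff_path, csv_path) {
  lab <- matrix(0L, dim_px[1], dim_px[2])
  tab <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$id, x = cl$pixels[, "x"],
               y = cl$pixels[, "y"])))
  for (cl in clusters)
    lab[cbind(cl$pixels[, "y"], cl$pixels[, "x"])] <- cl$id
  tiff::writeTIFF(lab / max(1L, length(clusters)), tiff_path,
                  bits.per.sample = 16L)
  utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(csv_path)
}
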