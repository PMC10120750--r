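#' Distortion-corrected mean of a UV field over a region
#'
#' Pixel averages on an equirectangular chart are biased by the chart's
#' non-uniform area element; weighting each pixel by its differential area
#' `dA` recovers the true 3D surface-area-weighted mean:
#' `sum(F * dA * mask) / sum(dA * mask)`.
#'
#' @param uv_field matrix of per-pixel values.
#' @param uv_dA matrix of per-pixel differential areas (see
#'   [uv_jacobian_metrics()]).
#' @param region_mask logical matrix (whole grid if omitted).
#' @return scalar; `NA` with a warning for an empty mask.
#' @export
corrected_mean <- function(uv_field, uv_dA, region_mask = NULL) {
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(uv_field),
                                                  ncol(uv_field))
  w <- uv_dA * region_mask
  if (sum(w) <= 0) {
    warning("empty region mask")
    return(NA_real_)
  }
  sum(uv_field * w, na.rm = TRUE) / sum(w[!is.na(uv_field)])
}

#' Spherical padding of an equirectangular image
#'
#' Periodic wrap along u (columns); across the poles the first/last rows are
#' reflected and flipped in u, reproducing the spherical continuation.
#'
#' @param uv_image matrix (rows = v, cols = u).
#' @param pad padding width in pixels (< rows/2).
#' @return padded matrix of size (rows + 2 pad) x (cols + 2 pad).
#' @export
spherical_pad <- function(uv_image, pad) {
  nr <- nrow(uv_image); nc <- ncol(uv_image)
  if (pad >= nr / 2) stop("pad must be smaller than half the row count")
  top <- uv_image[pad:1, nc:1, drop = FALSE]       # pole reflection + u flip
  bot <- uv_image[nr:(nr - pad + 1), nc:1, drop = FALSE]
  img <- rbind(top, uv_image, bot)
  left <- img[, (nc - pad + 1):nc, drop = FALSE]   # u periodic
  right <- img[, 1:pad, drop = FALSE]
  cbind(left, img, right)
}

#' Reference block-matching dense flow backend
#'
#' A coarse dense 2D displacement estimator: images are divided into blocks
#' and each block's integer displacement minimizes the sum of squared
#' differences over a +/- `search` window; per-pixel flow is the bilinear
#' upsampling of the block displacements. Any callable with the same
#' signature (two images to an rows x cols x 2 array of (dv, du)) can stand
#' in, e.g. ground-truth synthetic flow in tests.
#'
#' @param block block size in pixels.
#' @param search search radius in pixels.
#' @return function `(img1, img2) -> array(dim = c(rows, cols, 2))`.
#' @export
block_flow_backend <- function(block = 16, search = 4) {
  function(img1, img2) {
    nr <- nrow(img1); nc <- ncol(img1)
    br <- ceiling(nr / block); bc <- ceiling(nc / block)
    dv <- matrix(0, br, bc); du <- matrix(0, br, bc)
    for (bi in seq_len(br)) for (bj in seq_len(bc)) {
      r0 <- (bi - 1) * block + 1; r1 <- min(bi * block, nr)
      c0 <- (bj - 1) * block + 1; c1 <- min(bj * block, nc)
      ref <- img1[r0:r1, c0:c1]
      best <- Inf
      for (sv in -search:search) for (su in -search:search) {
        rr <- (r0:r1) + sv; cc <- (c0:c1) + su
        if (min(rr) < 1 || max(rr) > nr || min(cc) < 1 || max(cc) > nc) next
        err <- sum((img2[rr, cc] - ref)^2)
        if (err < best) { best <- err; dv[bi, bj] <- sv; du[bi, bj] <- su }
      }
    }
    out <- array(0, c(nr, nc, 2))
    out[, , 1] <- resize_bilinear(dv, nr, nc)
    out[, , 2] <- resize_bilinear(du, nr, nc)
    out
  }
}

#' Track blebs as bounding boxes in the UV plane
#'
#' Boxes are extracted from per-frame instance label images
#' (spherically padded), then linked by optical-flow-guided greedy bipartite
#' matching on intersection-over-union: each track's last box is advected by
#' the median flow inside it, candidate detections with IoU > `iou_min`
#' (default 0.25) are matched in decreasing IoU order, unmatched tracks are
#' propagated by flow for up to `max_gap` frames (default 5) and then
#' terminated. Post-filters keep tracks longer than `min_length` frames with
#' mean boxed curvature above `min_H`; box-area jumps
#' (|area - moving-average(3)| > `area_jump`) are repaired by linear
#' interpolation of the box corners; each track must claim a unique label id
#' for at least half of its lifetime or is dropped.
#'
#' @param per_frame_labels list of integer label matrices (one per frame).
#' @param per_frame_H list of curvature images on the same grid.
#' @param flow_backend callable `(img1, img2) -> flow array`; defaults to
#'   [block_flow_backend()].
#' @param pad spherical padding in pixels.
#' @param iou_min,max_gap,min_length,min_H,area_jump gating parameters.
#' @return list of `track` objects: data frames with columns `frame`,
#'   `vmin`, `umin`, `vmax`, `umax`, `interpolated`; label id in attribute
#'   `"label"`.
#' @export
track_blebs <- function(per_frame_labels, per_frame_H,
                        flow_backend = block_flow_backend(),
                        pad = NULL, iou_min = 0.25, max_gap = 5,
                        min_length = 5, min_H = 0.1, area_jump = 500) {
  n_frames <- length(per_frame_labels)
  nr <- nrow(per_frame_labels[[1]])
  if (is.null(pad)) pad <- min(50, floor(nr / 2) - 1)
  boxes <- lapply(per_frame_labels, boxes_from_labels, pad = pad)
  Hpad <- lapply(per_frame_H, spherical_pad, pad = pad)
  H8 <- lapply(Hpad, function(h) {
    r <- range(h); round((h - r[1]) / max(r[2] - r[1], 1e-12) * 255)
  })
  tracks <- list()      # active: list(frames=df, gap, label_votes)
  done <- list()
  for (t in seq_len(n_frames)) {
    det <- boxes[[t]]
    flow <- if (t > 1) flow_backend(H8[[t - 1]], H8[[t]]) else NULL
    # predict active track boxes
    if (length(tracks) && !is.null(flow)) {
      for (i in seq_along(tracks)) {
        b <- tracks[[i]]$last
        rr <- pmin(pmax(round(b["vmin"]):round(b["vmax"]), 1), nrow(flow))
        cc <- pmin(pmax(round(b["umin"]):round(b["umax"]), 1), ncol(flow))
        dv <- median(flow[rr, cc, 1]); du <- median(flow[rr, cc, 2])
        tracks[[i]]$pred <- b + c(dv, du, dv, du)
      }
    } else {
      for (i in seq_along(tracks)) tracks[[i]]$pred <- tracks[[i]]$last
    }
    # greedy IoU matching
    used_det <- rep(FALSE, nrow(det))
    matched <- rep(FALSE, length(tracks))
    if (length(tracks) && nrow(det)) {
      iou <- matrix(0, length(tracks), nrow(det))
      for (i in seq_along(tracks)) for (j in seq_len(nrow(det)))
        iou[i, j] <- box_iou(tracks[[i]]$pred, unlist(det[j, c("vmin", "umin",
                                                              "vmax", "umax")]))
      while (TRUE) {
        m <- which.max(iou)
        if (iou[m] <= iou_min) break
        i <- (m - 1) %% length(tracks) + 1
        j <- (m - 1) %/% length(tracks) + 1
        tracks[[i]]$frames <- rbind(tracks[[i]]$frames,
          data.frame(frame = t, vmin = det$vmin[j], umin = det$umin[j],
                     vmax = det$vmax[j], umax = det$umax[j],
                     interpolated = FALSE))
        tracks[[i]]$last <- c(vmin = det$vmin[j], umin = det$umin[j],
                              vmax = det$vmax[j], umax = det$umax[j])
        tracks[[i]]$gap <- 0
        tracks[[i]]$votes <- c(tracks[[i]]$votes, det$label[j])
        matched[i] <- TRUE
        used_det[j] <- TRUE
        iou[i, ] <- 0; iou[, j] <- 0
      }
    }
    # unmatched tracks: propagate or terminate
    if (length(tracks)) {
      keep <- rep(TRUE, length(tracks))
      for (i in seq_along(tracks)) {
        if (matched[i]) next
        tracks[[i]]$gap <- tracks[[i]]$gap + 1
        if (tracks[[i]]$gap > max_gap) {
          done[[length(done) + 1]] <- tracks[[i]]
          keep[i] <- FALSE
        } else {
          tracks[[i]]$last <- tracks[[i]]$pred
        }
      }
      tracks <- tracks[keep]
    }
    # new tracks from unmatched detections
    for (j in which(!used_det)) {
      tracks[[length(tracks) + 1]] <- list(
        frames = data.frame(frame = t, vmin = det$vmin[j], umin = det$umin[j],
                            vmax = det$vmax[j], umax = det$umax[j],
                            interpolated = FALSE),
        last = c(vmin = det$vmin[j], umin = det$umin[j], vmax = det$vmax[j],
                 umax = det$umax[j]),
        gap = 0, votes = det$label[j])
    }
  }
  done <- c(done, tracks)
  # post-filters
  out <- list()
  for (tr in done) {
    df <- tr$frames
    if (nrow(df) <= min_length) next
    Hmean <- mean(vapply(seq_len(nrow(df)), function(r) {
      h <- Hpad[[df$frame[r]]]
      rr <- pmin(pmax(round(df$vmin[r]):round(df$vmax[r]), 1), nrow(h))
      cc <- pmin(pmax(round(df$umin[r]):round(df$umax[r]), 1), ncol(h))
      mean(h[rr, cc])
    }, 0))
    if (Hmean <= min_H) next
    votes <- table(tr$votes)
    if (max(votes) < 0.5 * nrow(df)) next
    df <- repair_box_jumps(df, area_jump)
    attr(df, "label") <- as.integer(names(votes)[which.max(votes)])
    attr(df, "mean_H") <- Hmean
    out[[length(out) + 1]] <- df
  }
  out
}

boxes_from_labels <- function(lab, pad) {
  lp <- spherical_pad(lab, pad)
  ids <- sort(setdiff(unique(as.vector(lab))[unique(as.vector(lab)) > 0], 0))
  res <- lapply(ids, function(l) {
    # use the central (unpadded) copy of each label
    w <- which(lp[(pad + 1):(pad + nrow(lab)), (pad + 1):(pad + ncol(lab))] == l,
               arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    data.frame(label = l, vmin = min(w[, 1]) + pad, umin = min(w[, 2]) + pad,
               vmax = max(w[, 1]) + pad, umax = max(w[, 2]) + pad)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(label = integer(0), vmin = numeric(0),
                               umin = numeric(0), vmax = numeric(0),
                               umax = numeric(0))
  else out
}

box_iou <- function(a, b) {
  # boxes as (vmin, umin, vmax, umax)
  iv <- max(0, min(a[3], b[3]) - max(a[1], b[1]) + 1)
  iu <- max(0, min(a[4], b[4]) - max(a[2], b[2]) + 1)
  inter <- iv * iu
  aa <- (a[3] - a[1] + 1) * (a[4] - a[2] + 1)
  bb <- (b[3] - b[1] + 1) * (b[4] - b[2] + 1)
  as.numeric(inter / (aa + bb - inter))
}

repair_box_jumps <- function(df, area_jump) {
  area <- (df$vmax - df$vmin + 1) * (df$umax - df$umin + 1)
  ma <- moving_average(area, 3)
  bad <- which(abs(area - ma) > area_jump)
  good <- setdiff(seq_len(nrow(df)), bad)
  if (length(bad) && length(good) >= 2) {
    for (col in c("vmin", "umin", "vmax", "umax"))
      df[[col]][bad] <- approx(good, df[[col]][good], xout = bad, rule = 2)$y
    df$interpolated[bad] <- TRUE
  }
  df
}

moving_average <- function(x, w) {
  n <- length(x)
  out <- x
  r <- floor(w / 2)
  for (i in seq_len(n)) out[i] <- mean(x[max(1, i - r):min(n, i + r)])
  out
}

#' Peak detection with prominence and separation gating
#'
#' @param x numeric series.
#' @param prominence minimum prominence (height above the higher of the two
#'   flanking minima).
#' @param separation minimum index distance between accepted peaks.
#' @return integer peak positions.
#' @export
find_peaks <- function(x, prominence = 0.5, separation = 3) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # local maxima, accepting the leading edge of flat-topped plateaus
  dl <- c(-Inf, diff(x))
  dr <- c(diff(x), Inf)
  cand <- which(dl > 0 & dr <= 0)
  prom <- vapply(cand, function(i) {
    higher_l <- which(x[1:(i - 1)] > x[i])
    a <- if (length(higher_l)) max(higher_l) else 1L
    higher_r <- which(x[(i + 1):n] > x[i])
    b <- if (length(higher_r)) i + min(higher_r) else n
    x[i] - max(min(x[a:i]), min(x[i:b]))
  }, 0)
  cand <- cand[prom > prominence]
  if (!length(cand)) return(integer(0))
  # enforce separation, keeping the higher peak
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= separation)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Align bleb area timeseries on their maxima
#'
#' Per-track area series are smoothed with a moving average (window 3),
#' peaks with prominence > 0.5 separated by at least 3 timepoints are taken
#' as events, and windows of +/- `half_window` timepoints (29 total by
#' default) centred on each peak are averaged into a mean event profile
#' with its standard error.
#'
#' @param area_series list of numeric per-track timeseries (e.g. corrected
#'   bleb areas).
#' @param half_window half width of the aligned window.
#' @param prominence,separation peak gating.
#' @return list: `profile` (mean per lag), `sem`, `n_events`, `lags`,
#'   `event_times` (list per track).
#' @export
align_bleb_events <- function(area_series, half_window = 14,
                              prominence = 0.5, separation = 3) {
  lags <- -half_window:half_window
  acc <- matrix(NA_real_, 0, length(lags))
  evts <- list()
  for (k in seq_along(area_series)) {
    x <- area_series[[k]]
    xs <- moving_average(x, 3)
    pk <- find_peaks(xs, prominence, separation)
    evts[[k]] <- pk
    for (p in pk) {
      row <- rep(NA_real_, length(lags))
      idx <- p + lags
      ok <- idx >= 1 & idx <= length(x)
      row[ok] <- x[idx[ok]]
      acc <- rbind(acc, row)
    }
  }
  if (!nrow(acc)) return(list(profile = rep(NA_real_, length(lags)),
                              sem = rep(NA_real_, length(lags)),
                              n_events = 0, lags = lags, event_times = evts))
  profile <- colMeans(acc, na.rm = TRUE)
  sem <- apply(acc, 2, function(cl) {
    cl <- cl[!is.na(cl)]
    if (length(cl) < 2) NA_real_ else sd(cl) / sqrt(length(cl))
  })
  list(profile = profile, sem = sem, n_events = nrow(acc), lags = lags,
       event_times = evts)
}

#' Grid-initialized ROI tracking with cross-correlation statistics
#'
#' ROIs are initialized on a regular grid, advected frame-to-frame by the
#' median dense flow inside each ROI window, and distortion-corrected
#' timeseries of two channels are sampled in a square window around each ROI
#' centre. The per-ROI normalized cross-correlation between the two
#' timeseries is aggregated into a population mean with a 95% normal
#' confidence interval per lag; instantaneous (lag 0) significance is
#' reported as the CI excluding zero.
#'
#' @param movie_a,movie_b lists of per-frame images (e.g. actin ratio TC and
#'   curvature H).
#' @param uv_dA differential-area image for the correction weights.
#' @param flow_backend dense flow callable (applied to `movie_a`).
#' @param n_rois approximate number of grid ROIs.
#' @param roi_width square window width (pixels).
#' @param max_lag maximum correlation lag (frames).
#' @return list: `tracks` (per-ROI data frame of centres), `correlations`
#'   (ROI x lag matrix), `mean_corr`, `ci_low`, `ci_high`, `lags`,
#'   `lag0_significant`.
#' @export
track_rois_and_correlate <- function(movie_a, movie_b, uv_dA,
                                     flow_backend = block_flow_backend(),
                                     n_rois = 1000, roi_width = NULL,
                                     max_lag = NULL) {
  n_frames <- length(movie_a)
  nr <- nrow(movie_a[[1]]); nc <- ncol(movie_a[[1]])
  if (is.null(max_lag)) max_lag <- max(2, floor(n_frames / 3))
  k <- max(1, round(sqrt(n_rois * nr / nc)))
  rows <- round(seq(1, nr, length.out = k))
  cols <- round(seq(1, nc, length.out = round(n_rois / k)))
  ctrs <- as.matrix(expand.grid(v = rows, u = cols))
  if (is.null(roi_width)) roi_width <- max(5, round(mean(c(nr, nc)) / k))
  half <- floor(roi_width / 2)
  pos <- array(NA_real_, c(nrow(ctrs), n_frames, 2))
  pos[, 1, ] <- ctrs
  alive <- rep(TRUE, nrow(ctrs))
  for (t in 2:n_frames) {
    fl <- flow_backend(movie_a[[t - 1]], movie_a[[t]])
    for (i in which(alive)) {
      p <- pos[i, t - 1, ]
      rr <- round(p[1]) + (-half:half); cc <- round(p[2]) + (-half:half)
      rr <- rr[rr >= 1 & rr <= nr]; cc <- cc[cc >= 1 & cc <= nc]
      if (!length(rr) || !length(cc)) { alive[i] <- FALSE; next }
      newp <- p + c(median(fl[rr, cc, 1]), median(fl[rr, cc, 2]))
      if (newp[1] < 1 || newp[1] > nr || newp[2] < 1 || newp[2] > nc) {
        alive[i] <- FALSE          # ROI left the grid: terminated
      } else pos[i, t, ] <- newp
    }
  }
  # corrected timeseries + cross-correlation per ROI
  lags <- -max_lag:max_lag
  cors <- matrix(NA_real_, nrow(ctrs), length(lags))
  for (i in seq_len(nrow(ctrs))) {
    ok <- !is.na(pos[i, , 1])
    if (sum(ok) < max_lag + 3) next
    ta <- tb <- rep(NA_real_, n_frames)
    for (t in which(ok)) {
      rr <- round(pos[i, t, 1]) + (-half:half)
      cc <- round(pos[i, t, 2]) + (-half:half)
      rr <- rr[rr >= 1 & rr <= nr]; cc <- cc[cc >= 1 & cc <= nc]
      msk <- matrix(FALSE, nr, nc); msk[rr, cc] <- TRUE
      ta[t] <- corrected_mean(movie_a[[t]], uv_dA, msk)
      tb[t] <- corrected_mean(movie_b[[t]], uv_dA, msk)
    }
    cors[i, ] <- norm_xcorr(ta[ok], tb[ok], max_lag)
  }
  ok_roi <- rowSums(is.na(cors)) == 0
  mc <- colMeans(cors[ok_roi, , drop = FALSE])
  se <- apply(cors[ok_roi, , drop = FALSE], 2, sd) / sqrt(sum(ok_roi))
  ci_low <- mc - 1.96 * se
  ci_high <- mc + 1.96 * se
  lag0 <- which(lags == 0)
  list(tracks = pos, correlations = cors, mean_corr = mc, ci_low = ci_low,
       ci_high = ci_high, lags = lags,
       lag0_significant = ci_low[lag0] > 0 || ci_high[lag0] < 0)
}

# normalized cross-correlation of two series over +/- max_lag
norm_xcorr <- function(a, b, max_lag) {
  a <- a - mean(a); a <- a / (sqrt(mean(a^2)) + 1e-12)
  b <- b - mean(b); b <- b / (sqrt(mean(b^2)) + 1e-12)
  n <- length(a)
  vapply(-max_lag:max_lag, function(l) {
    if (l >= 0) {
      ia <- 1:(n - l); ib <- (1 + l):n
    } else {
      ia <- (1 - l):n; ib <- 1:(n + l)
    }
    mean(a[ia] * b[ib])
  }, 0)
}

#' Slow/fast speed populations by 3-class Otsu thresholding
#'
#' The per-track mean speeds are histogrammed (25 bins over 0-10 um/min) and
#' the two thresholds of 3-class Otsu thresholding are reported as the slow
#' and fast population estimates (the convention used for surface
#' retrograde-flow versus travelling-ruffle speeds). A 2-component Gaussian
#' mixture estimate is returned alongside for comparison; a unimodality
#' heuristic triggers a warning.
#'
#' @param track_speeds numeric vector of per-track mean speeds (um/min).
#' @return list: `slow`, `fast` (Otsu thresholds), `mixture_means`,
#'   `bimodal`.
#' @export
speed_populations <- function(track_speeds) {
  x <- track_speeds[is.finite(track_speeds)]
  if (length(unique(x)) < 3) {
    warning("degenerate speed distribution")
    return(list(slow = NA_real_, fast = NA_real_,
                mixture_means = rep(mean(x), 2), bimodal = FALSE))
  }
  br <- seq(0, 10, length.out = 26)
  h <- tabulate(findInterval(pmin(pmax(x, 0), 10 - 1e-9), br), 25)
  th <- otsu_thresholds(x, 3)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  mix <- tryCatch(mclust::Mclust(x, G = 2, verbose = FALSE)$parameters$mean,
                  error = function(e) rep(NA_real_, 2))
  # crude bimodality check: a histogram valley between two maxima
  sm <- c(0, moving_average(h, 3), 0)   # pad so edge modes count as peaks
  pk <- find_peaks(sm, prominence = max(sm) * 0.1, separation = 3)
  bimodal <- length(pk) >= 2
  if (!bimodal) warning("speed distribution looks unimodal; population split unreliable")
  list(slow = th[1], fast = th[2],
       mixture_means = sort(unname(mix), na.last = TRUE), bimodal = bimodal)
}

#' Kernel conditional expectation E[Y | X = x]
#'
#' Gaussian product-kernel density (Scott's bandwidth) on a fixed grid; the
#' conditional mean and standard deviation are the printed integral ratios
#' of the joint density.
#'
#' @param x,y paired samples.
#' @param xlim,ylim evaluation ranges.
#' @param nbins grid resolution per axis.
#' @return list: `x` (grid), `mean`, `sd` (NA where the X neighbourhood is
#'   empty).
#' @export
conditional_expectation <- function(x, y, xlim = c(-0.2, 0.6),
                                    ylim = c(-1, 1), nbins = 100) {
  n <- length(x)
  hx <- sd(x) * n^(-1 / 6)
  hy <- sd(y) * n^(-1 / 6)
  gx <- seq(xlim[1], xlim[2], length.out = nbins)
  gy <- seq(ylim[1], ylim[2], length.out = nbins)
  Kx <- exp(-outer(gx, x, "-")^2 / (2 * hx^2))
  Ky <- exp(-outer(gy, y, "-")^2 / (2 * hy^2))
  joint <- Kx %*% t(Ky)            # nbins x nbins: p(x, y) up to constants
  px <- rowSums(joint)
  m <- as.vector(joint %*% gy) / px
  m2 <- as.vector(joint %*% gy^2) / px
  sdv <- sqrt(pmax(m2 - m^2, 0))
  empty <- px < max(px) * 1e-6
  m[empty] <- NA_real_; sdv[empty] <- NA_real_
  list(x = gx, mean = m, sd = sdv)
}

#' Project track velocities onto the cell-bottom plane
#'
#' Fits a plane through the supplied bottom-surface vertices by PCA (the
#' normal is the smallest principal direction), projects per-step 3D track
#' displacements onto the plane, and converts to um/min.
#'
#' @param tracks_3d list of n_t x 3 coordinate matrices (voxel units).
#' @param bottom_points m x 3 matrix of cell-bottom vertices.
#' @param voxel_size um per voxel (scalar or length 3).
#' @param frame_interval seconds between frames.
#' @return list: `speeds` (per-track mean planar speed, um/min), `normal`.
#' @export
plane_fit_speed_projection <- function(tracks_3d, bottom_points,
                                       voxel_size = 1, frame_interval = 1) {
  if (nrow(bottom_points) < 3) stop("need at least 3 bottom vertices")
  ctr <- colMeans(bottom_points)
  ev <- eigen(crossprod(sweep(bottom_points, 2, ctr)), symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  vs <- if (length(voxel_size) == 1) rep(voxel_size, 3) else voxel_size
  speeds <- vapply(tracks_3d, function(tr) {
    if (nrow(tr) < 2) return(NA_real_)
    d <- diff(tr) * rep(vs, each = nrow(tr) - 1)
    dpl <- d - outer(as.vector(d %*% nrm), nrm)
    mean(sqrt(rowSums(dpl^2))) / frame_interval * 60
  }, 0)
  list(speeds = speeds, normal = nrm)
}

#' Sample a volume along inward surface-normal trajectories
#'
#' From every vertex a trajectory is traced into the cell along the steepest
#' gradient of the distance transform down to an absolute depth, and the
#' trajectory samples are reduced by the chosen statistic (`"p95"` captures
#' thin cortical shells, `"mean"` suits diffuse volumetric signals).
#' Optional per-frame normalization by the whole-volume mean corrects global
#' photobleaching.
#'
#' @param volume intensity `volume_image`.
#' @param mesh the cell `surface_mesh` (voxel units).
#' @param cell_binary binary `volume_image` defining inside/outside.
#' @param depth_um depth in micrometres.
#' @param statistic `"mean"` or `"p95"`.
#' @param voxel_size um per voxel.
#' @param step step size along the trajectory (voxels).
#' @param normalize divide by the mean intensity inside the cell.
#' @return per-vertex numeric vector; truncated-trajectory count in
#'   attribute `"n_truncated"`.
#' @export
surface_proximal_sampling <- function(volume, mesh, cell_binary, depth_um = 1,
                                      statistic = c("mean", "p95"),
                                      voxel_size = 1, step = 0.5,
                                      normalize = FALSE) {
  statistic <- match.arg(statistic)
  depth_vox <- depth_um / mean(voxel_size)
  phi <- signed_distance(vol_data(cell_binary), inside = "negative")
  g <- array_gradient(gaussian_smooth_3d(phi, 1))
  off <- cell_binary$origin_offset
  gv <- lapply(g, function(a) volume_image(a, origin_offset = off))
  n_steps <- max(2, ceiling(depth_vox / step))
  P <- mesh$vertices
  samples <- matrix(NA_real_, nrow(P), n_steps + 1)
  samples[, 1] <- sample_volume(volume, P, fill = NA_real_)
  truncated <- rep(FALSE, nrow(P))
  for (s in seq_len(n_steps)) {
    gm <- cbind(sample_volume(gv[[1]], P), sample_volume(gv[[2]], P),
                sample_volume(gv[[3]], P))
    gm <- gm / pmax(sqrt(rowSums(gm^2)), 1e-9)
    P <- P - step * gm              # inward: against the outward gradient
    vals <- sample_volume(volume, P, fill = NA_real_)
    truncated <- truncated | is.na(vals)
    samples[, s + 1] <- vals
  }
  out <- apply(samples, 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(NA_real_)
    if (statistic == "mean") mean(r) else quantile(r, 0.95, names = FALSE)
  })
  if (normalize) {
    inside_mean <- mean(vol_data(volume)[vol_data(cell_binary) != 0])
    out <- out / inside_mean
  }
  attr(out, "n_truncated") <- sum(truncated)
  out
}

#' Local-surface maximum intensity projection
#'
#' Visualization utility: extends depth rays at every (x, y) pixel and takes
#' the maximum intensity within `half_depth` voxels of the cell surface,
#' producing a 2D image dominated by surface-proximal signal.
#'
#' @param volume intensity `volume_image`.
#' @param cell_binary binary `volume_image`.
#' @param half_depth half thickness of the surface band (voxels).
#' @return 2D matrix (x, y dims of the volume).
#' @export
surface_mip <- function(volume, cell_binary, half_depth = 9) {
  v <- vol_data(volume)
  band <- abs(signed_distance(vol_data(cell_binary))) <= half_depth
  masked <- ifelse(band, v, -Inf)
  out <- apply(masked, c(1, 2), max)
  out[!is.finite(out)] <- 0
  out
}
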