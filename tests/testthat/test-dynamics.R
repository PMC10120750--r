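test_that("corrected means equal direct 3D area-weighted means on a sphere chart", {
  param <- identity_sphere_param(20)
  uv <- uv_map(param, N = 64)
  m <- uv_jacobian_metrics(uv)
  # field = z^2 on the sphere: compare the dA-weighted chart mean with the
  # mesh-side area-weighted oracle
  zf <- pullback_field(uv, param$sphere_vertices[, 3]^2)
  chart_mean <- corrected_mean(zf, m$dA)
  a <- face_areas(param$source)
  f <- param$faces
  z2 <- param$sphere_vertices[, 3]^2
  fz <- (z2[f[, 1]] + z2[f[, 2]] + z2[f[, 3]]) / 3
  mesh_mean <- sum(fz * a) / sum(a)
  expect_equal(chart_mean, mesh_mean, tolerance = 0.01)
  # whereas the naive pixel mean is biased
  expect_gt(abs(mean(zf) - mesh_mean) / mesh_mean, 0.05)
  # constant fields are exact under any mask
  msk <- matrix(FALSE, 64, 128); msk[3:10, 5:20] <- TRUE
  expect_equal(corrected_mean(matrix(7, 64, 128), m$dA, msk), 7)
  expect_warning(out <- corrected_mean(zf, m$dA, msk & FALSE), "empty")
  expect_true(is.na(out))
})

test_that("spherical padding wraps u and reflects/flips across the poles", {
  img <- matrix(seq_len(6 * 8), 6, 8)
  p <- spherical_pad(img, 2)
  expect_equal(dim(p), c(10L, 12L))
  # u periodicity
  expect_equal(p[3:8, 1:2], img[, 7:8])
  expect_equal(p[3:8, 11:12], img[, 1:2])
  # pole: reflected rows with u flipped
  expect_equal(p[2, 3:10], img[1, 8:1])
  expect_equal(p[1, 3:10], img[2, 8:1])
  expect_equal(p[9, 3:10], img[6, 8:1])
  expect_error(spherical_pad(img, 3), "pad")
})

test_that("bleb tracking recovers stationary tracks and bridges short gaps", {
  spec <- phantom_spec(base_radius = 16, mesh_k = 10, seed = 2,
                       n_protrusions = 3)
  mv <- make_bleb_movie(spec, n_frames = 20, period = 10, N = 48)
  gt_flow <- function(a, b) array(0, c(nrow(a), ncol(a), 2))
  tr <- track_blebs(mv$uv_labels, mv$uv_H, flow_backend = gt_flow, pad = 10)
  expect_length(tr, 3)
  expect_true(all(vapply(tr, nrow, 0L) == 20))
  # determinism
  tr2 <- track_blebs(mv$uv_labels, mv$uv_H, flow_backend = gt_flow, pad = 10)
  expect_identical(lapply(tr, function(d) d[c("vmin", "umax")]),
                   lapply(tr2, function(d) d[c("vmin", "umax")]))
  # a bleb hidden for 3 frames is bridged; hidden for 7 it splits
  # (slow oscillation so box sizes are stable across the gap)
  mvs <- make_bleb_movie(spec, n_frames = 20, period = 100, N = 48)
  labs <- mvs$uv_labels
  hide <- function(lab_imgs, frames, id) {
    for (t in frames) lab_imgs[[t]][lab_imgs[[t]] == id] <- 0L
    lab_imgs
  }
  tr3 <- track_blebs(hide(labs, 9:11, 1L), mvs$uv_H, flow_backend = gt_flow,
                     pad = 10)
  expect_length(tr3, 3)
  tr7 <- track_blebs(hide(labs, 7:13, 1L), mvs$uv_H, flow_backend = gt_flow,
                     pad = 10, min_length = 4)
  expect_length(tr7, 4)   # the interrupted bleb yields two track fragments
})

test_that("event alignment recovers the generating period", {
  spec <- phantom_spec(base_radius = 16, mesh_k = 10, seed = 2,
                       n_protrusions = 3)
  mv <- make_bleb_movie(spec, n_frames = 30, period = 10, N = 48)
  series <- lapply(1:3, function(i) {
    sub <- mv$gt_tracks[mv$gt_tracks$bleb == i, ]
    (sub$vmax - sub$vmin + 1) * (sub$umax - sub$umin + 1)
  })
  al <- align_bleb_events(series, half_window = 6)
  iv <- unlist(lapply(al$event_times, diff))
  expect_equal(mean(iv), 10, tolerance = 1 / 10)
  expect_gt(al$n_events, 3)
  # profile peaks at lag 0
  expect_equal(which.max(al$profile), which(al$lags == 0))
  # no events below the prominence gate
  flat <- lapply(1:3, function(i) rep(100, 30) + 0.1 * sin(1:30))
  expect_equal(align_bleb_events(flat)$n_events, 0)
})

test_that("ROI cross-correlation finds planted lags and nulls", {
  set.seed(5)
  n_frames <- 16; nr <- 24; nc <- 48
  base <- lapply(seq_len(n_frames), function(t)
    matrix(sin(0.7 * t + outer(seq_len(nr) / 4, seq_len(nc) / 4, "+")) +
           rnorm(nr * nc, 0, 0.05), nr, nc))
  dA <- matrix(1, nr, nc)
  gtf <- function(a, b) array(0, c(nr, nc, 2))
  same <- track_rois_and_correlate(base, base, dA, flow_backend = gtf,
                                   n_rois = 40, roi_width = 5, max_lag = 4)
  lag0 <- which(same$lags == 0)
  expect_equal(unname(same$mean_corr[lag0]), 1, tolerance = 1e-6)
  expect_true(same$lag0_significant)
  # independent noise: lag-0 mean near 0, CI contains 0
  noise_a <- lapply(seq_len(n_frames), function(t) matrix(rnorm(nr * nc), nr, nc))
  noise_b <- lapply(seq_len(n_frames), function(t) matrix(rnorm(nr * nc), nr, nc))
  nl <- track_rois_and_correlate(noise_a, noise_b, dA, flow_backend = gtf,
                                 n_rois = 40, roi_width = 5, max_lag = 4)
  expect_lt(abs(nl$mean_corr[lag0]), 0.15)
  expect_false(nl$lag0_significant)
  # movie_b delayed by two frames: the population correlation peaks at lag 2
  shifted <- track_rois_and_correlate(base[3:n_frames],
                                      base[1:(n_frames - 2)], dA,
                                      flow_backend = gtf, n_rois = 40,
                                      roi_width = 5, max_lag = 4)
  expect_equal(shifted$lags[which.max(shifted$mean_corr)], 2)
})

test_that("speed populations recover a planted fast mode near 4.2 um/min", {
  set.seed(8)
  sp <- c(rnorm(80, 0.5, 0.1), rnorm(80, 4.2, 0.8))
  po <- speed_populations(sp)
  expect_equal(po$fast, 4.2, tolerance = 0.5 / 4.2)
  expect_true(po$bimodal)
  expect_equal(po$mixture_means[2], 4.2, tolerance = 0.15)
  # shifting the fast mode shifts the estimate monotonically
  fasts <- vapply(c(3.5, 4.5, 5.5), function(mu) {
    set.seed(9)
    suppressWarnings(
      speed_populations(c(rnorm(80, 0.5, 0.1), rnorm(80, mu, 0.8)))$fast)
  }, 0)
  expect_true(all(diff(fasts) > 0))
  expect_warning(speed_populations(rep(2, 50)), "degenerate")
})

test_that("surface-proximal sampling separates shells from diffuse signal", {
  spec <- phantom_spec(base_radius = 12, mesh_k = 14, seed = 10,
                       n_protrusions = 0)
  out <- make_volume(spec, channels = c("binary", "shell"), shell_depth = 3,
                     shell_sigma = 1)
  mesh <- out$mesh
  uni <- volume_image(array(2, dim(out$binary$data)),
                      origin_offset = out$binary$origin_offset)
  su <- surface_proximal_sampling(uni, mesh, out$binary, depth_um = 1)
  expect_equal(median(su, na.rm = TRUE), 2, tolerance = 1e-6)
  p95 <- surface_proximal_sampling(out$shell, mesh, out$binary, depth_um = 4,
                                   statistic = "p95")
  mn <- surface_proximal_sampling(out$shell, mesh, out$binary, depth_um = 4,
                                  statistic = "mean")
  expect_gt(median(p95, na.rm = TRUE), 1.3 * median(mn, na.rm = TRUE))
})
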