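test_that("a sphere is a fixed point of area-normalized cMCF", {
  ic <- icosphere(12, 1)
  flow <- cmcf(ic, flow_config(delta_t = 1e-3, max_iters = 5))
  v0 <- flow$snapshots[[1]]
  v5 <- flow$snapshots[[6]]
  expect_lt(max(abs(v5 - v0)), 5e-4)
  # connectivity and vertex count never change
  expect_identical(flow$faces, ic$faces)
  expect_equal(nrow(v5), nrow(ic$vertices))
})

test_that("cMCF shrinks the aspect ratio of an ellipsoid monotonically", {
  ic <- icosphere(12, 1)
  ell <- surface_mesh(sweep(ic$vertices, 2, c(2, 1, 1), "*"), ic$faces)
  flow <- cmcf(ell, flow_config(delta_t = 2e-3, max_iters = 10))
  aspects <- vapply(flow$snapshots, function(v) {
    r <- apply(sweep(v, 2, colMeans(v)), 2, function(x) max(abs(x)))
    max(r) / min(r)
  }, 0)
  expect_true(all(diff(aspects) < 1e-6))
  expect_lt(aspects[length(aspects)], aspects[1])
})

test_that("area renormalization holds after every iteration and genus is preserved", {
  spec <- phantom_spec(base_radius = 12, mesh_k = 14, seed = 4,
                       n_protrusions = 2)
  ph <- make_cell_mesh(spec)
  flow <- cmcf(ph, flow_config(max_iters = 5))
  for (v in flow$snapshots[-1]) {
    m <- surface_mesh(v, flow$faces, drop_degenerate = FALSE)
    expect_equal(mesh_area(m), 1, tolerance = 1e-9)
    expect_equal(euler_genus(m)$genus, 0)
  }
})

test_that("auto_stop detects the elbow, honours t_min, defaults to max_iters", {
  trace <- c(5, 3, 2, 1.5, 1.45, 1.44)
  expect_equal(auto_stop(trace, t_min = 1, delta_thresh = 0.1), 4L)
  expect_equal(auto_stop(trace, t_min = 10, delta_thresh = 0.1), 10L)
  steep <- c(100, 50, 25, 12, 6)
  expect_equal(auto_stop(steep, t_min = 1, delta_thresh = 1e-9), 4L)
  expect_error(auto_stop(c(1), 1, 0.1), "length")
})

test_that("active-contour cMCF advances a sphere in equal normal steps", {
  ic <- icosphere(16, 10)
  ic$vertices <- sweep(ic$vertices, 2, -c(20, 20, 20))
  vol <- voxelize(ic, dilation_radius = 3)
  phi <- signed_distance(vol$data)
  phiv <- volume_image(phi, origin_offset = vol$origin_offset)
  out <- active_contour_cmcf(ic, phiv, alpha_step = 1, n_iter = 5,
                             config = flow_config(delta_t = 1e-4))
  r <- sqrt(rowSums(sweep(out$vertices, 2, c(20, 20, 20))^2))
  expect_equal(mean(r), 15, tolerance = 0.08)  # radius grew by ~5 voxels
  # alpha = 0 reduces to a pure smoothing (cMCF) step: a sphere stays put
  out0 <- active_contour_cmcf(ic, phiv, alpha_step = 0, n_iter = 1,
                              config = flow_config(delta_t = 1e-4))
  r0 <- sqrt(rowSums(sweep(out0$vertices, 2, c(20, 20, 20))^2))
  expect_equal(mean(r0), 10, tolerance = 0.02)
})

test_that("topographic cMCF flattens a bump while pinning the boundary footprint", {
  # open sheet in (d, v, u) with one Gaussian bump
  nv <- 24; nu <- 36
  g <- as.matrix(expand.grid(v = seq_len(nv), u = seq_len(nu)))
  dcoord <- 4 * exp(-((g[, 1] - nv / 2)^2 + (g[, 2] - nu / 2)^2) / 18)
  verts <- cbind(dcoord, g[, 1], g[, 2])
  id <- function(i, j) (j - 1) * nv + i
  f <- NULL
  for (j in seq_len(nu - 1)) for (i in seq_len(nv - 1)) {
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i, j + 1)),
               c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  sheet <- surface_mesh(verts, f, drop_degenerate = FALSE)
  res <- topographic_cmcf(sheet, flow_config(delta_t = 10, max_iters = 8))
  amp <- vapply(res$snapshots, function(v) max(abs(v[, 1])), 0)
  expect_true(all(diff(amp) < 1e-9))           # monotone decay
  expect_lt(amp[length(amp)], 0.5 * amp[1])
  bnd <- cellwrap:::boundary_vertices(sheet)
  final <- res$snapshots[[length(res$snapshots)]]
  expect_lt(max(abs(final[bnd, 2:3] - verts[bnd, 2:3])), 1e-8)
  # an already-flat sheet is a fixed point
  flat <- sheet; flat$vertices[, 1] <- 0
  resf <- topographic_cmcf(flat, flow_config(delta_t = 10, max_iters = 3))
  expect_lt(max(abs(resf$snapshots[[4]][, 1])), 1e-10)
})
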