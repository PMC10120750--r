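test_that("equirectangular chart of the unit sphere matches the analytic map", {
  param <- identity_sphere_param(24)
  uv <- uv_map(param, N = 64)
  N <- 64; cols <- 128
  theta <- (seq_len(N) - 0.5) / N * pi
  phi <- (seq_len(cols) - 0.5) / cols * 2 * pi
  ana <- array(0, c(N, cols, 3))
  ana[, , 1] <- outer(sin(theta), cos(phi))
  ana[, , 2] <- outer(sin(theta), sin(phi))
  ana[, , 3] <- matrix(cos(theta), N, cols)
  expect_lt(max(abs(uv$xyz_lookup - ana)), 1e-3)
  expect_equal(uv$n_fallback, 0)
  # barycentric weights are a convex combination
  expect_true(all(uv$bary$mu >= 0))
  expect_equal(as.vector(uv$bary$mu[, , 1] + uv$bary$mu[, , 2] +
                         uv$bary$mu[, , 3]),
               rep(1, N * cols), tolerance = 1e-9)
})

test_that("seam-duplicated grids repeat the first column", {
  param <- identity_sphere_param(12)
  uv <- uv_map(param, N = 32, seam_duplicate = TRUE)
  expect_equal(uv$cols, 65L)
  expect_equal(uv$xyz_lookup[, 1, ], uv$xyz_lookup[, 65, ], tolerance = 1e-9)
})

test_that("pullback interpolates fields exactly for constants and blends others", {
  param <- identity_sphere_param(16)
  uv <- uv_map(param, N = 48)
  const <- pullback_field(uv, rep(2.5, nrow(param$sphere_vertices)))
  expect_equal(range(const), c(2.5, 2.5))
  zfield <- pullback_field(uv, param$sphere_vertices[, 3])
  theta <- (seq_len(48) - 0.5) / 48 * pi
  expect_equal(rowMeans(zfield), cos(theta), tolerance = 1e-2)
  expect_error(pullback_field(uv, rep(1, 10)), "length")
})

test_that("pixel -> 3D -> pixel round trips land within one pixel", {
  param <- identity_sphere_param(20)
  uv <- uv_map(param, N = 64)
  set.seed(11)
  rr <- sample(2:63, 40, replace = TRUE)
  cc <- sample(1:128, 40, replace = TRUE)
  pts <- t(vapply(seq_along(rr), function(i) uv$xyz_lookup[rr[i], cc[i], ],
                  numeric(3)))
  back <- uv_coords_of_directions(pts, uv)
  expect_lt(max(abs(back[, 1] - rr)), 1)
  expect_lt(max(abs(back[, 2] - cc)), 1)
})

test_that("weighted PCA picks the axis orthogonal to a weighted band", {
  param <- identity_sphere_param(20)
  v <- param$sphere_vertices
  # weight concentrated on the equatorial band of the x-y plane
  w <- exp(-v[, 3]^2 / 0.05)
  rf <- optimal_axis(param, w)
  expect_equal(abs(unname(rf$R[3, 3])), 1, tolerance = 1e-2)  # e3 ~ +/- z
  expect_equal(det(rf$R), 1, tolerance = 1e-9)
  # uniform weights on a symmetric sphere: degenerate, identity fallback
  expect_warning(rfu <- optimal_axis(param, rep(1, nrow(v))), "degenerate")
  expect_equal(rfu$R, diag(3))
  expect_error(optimal_axis(param, rep(0, nrow(v))), "non-negative")
})

test_that("total differential area is invariant under the rotation frame", {
  spec <- phantom_spec(base_radius = 10, mesh_k = 14, seed = 9,
                       n_protrusions = 2)
  ph <- make_cell_mesh(spec)
  sp <- conformal_sphere_map(ph)
  uv1 <- uv_map(sp, N = 48)
  w <- abs(ph$vertices[, 3])
  uv2 <- uv_map(sp, N = 48, rotation = optimal_axis(sp, w))
  a1 <- uv_jacobian_metrics(uv1)$total_area
  a2 <- uv_jacobian_metrics(uv2)$total_area
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("curvature-weighted rotation moves a polar bleb toward the equator", {
  spec <- phantom_spec(base_radius = 12, mesh_k = 16, seed = 0,
                       protrusions = list(list(kind = "bleb",
                                               center_direction = c(0, 0, 1),
                                               height = 4, width = 0.5)))
  ph <- make_cell_mesh(spec)
  sp <- conformal_sphere_map(ph)
  w <- ifelse(ph$vertex_fields$gt_label > 0, 1, 1e-3)
  rf <- optimal_axis(sp, w)
  uv <- uv_map(sp, N = 48, rotation = rf)
  # bleb centroid latitude after rotation: away from the poles
  bleb_dir <- colMeans(sp$sphere_vertices[ph$vertex_fields$gt_label > 0, ])
  bleb_dir <- bleb_dir / sqrt(sum(bleb_dir^2))
  lat <- abs(90 - acos(abs(sum(bleb_dir * rf$R[, 3]))) * 180 / pi)
  expect_lt(lat, 45)
})
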