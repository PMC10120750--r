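test_that("outward propagation reproduces analytic offset spheres", {
  fx <- sphere_space_fixture()
  ts <- fx$ts
  for (k in c(4, 8, 12)) {
    sl <- matrix(ts$lookup[ts$d_zero_index + k, , , ], ncol = 3)
    r <- sqrt(rowSums(sweep(sl, 2, fx$ctr)^2))
    expect_lt(max(abs(r - (20 + k * ts$alpha))), 0.5)
  }
  # d = 0 slice equals the reference UV lookup bit-identically
  expect_identical(ts$lookup[ts$d_zero_index, , , ], fx$uv$xyz_lookup)
  # no self-crossing trajectories on the sphere phantom
  expect_equal(ts$n_nonmonotone, 0)
})

test_that("the space encapsulates the cell and D_out covers protrusion height", {
  fx <- sphere_space_fixture()
  # cell radius 26, reference radius 20: need D_out * alpha >= 6
  expect_gte(fx$ts$D_out * fx$ts$alpha, 6)
  tb <- resample_volume(fx$ts, fx$cellb)
  # reference slice lies inside the cell everywhere
  expect_true(all(tb[fx$ts$d_zero_index, , ] > 0.5))
  # top slice lies outside
  expect_true(all(tb[dim(tb)[1], , ] < 0.5))
})

test_that("volume resampling is exact for constants and localizes shells", {
  fx <- sphere_space_fixture()
  const <- volume_image(array(3.7, dim(fx$cellb$data)))
  rc <- resample_volume(fx$ts, const)
  # exact wherever the lookup stays inside the sampled grid (the outermost
  # sheets may leave it; those samples are 0 and counted)
  inner <- fx$ts$d_zero_index + (-16):16
  expect_equal(range(rc[inner, , ]), c(3.7, 3.7))
  # bright shell 3 voxels outside the reference -> band at d = +3/alpha
  co <- as.matrix(expand.grid(1:61, 1:61, 1:61)) - 1
  rad <- sqrt(rowSums(sweep(co, 2, fx$ctr)^2))
  shell <- array(exp(-(rad - 23)^2 / 2), c(61, 61, 61))
  rs <- resample_volume(fx$ts, volume_image(shell))
  prof <- apply(rs, 1, mean)
  expect_equal(which.max(prof) - fx$ts$d_zero_index, 3 / fx$ts$alpha,
               tolerance = 1)
})

test_that("coordinate round trips are sub-voxel and outsiders are flagged", {
  fx <- sphere_space_fixture()
  ts <- fx$ts
  dm <- dim(ts$lookup)
  # exact round trip on lookup nodes
  nodes <- rbind(c(0, 10, 20), c(5, 30, 100), c(-3, 50, 60))
  xyz <- topo_to_cartesian(nodes, ts)
  expect_equal(cartesian_to_topo(xyz, ts), nodes, tolerance = 1e-6,
               ignore_attr = TRUE)
  set.seed(2)
  pts <- cbind(runif(40, -ts$D_in + 1, ts$D_out - 1), runif(40, 4, 59),
               runif(40, 4, 123))
  xyz2 <- topo_to_cartesian(pts, ts)
  back <- cartesian_to_topo(xyz2, ts)
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 1)
  # a Cartesian point far outside the space is flagged
  far <- cartesian_to_topo(rbind(c(200, 200, 200)), ts)
  expect_true(1 %in% attr(far, "outside"))
  out_duv <- topo_to_cartesian(rbind(c(999, 10, 10)), ts)
  expect_true(1 %in% attr(out_duv, "outside"))
})

test_that("signed distance increases monotonically along every trajectory", {
  fx <- sphere_space_fixture()
  ts <- fx$ts
  phiv <- ts$phi
  set.seed(3)
  cols <- sample(ts$cols, 20)
  rows <- sample(ts$rows, 20)
  for (i in seq_len(20)) {
    traj <- ts$lookup[, rows[i], cols[i], ]
    phis <- sample_volume(phiv, traj)
    expect_gt(min(diff(phis)), 0)
  }
})

test_that("topographic meshing recovers a flat sheet for a smooth cell", {
  fx <- sphere_space_fixture()
  tb <- (resample_volume(fx$ts, fx$cellb) >= 0.5) * 1
  tm <- topographic_mesh(tb, fx$ts, target_fraction = 0.5)
  d <- tm$mesh$vertices[, 1]
  # cell is a sphere r=26 with reference r=20: surface at d ~ 12 steps
  expect_equal(median(d), 12, tolerance = 1.5)
  expect_lt(sd(d), 1)
  # Cartesian twin sits on the r=26 sphere
  r <- sqrt(rowSums(sweep(tm$cartesian_twin$vertices, 2, fx$ctr)^2))
  expect_equal(median(r), 26, tolerance = 0.8)
})
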