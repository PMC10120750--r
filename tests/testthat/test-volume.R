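test_that("distance transform and signed distance behave analytically", {
  b <- ball_binary(10)
  edt <- distance_transform(b)
  ctr <- (dim(b$data) + 1) / 2
  # distance from the corner to the ball surface
  corner_dist <- sqrt(sum((ctr - 1)^2)) - 10
  expect_equal(edt[1, 1, 1], corner_dist, tolerance = 0.3)
  phi <- signed_distance(b)
  expect_lt(phi[ctr[1], ctr[2], ctr[3]], 0)   # negative inside
  expect_gt(phi[1, 1, 1], 0)
  expect_equal(signed_distance(b, inside = "positive"), -phi)
})

test_that("hole filling and component labelling work on constructed volumes", {
  a <- array(0, c(15, 15, 15))
  a[4:12, 4:12, 4:12] <- 1
  a[6:10, 6:10, 6:10] <- 0        # internal cavity
  filled <- binary_fill_holes(a)
  expect_true(all(filled[6:10, 6:10, 6:10]))
  expect_false(filled[1, 1, 1])
  a2 <- array(0, c(12, 12, 12))
  a2[2:4, 2:4, 2:4] <- 1
  a2[8:10, 8:10, 8:10] <- 1
  expect_equal(max(label_components_3d(a2)), 2)
})

test_that("mean curvature from the SDF matches 1/r on balls and 0 on slabs", {
  for (r in c(10, 20)) {
    b <- ball_binary(r)
    H <- mean_curvature_from_sdf(b)
    shell <- abs(signed_distance(b)) < 1.2
    expect_equal(mean(H[shell]), 1 / r, tolerance = 0.1)  # within 10%
  }
  # scale law: H halves when the radius doubles
  H10 <- mean_curvature_from_sdf(ball_binary(10))
  s10 <- abs(signed_distance(ball_binary(10))) < 1.2
  H20 <- mean_curvature_from_sdf(ball_binary(20))
  s20 <- abs(signed_distance(ball_binary(20))) < 1.2
  expect_equal(mean(H10[s10]) / mean(H20[s20]), 2, tolerance = 0.1)
  slab <- array(0, c(30, 30, 30))
  slab[, , 1:15] <- 1
  Hs <- mean_curvature_from_sdf(slab)
  face <- abs(signed_distance(slab)) < 1.2
  face[, , c(1:3, 28:30)] <- FALSE   # ignore the volume border
  face[c(1:3, 28:30), , ] <- FALSE
  face[, c(1:3, 28:30), ] <- FALSE
  expect_lt(mean(abs(Hs[face])), 0.02)
})

test_that("voxelization encloses the analytic volume and closes small holes", {
  ic <- icosphere(20, 15)
  ic$vertices <- sweep(ic$vertices, 2, -c(25, 25, 25))
  vol <- voxelize(ic, dilation_radius = 5)
  expect_equal(sum(vol$data), 4 / 3 * pi * 15^3, tolerance = 0.05)
  # dilation/erosion nearly cancel on a watertight mesh
  vol0 <- voxelize(ic, dilation_radius = 0)
  expect_equal(sum(vol0$data), sum(vol$data), tolerance = 0.03)
  # a punched hole is closed by the morphological pass
  spec <- phantom_spec(base_radius = 14, mesh_k = 20, seed = 3,
                       n_protrusions = 0, defects = list(holes = 1))
  holey <- make_cell_mesh(spec)
  expect_false(euler_genus(holey)$watertight)
  volh <- voxelize(holey, dilation_radius = 3)
  expect_gt(sum(volh$data), 0.9 * 4 / 3 * pi * 14^3)
})

test_that("remesh yields deterministic, watertight, near-equilateral genus-0 meshes", {
  b <- ball_binary(10)
  m1 <- remesh(b, 0.5)
  eg <- euler_genus(m1)
  expect_true(eg$watertight)
  expect_equal(eg$genus, 0)
  expect_gt(median(radius_ratio(m1)), 0.7)
  m2 <- remesh(b, 0.5)
  expect_identical(m1$vertices, m2$vertices)   # deterministic seeding
  expect_error(remesh(b, 1.2), "target_fraction")
  # Gauss-Bonnet on the remeshed surface
  expect_equal(sum(gaussian_curvature(m1)), 4 * pi, tolerance = 1e-5)
})

test_that("bumpy phantom remesh conserves volume against its binary", {
  spec <- small_phantom_spec()
  vol <- voxelize(make_cell_mesh(spec), 5)
  m <- remesh(vol, 0.5)
  expect_equal(mesh_volume(m), sum(vol$data), tolerance = 0.03)
})

test_that("trilinear sampling is exact for linear fields and flags outsiders", {
  a <- array(0, c(8, 8, 8))
  co <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  a[] <- 2 * co[, 1] + 3 * co[, 2] - co[, 3]
  v <- volume_image(a)
  pts <- rbind(c(2.5, 3.25, 1.75), c(0, 0, 0), c(20, 1, 1))
  s <- sample_volume(v, pts, fill = -99)
  expect_equal(s[1], 2 * 2.5 + 3 * 3.25 - 1.75, tolerance = 1e-12)
  expect_equal(s[3], -99)
  expect_equal(attr(s, "n_outside"), 1L)
})
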