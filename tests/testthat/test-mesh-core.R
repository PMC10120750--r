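test_that("OBJ and PLY round-trips preserve geometry and fields", {
  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  fo <- tempfile(fileext = ".obj")
  write_mesh(tet, fo)
  back <- read_mesh(fo)
  expect_identical(back$vertices, tet$vertices)
  expect_identical(back$faces, tet$faces)

  # PLY with a per-vertex quality field written by the test
  fp <- tempfile(fileext = ".ply")
  tet$vertex_fields$quality <- c(0.1, 0.5, 0.9, 1.3)
  write_mesh(tet, fp)
  back2 <- read_mesh(fp)
  expect_equal(back2$vertex_fields$quality, tet$vertex_fields$quality)
  expect_identical(back2$faces, tet$faces)

  # malformed OBJ names the offending line
  fb <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0", "v 0 1 0", "f 1 2 3"), fb)
  expect_error(read_mesh(fb), "malformed")
})

test_that("radius ratio is 1 for equilateral, matches formula, ~0 for slivers", {
  eq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                     rbind(c(1, 2, 3)))
  expect_equal(radius_ratio(eq), 1, tolerance = 1e-12)

  # right isoceles, legs 1,1: r_in = (a+b-c)/2, r_circ = c/2
  ri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3)))
  r_in <- (1 + 1 - sqrt(2)) / 2
  r_circ <- sqrt(2) / 2
  expect_equal(radius_ratio(ri), 2 * r_in / r_circ, tolerance = 1e-12)

  sliver <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1e-3, 0)),
                         rbind(c(1, 2, 3)), drop_degenerate = FALSE)
  expect_lt(radius_ratio(sliver), 0.05)
})

test_that("Gaussian curvature satisfies Gauss-Bonnet and local deficits", {
  ic <- icosphere(12, 1)
  expect_equal(sum(gaussian_curvature(ic)), 4 * pi, tolerance = 1e-6)

  # closed unit cube, diagonals arranged so vertex 1 keeps three right angles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- surface_mesh(v, f)
  K <- gaussian_curvature(cube)
  expect_equal(sum(K), 4 * pi, tolerance = 1e-9)
  expect_equal(K[1], pi / 2, tolerance = 1e-9)

  tor <- torus_mesh()
  expect_equal(sum(gaussian_curvature(tor)), 0, tolerance = 1e-6)
})

test_that("euler_genus classifies closed, holed and handled surfaces", {
  ic <- icosphere(8, 1)
  eg <- euler_genus(ic)
  expect_equal(eg$chi, 2)
  expect_equal(eg$genus, 0)
  expect_true(eg$watertight)

  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4)))
  eg2 <- euler_genus(tet)    # one face removed: a single triangular hole
  expect_equal(eg2$chi, 1)
  expect_equal(eg2$genus, 0)
  expect_equal(eg2$n_boundaries, 1)
  expect_false(eg2$watertight)

  eg3 <- euler_genus(torus_mesh())
  expect_equal(eg3$chi, 0)
  expect_equal(eg3$genus, 1)
})

test_that("cotangent operators have the expected structure", {
  # two equilateral triangles sharing an edge: cotangent weight on the
  # shared edge is (cot60 + cot60)/2 = 1/sqrt(3)
  pair <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                             c(0.5, -sqrt(3) / 2, 0)),
                       rbind(c(1, 2, 3), c(1, 4, 2)))
  ops <- build_operators(pair)
  expect_equal(ops$L[1, 2], 1 / sqrt(3), tolerance = 1e-12)
  expect_lt(max(abs(Matrix::rowSums(ops$L))), 1e-12)

  ic <- icosphere(10, 1)
  ops2 <- build_operators(ic)
  # barycentric mass: trace equals total surface area
  expect_equal(sum(Matrix::diag(ops2$M)), mesh_area(ic), tolerance = 1e-9)
  # L annihilates constants
  expect_lt(max(abs(ops2$L %*% rep(1, nrow(ic$vertices)))), 1e-10)
})

test_that("mesh gradient is exact for linear fields", {
  ic <- icosphere(8, 1)
  g <- mesh_gradient(ic, ic$vertices[, 1] * 2 + 1)
  # gradient of 2x restricted to each face is the tangential part of (2,0,0)
  n <- face_normals(ic)
  expected <- cbind(2 - 2 * n[, 1] * n[, 1], -2 * n[, 1] * n[, 2],
                    -2 * n[, 1] * n[, 3])
  expect_equal(g, expected, tolerance = 1e-9)
})
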