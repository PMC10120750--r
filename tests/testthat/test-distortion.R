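flat_grid_mesh <- function(nx = 6, ny = 6) {
  g <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny)))
  id <- function(i, j) (j - 1) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i, j + 1)),
               c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(cbind(g, 0), f, drop_degenerate = FALSE)
}

test_that("conformal error is 1 for similarities and sigma-exact for stretches", {
  m <- flat_grid_mesh()
  expect_equal(face_conformal_error(m, m)$global, 1, tolerance = 1e-12)
  # uniform scaling (and a rigid motion) is conformal but not equiareal-free
  s <- m
  R <- matrix(c(cos(0.7), -sin(0.7), 0, sin(0.7), cos(0.7), 0, 0, 0, 1), 3, 3)
  s$vertices <- 3 * m$vertices %*% R + 5
  ce <- face_conformal_error(m, s)
  expect_equal(ce$global, 1, tolerance = 1e-6)
  # anisotropic stretch diag(2, 1): singular values 2 and 1 everywhere
  a <- m
  a$vertices <- m$vertices %*% diag(c(2, 1, 1))
  ca <- face_conformal_error(m, a)
  expect_equal(unname(ca$per_face), rep(2, nrow(m$faces)), tolerance = 1e-10)
  expect_equal(ca$global, 2, tolerance = 1e-10)
})

test_that("area distortion is scale-free and localizes a doubled face", {
  m <- flat_grid_mesh()
  expect_equal(face_area_distortion(m, m)$global, 1, tolerance = 1e-12)
  s <- m
  s$vertices <- 7 * m$vertices
  expect_equal(face_area_distortion(m, s)$global, 1, tolerance = 1e-12)
  # 4-face strip with one face doubled in relative area in the target
  src <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                            c(0, 1, 0), c(1, 1, 0), c(2, 1, 0)),
                      rbind(c(1, 2, 4), c(2, 5, 4), c(2, 3, 5), c(3, 6, 5)),
                      drop_degenerate = FALSE)
  tgt <- src
  tgt$vertices[3, 1] <- 3; tgt$vertices[6, 1] <- 3  # last two faces widen
  ad <- face_area_distortion(src, tgt)
  aA <- face_areas(src) / sum(face_areas(src))
  aB <- face_areas(tgt) / sum(face_areas(tgt))
  expect_equal(ad$per_face, aA / aB, tolerance = 1e-12)
  expect_equal(ad$area_fraction_ratio, mean(aB / aA), tolerance = 1e-12)
})

test_that("mesh comparison metrics are zero on identity and analytic on offsets", {
  ic <- icosphere(14, 20)
  cmp0 <- compare_meshes(ic, ic)
  expect_equal(cmp0$chamfer, 0)
  expect_lt(cmp0$sliced_wasserstein, 1e-9)
  expect_equal(cmp0$delta_area_pct, 0)
  ic21 <- icosphere(14, 21)
  cmp <- compare_meshes(ic, ic21)
  expect_equal(cmp$chamfer, 2, tolerance = 0.1)   # 1 voxel each direction
  sc <- ic
  sc$vertices <- 1.1 * ic$vertices
  expect_equal(compare_meshes(sc, ic)$delta_area_pct, 21, tolerance = 0.01)
})

test_that("sliced Wasserstein is seed-reproducible with small seed-free spread", {
  ic <- icosphere(10, 10)
  ell <- ic
  ell$vertices <- ic$vertices %*% diag(c(1.5, 1, 1))
  a <- compare_meshes(ic, ell, seed = 42)$sliced_wasserstein
  b <- compare_meshes(ic, ell, seed = 42)$sliced_wasserstein
  expect_identical(a, b)
  vals <- vapply(1:5, function(s)
    compare_meshes(ic, ell, seed = s)$sliced_wasserstein, 0)
  expect_lt(sd(vals) / mean(vals), 0.05)
})

test_that("UV Jacobian metrics recover the sphere's area element", {
  param <- identity_sphere_param(20)
  uv <- uv_map(param, N = 64)
  m <- uv_jacobian_metrics(uv)
  expect_equal(m$total_area, 4 * pi, tolerance = 0.01)
  # dA proportional to sin(polar angle) along a column
  theta <- (seq_len(64) - 0.5) / 64 * pi
  prof <- rowMeans(m$dA)
  expect_gt(cor(prof, sin(theta)), 0.999)
  # area distortion is extreme at the pole rows
  expect_true(which.max(rowMeans(m$lambda)) %in% c(1L, 64L))
  # a flat isometric chart has Q = lambda = 1
  g <- flat_grid_mesh(8, 8)
  look <- array(0, c(7, 7, 3))   # pixel centres of an isometric patch
  look[, , 1] <- matrix(rep(1:7, 7), 7, 7)
  look[, , 2] <- matrix(rep(1:7, each = 7), 7, 7)
  mm <- uv_jacobian_metrics(look)
  inner <- mm$Q[2:6, 2:6]
  expect_equal(as.vector(inner), rep(max(inner), 25), tolerance = 1e-9)
})
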