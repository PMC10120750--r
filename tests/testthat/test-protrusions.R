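test_that("the height image reports the longest contiguous run per column", {
  slab <- array(0, c(20, 6, 8))
  slab[1:10, , ] <- 1
  expect_equal(approximate_height_image(slab), matrix(10, 6, 8))
  col <- array(0, c(20, 1, 1))
  col[c(1:3, 7:11), 1, 1] <- 1     # runs of 3 and 5 separated by a gap
  expect_equal(approximate_height_image(col)[1, 1], 5)
  expect_equal(approximate_height_image(array(0, c(5, 2, 2))),
               matrix(0, 2, 2))
})

test_that("ALS matches a 1D oracle on separable profiles and suppresses spikes", {
  nv <- 48; nu <- 64
  prof <- 10 + 2 * sin(seq(0, 2 * pi, length.out = nv))
  img <- matrix(prof, nv, nu)
  als <- als_reference_surface(img, downsample = 1)
  oracle <- als_1d_oracle(prof)
  inner <- 5:(nv - 5)
  expect_equal(als$d_ref[inner, 10], oracle[inner], tolerance = 0.05)

  # a tall spike barely moves the asymmetric baseline (at the default
  # working resolution, where the regularization is effective)
  spiky <- img
  spiky[20:24, 30:34] <- 30
  als2 <- als_reference_surface(spiky)
  expect_lt(max(als2$d_ref[20:24, 30:34]) - max(img[20:24, 30:34]), 2)

  # two-level terrain: the baseline tracks the lower envelope smoothly
  terr <- matrix(5, nv, nu)
  terr[, 33:64] <- 12
  als3 <- als_reference_surface(terr, downsample = 1)
  expect_lt(mean(als3$d_ref[, 1:28]), 6.5)
  expect_equal(als_reference_surface(matrix(4, nv, nu),
                                     downsample = 1)$d_ref,
               matrix(4, nv, nu), tolerance = 1e-6)
})

test_that("3-class Otsu thresholds separate well-separated modes", {
  set.seed(12)
  x <- c(rnorm(300, 0, 0.3), rnorm(300, 5, 0.3), rnorm(300, 10, 0.3))
  truth <- rep(1:3, each = 300)
  th <- otsu_thresholds(x, 3)
  expect_lt(th[1], th[2])
  pred <- findInterval(x, th) + 1
  expect_gt(mean(pred == truth), 0.95)
  y <- c(rnorm(300, 0, 0.3), rnorm(300, 5, 0.3))
  th2 <- otsu_thresholds(y, 2)
  expect_gt(mean((y > th2) == rep(c(FALSE, TRUE), each = 300)), 0.95)
})

test_that("label spreading never invents labels and respects clamping", {
  ic <- icosphere(8, 1)
  A <- cellwrap:::mesh_affinity(ic)
  seeds <- integer(nrow(ic$vertices))
  seeds[1] <- 3L; seeds[300] <- 7L
  out <- label_spread(A, seeds, n_iter = 10)
  expect_true(all(out %in% c(0L, 3L, 7L)))
  expect_equal(out[1], 3L)
  expect_equal(out[300], 7L)
})

test_that("binary segmentation is empty on a flat noisy sheet", {
  set.seed(13)
  nv <- 24; nu <- 36
  g <- as.matrix(expand.grid(v = seq_len(nv), u = seq_len(nu)))
  verts <- cbind(rnorm(nrow(g), 0, 0.02), g[, 1] - 1, g[, 2] - 1)
  id <- function(i, j) (j - 1) * nv + i
  f <- NULL
  for (j in seq_len(nu - 1)) for (i in seq_len(nv - 1)) {
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i, j + 1)),
               c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  sheet <- surface_mesh(verts, f, drop_degenerate = FALSE)
  expect_warning(out <- binary_protrusions(sheet, NULL), "empty")
  expect_true(all(out == 0L))
})

test_that("segmentation recovers every planted bleb exactly once", {
  fx <- seg_pipeline()
  inst <- fx$seg$instances$vertex_labels
  labs <- setdiff(unique(inst), 0L)
  expect_length(labs, 5)
  # every instance maps onto exactly one ground-truth bleb
  nn <- cellwrap:::.cpp_nn_index(fx$res$topo_mesh$cartesian_twin$vertices,
                                 fx$mesh$vertices)$index
  gtt <- fx$mesh$vertex_fields$gt_label[nn]
  hits <- vapply(labs, function(l) {
    tt <- table(gtt[inst == l & gtt > 0])
    as.integer(names(tt)[which.max(tt)])
  }, 0L)
  expect_setequal(hits, 1:5)
  # instances are connected on the mesh graph
  for (l in labs) {
    cs <- cellwrap:::mesh_subset_components(fx$res$topo_mesh$mesh, inst == l)
    expect_equal(length(cs$areas), 1)
  }
})

test_that("a flat cMCF reference under-segments relative to the ALS reference", {
  fx <- seg_pipeline()
  tm <- fx$res$topo_mesh
  bin_als <- fx$seg$binary
  bin_flat <- binary_protrusions(tm, NULL, affinity_config(n_iter = 5),
                                 min_area_initial = 12, min_area_final = 31)
  n_comp <- function(b) {
    if (!any(b > 0)) return(0L)
    length(cellwrap:::mesh_subset_components(tm$mesh, b > 0)$areas)
  }
  expect_lte(n_comp(bin_flat), n_comp(bin_als))
})

test_that("volume decomposition partitions the cell and keeps cortex smooth", {
  fx <- seg_pipeline()
  dec <- decompose_volume(fx$res$topo_space, fx$res$topo_binary,
                          fx$res$topo_mesh, fx$seg$instances$vertex_labels)
  total <- sum(fx$res$topo_binary)
  expect_equal((dec$cortex_volume + sum(dec$volumes)) / total, 1,
               tolerance = 0.02)
  expect_length(dec$volumes, 5)
  # labelled voxels sit at or above the reference (internal exclusion rule)
  lab_idx <- which(dec$protrusion_labels > 0, arr.ind = TRUE)
  dref_at <- dec$d_ref[cbind(lab_idx[, 2], lab_idx[, 3])]
  expect_gt(mean(lab_idx[, 1] - 1 >= dref_at - 1), 0.95)
})
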