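test_that("phantoms are reproducible and carry correct topology", {
  spec <- phantom_spec(base_radius = 12, mesh_k = 12, seed = 5,
                       n_protrusions = 5)
  m1 <- make_cell_mesh(spec)
  m2 <- make_cell_mesh(spec)
  expect_identical(m1$vertices, m2$vertices)
  expect_equal(length(setdiff(unique(m1$vertex_fields$gt_label), 0L)), 5)
  expect_equal(euler_genus(m1)$genus, 0)
  expect_true(attr(m1, "watertight"))

  hole <- make_cell_mesh(phantom_spec(base_radius = 12, mesh_k = 12, seed = 5,
                                      n_protrusions = 0,
                                      defects = list(holes = 1)))
  expect_false(euler_genus(hole)$watertight)
  expect_false(attr(hole, "watertight"))

  handle <- make_cell_mesh(phantom_spec(base_radius = 12, mesh_k = 12,
                                        seed = 5, n_protrusions = 0,
                                        defects = list(handle = TRUE)))
  expect_equal(euler_genus(handle)$genus, 1)
})

test_that("overlapping protrusions are rejected unless explicitly allowed", {
  pr <- list(list(kind = "bleb", center_direction = c(1, 0, 0), height = 3,
                  width = 0.5),
             list(kind = "bleb", center_direction = c(cos(0.6), sin(0.6), 0),
                  height = 3, width = 0.5))
  expect_error(phantom_spec(protrusions = pr), "overlapping")
  expect_s3_class(phantom_spec(protrusions = pr, allow_overlap = TRUE),
                  "phantom_spec")
  expect_error(phantom_spec(protrusions = list(list(kind = "blob"))),
               "unknown protrusion kind")
})

test_that("synthetic volumes place shells and couple intensity to curvature", {
  spec <- phantom_spec(base_radius = 12, mesh_k = 14, seed = 6,
                       n_protrusions = 2)
  out <- make_volume(spec, channels = c("binary", "shell", "curved_shell"),
                     shell_depth = 0, shell_sigma = 1)
  expect_true(all(out$binary$data %in% c(0, 1)))
  # shell at depth 0 peaks on the surface voxels
  surf <- out$binary$data != 0 & !cellwrap:::binary_erode(out$binary$data, 1.5)
  interior <- cellwrap:::binary_erode(out$binary$data, 4)
  expect_gt(mean(out$shell$data[surf]), 5 * mean(out$shell$data[interior]))
  # curvature-coupled channel correlates with H on the shell
  H <- mean_curvature_from_sdf(out$binary)
  sel <- surf & is.finite(H)
  expect_gt(cor(H[sel], out$curved_shell$data[sel] / out$shell$data[sel]),
            0.5)
})

test_that("bleb movies expose ground-truth periodicity and bleaching", {
  spec <- phantom_spec(base_radius = 14, mesh_k = 10, seed = 7,
                       n_protrusions = 3)
  mv <- make_bleb_movie(spec, n_frames = 30, period = 10, N = 32)
  expect_length(mv$meshes, 30)
  expect_length(mv$event_times, 3)
  # each bleb sees ~3 crests in 30 frames at period 10
  expect_true(all(vapply(mv$event_times, length, 0L) == 3))
  # static movie when the spec oscillation collapses: constant labels
  expect_identical(mv$uv_labels[[1]], mv$uv_labels[[11]])
  mvb <- make_bleb_movie(spec, n_frames = 10, period = 10, N = 32,
                         bleach_rate = 0.2)
  means <- vapply(mvb$uv_H, mean, 0)
  expect_equal(means[6] / means[1], exp(-0.2 * 5), tolerance = 0.15)
  expect_error(make_bleb_movie(spec, period = 3), "period")
})
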