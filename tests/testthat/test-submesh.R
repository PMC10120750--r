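test_that("submesh extraction and disk/square unwrapping are bijective", {
  ic <- icosphere(20, 10)
  cap <- extract_submesh(ic, ic$vertices[, 3] > 3)
  expect_equal(euler_genus(cap)$n_boundaries, 1)
  sq <- unwrap_submesh_to_square(cap, N = 64)
  expect_equal(sq$n_flipped, 0)
  expect_lt(abs(sq$lambda - 1), 0.1)
  # a flat disk unwraps nearly isometrically
  flat <- cap
  flat$vertices[, 3] <- 0
  sqf <- unwrap_submesh_to_square(flat, N = 64)
  expect_equal(sqf$lambda, 1, tolerance = 0.02)
  expect_equal(sqf$n_flipped, 0)
  # rasterization covers the full square for a disk-like patch
  r <- square_raster(sq, cap$vertices[, 3])
  expect_gt(mean(!is.na(r)), 0.95)
  # multiple boundary loops are rejected with a count
  two_holes <- extract_submesh(ic, abs(ic$vertices[, 3]) < 8)
  expect_error(unwrap_submesh_to_square(two_holes), "boundar")
})

test_that("a tall thin spike relaxes after the downsample fallback", {
  spec <- phantom_spec(base_radius = 14, mesh_k = 24, seed = 4,
                       protrusions = list(list(kind = "spike",
                                               center_direction = c(0, 0, 1),
                                               height = 14, width = 0.5)))
  ph <- make_cell_mesh(spec)
  spike <- extract_submesh(ph, ph$vertices[, 3] > 15)
  expect_equal(euler_genus(spike)$n_boundaries, 1)
  sq <- unwrap_submesh_to_square(spike, N = 64)
  expect_equal(sq$n_flipped, 0)
  expect_lt(abs(sq$lambda - 1), 0.1)
})

test_that("watershed refinement splits fused blebs and passes clean ones", {
  sep <- 0.62
  spec <- phantom_spec(base_radius = 20, mesh_k = 30, seed = 5,
                       allow_overlap = TRUE,
                       protrusions = list(
                         list(kind = "bleb", center_direction = c(1, 0, 0),
                              height = 6, width = 0.45),
                         list(kind = "bleb",
                              center_direction = c(cos(sep), sin(sep), 0),
                              height = 6, width = 0.45)))
  ph <- make_cell_mesh(spec)
  fused <- as.integer(ph$vertex_fields$gt_label > 0)
  expect_length(cellwrap:::mesh_subset_components(ph, fused > 0)$areas, 1)
  H <- as.numeric(mean_curvature_from_sdf(ph))
  ref <- refine_blebs(ph, fused, H)
  expect_length(setdiff(unique(ref), 0L), 2)
  # total labelled area conserved within 15%
  va <- cellwrap:::face_to_vertex_area(ph)
  expect_equal(sum(va[ref > 0]) / sum(va[fused > 0]), 1, tolerance = 0.15)

  # a single clean bleb goes through unchanged
  spec1 <- phantom_spec(base_radius = 20, mesh_k = 24, seed = 6,
                        n_protrusions = 1)
  ph1 <- make_cell_mesh(spec1)
  l1 <- as.integer(ph1$vertex_fields$gt_label > 0)
  r1 <- refine_blebs(ph1, l1, as.numeric(mean_curvature_from_sdf(ph1)))
  expect_length(setdiff(unique(r1), 0L), 1)
})

test_that("Cartesian decomposition closes protrusions with bending caps", {
  spec <- phantom_spec(base_radius = 20, mesh_k = 30, seed = 7,
                       n_protrusions = 2)
  ph <- make_cell_mesh(spec)
  cd <- cartesian_decompose(ph, ph$vertex_fields$gt_label)
  expect_length(cd$protrusions, 2)
  expect_length(cd$skipped, 0)
  for (m in cd$protrusions) {
    eg <- euler_genus(m)
    expect_true(eg$watertight)
    expect_gt(mesh_volume(m), 0)
  }
  # hemisphere-like boundary: cap area at least the disk of the loop
  sub <- extract_submesh(ph, ph$vertex_fields$gt_label == 1)
  loop <- cellwrap:::boundary_loop_order(sub)[[1]]
  bv <- sub$vertices[loop, ]
  ctr <- colMeans(bv)
  rad <- mean(sqrt(rowSums(sweep(bv, 2, ctr)^2)))
  cap <- cellwrap:::bending_cap(sub)
  expect_gte(mesh_area(cap), 0.95 * pi * rad^2)
  # a planar loop gets a flat (zero-bending) cap
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  cone <- surface_mesh(rbind(cbind(cos(th), sin(th), 0), c(0, 0, 1)),
                       cbind(1:32, c(2:32, 1), 33), drop_degenerate = FALSE)
  flatcap <- cellwrap:::bending_cap(cone)
  expect_lt(max(abs(flatcap$vertices[, 3])), 1e-9)
})
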