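test_that("a sphere maps to itself with conformal error 1 and no flips", {
  ic <- icosphere(16, 3)
  sp <- conformal_sphere_map(ic)
  expect_equal(sp$conformal_error, 1, tolerance = 1e-3)
  expect_equal(sp$n_flipped, 0)
  expect_equal(sqrt(rowSums(sp$sphere_vertices^2)),
               rep(1, nrow(sp$sphere_vertices)), tolerance = 1e-9)
  expect_identical(sp$faces, ic$faces)
})

test_that("spherical parameterization refuses non-genus-0 input", {
  expect_error(conformal_sphere_map(torus_mesh()), "genus-0")
  tet_open <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(0, 0, 1)),
                           rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4)))
  expect_error(conformal_sphere_map(tet_open), "genus-0")
})

test_that("an ellipsoid maps quasi-conformally with pole area shrinkage", {
  ic <- icosphere(16, 1)
  ell <- surface_mesh(sweep(ic$vertices, 2, c(2, 1, 1), "*"), ic$faces)
  sp <- conformal_sphere_map(ell)
  expect_lt(sp$conformal_error, 1.05)
  expect_equal(sp$n_flipped, 0)
  lam <- face_area_distortion(ell, sphere_mesh(sp))$per_face
  # tips (|x| large) are area-compressed on the sphere: lambda far from 1
  bc <- abs(ell$vertices[ell$faces[, 1], 1])
  tip <- bc > quantile(bc, 0.9)
  expect_gt(median(lam[tip]), 2 * median(lam[!tip]))
})

test_that("equiareal relaxation reaches lambda ~ 1 bijectively", {
  ic <- icosphere(16, 1)
  ell <- surface_mesh(sweep(ic$vertices, 2, c(2, 1, 1), "*"), ic$faces)
  sp <- conformal_sphere_map(ell)
  rel <- relax_area_distortion(sp, relax_config(max_iters = 60))
  expect_equal(rel$area_distortion, 1, tolerance = 1e-2)
  expect_equal(rel$n_flipped, 0)
  expect_false(rel$collapsed)
  # bijectivity held at every accepted iterate
  for (s in rel$snapshots) {
    cand <- structure(list(sphere_vertices = s, faces = rel$faces),
                      class = "sphere_param")
    expect_equal(cellwrap:::count_flipped(cand), 0)
  }
  # the trade-off: lambda error shrinks while Q grows along the trajectory
  tr <- rel$relax_trace
  expect_lt(tail(tr$equiareal_obj, 1), tr$equiareal_obj[1])
  expect_gte(tail(tr$Q, 1), tr$Q[1] * 0.98)
})

test_that("an already-equiareal parameterization barely moves", {
  param <- identity_sphere_param(16)
  rel <- relax_area_distortion(param, relax_config(max_iters = 5))
  disp <- sqrt(rowSums((rel$sphere_vertices - param$sphere_vertices)^2))
  expect_lt(max(disp), 0.05 * mean_edge_length(sphere_mesh(param)))
})

test_that("stopping objectives behave as expected across the trajectory", {
  param <- identity_sphere_param(12)
  met <- evaluate_stopping_criteria(param)
  expect_equal(met$mips, 2, tolerance = 1e-6)      # analytic MIPS minimum
  expect_equal(met$lambda, 1, tolerance = 1e-6)
  ic <- icosphere(14, 1)
  ell <- surface_mesh(sweep(ic$vertices, 2, c(1.6, 1, 1), "*"), ic$faces)
  sp <- conformal_sphere_map(ell)
  rel <- relax_area_distortion(sp, relax_config(max_iters = 60))
  tr <- rel$relax_trace
  # MIPS is minimal at iteration 0 (the conformal map)
  mips0 <- evaluate_stopping_criteria(sp)$mips
  expect_lte(mips0, min(tr$mips) + 1e-6)
  # the isometric objective dips in the interior of the trajectory
  iso_path <- c((1 - 0.5) * sp$conformal_error + 0.5 * log(
    face_area_distortion(ell, sphere_mesh(sp))$global), tr$isometric)
  expect_lt(min(iso_path), iso_path[1])
  expect_lte(min(tr$isometric), tail(tr$isometric, 1))
})
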