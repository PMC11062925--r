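test_that("generation is fully deterministic under a fixed seed", {
  a <- make_patient(synthetic_patient_config(seed = 11,
                                             lv = list(nu = 18, nv = 9,
                                                       nw = 2)))
  b <- make_patient(synthetic_patient_config(seed = 11,
                                             lv = list(nu = 18, nv = 9,
                                                       nw = 2)))
  expect_identical(a$mesh$nodes, b$mesh$nodes)
  expect_identical(a$mesh$tets, b$mesh$tets)
  expect_identical(a$mesh$nodal_mbf, b$mesh$nodal_mbf)
  expect_identical(a$tree$segments, b$tree$segments)
  expect_identical(a$true_flows, b$true_flows)
})

test_that("the LV shell mesh is valid and near the analytic volume", {
  cfg <- synthetic_patient_config(seed = 1)
  mesh <- make_lv_mesh(cfg)
  expect_true(all(tet_volumes(mesh) > 0))
  expect_gte(nrow(mesh$nodes), 500)
  # doubling resolution changes the volume by < 2% (shape convergence)
  cfg2 <- synthetic_patient_config(seed = 1,
                                   lv = list(nu = 48, nv = 24, nw = 6))
  v1 <- mesh_volume(mesh)
  v2 <- mesh_volume(make_lv_mesh(cfg2))
  expect_lt(abs(v1 - v2) / v2, 0.02)
  expect_error(make_lv_mesh(synthetic_patient_config(
    lv = list(thickness = -1))), "thickness")
})

test_that("the epicardial tree satisfies its construction contracts", {
  cfg <- synthetic_patient_config(seed = 3, n_lv_outlets = 2,
                                  lv = list(nu = 18, nv = 9, nw = 2))
  mesh <- make_lv_mesh(cfg)
  tree <- make_epicardial_tree(cfg, mesh)
  seg <- tree$segments
  lv_leaves <- tree$outlet_ids[seg$perfuses_lv[match(tree$outlet_ids,
                                                     seg$id)]]
  expect_equal(length(lv_leaves), 2)
  expect_gte(length(tree$outlet_ids) - length(lv_leaves), 1)

  # LV outlets lie on the outer ellipsoid surface
  pts <- outlet_points(tree, lv_only = TRUE)
  g <- cfg$lv
  r <- (pts[, "x"]^2 + pts[, "y"]^2) / g$a^2 + pts[, "z"]^2 / g$c^2
  expect_true(all(abs(r - 1) < 1e-9))

  # radii never increase down the tree
  pat <- fix_patient()
  seg <- pat$tree$segments
  pr <- match(seg$parent, seg$id)
  has_par <- !is.na(pr)
  expect_true(all(seg$radius[has_par] <= seg$radius[pr[has_par]] + 1e-12))
})

test_that("ground-truth flows reduce to Murray at sigma 0 and diverge at 0.4", {
  pat <- fix_patient()
  cfg0 <- synthetic_patient_config(seed = 1, sigma = 0)
  fl0 <- make_ground_truth_flows(cfg0, pat$tree, pat$map$v_lv)
  seg <- pat$tree$segments
  ids <- names(fl0)
  d <- 2 * seg$radius[match(as.integer(ids), seg$id)]
  murray <- d^2.6 / sum(d^2.6)
  expect_equal(unname(attr(fl0, "fractions")), murray, tolerance = 1e-12)
  expect_equal(sum(attr(fl0, "fractions")), 1, tolerance = 1e-12)
  # total equals the morphometric rule
  expect_equal(sum(fl0), morphometric_q_lv(pat$map$v_lv) / 60,
               tolerance = 1e-12)

  cfg4 <- synthetic_patient_config(seed = 1, sigma = 0.4)
  fl4 <- make_ground_truth_flows(cfg4, pat$tree, pat$map$v_lv)
  dev <- abs(attr(fl4, "fractions") - murray) / murray
  expect_gt(mean(dev), 0.10)
})

test_that("the MBF field integrates back to the true flows", {
  pat <- fix_patient()
  mb <- integrate_mbf(pat$mesh, pat$map)
  expect_equal(mb$territory_flow[names(pat$true_flows)],
               pat$true_flows, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mb$q_lv, sum(pat$true_flows), tolerance = 1e-10)

  # zero noise: one MBF value per territory
  cfg <- synthetic_patient_config(seed = 5, mbf_noise_cv = 0,
                                  lv = list(nu = 18, nv = 9, nw = 2))
  p0 <- make_patient(cfg)
  for (i in p0$map$outlet_ids) {
    vals <- p0$mesh$nodal_mbf[p0$map$nodal_label == i]
    expect_lt(diff(range(vals)), 1e-9 * max(vals))
  }
})

test_that("generated patients satisfy the downstream preconditions", {
  pat <- fix_patient()
  expect_equal(sum(pat$map$flow_fraction), 1, tolerance = 1e-12)
  expect_true(all(pat$map$territory_volume > 0))
  expect_true(all(pat$mesh$nodal_mbf >= 0))
  expect_equal(sum(pat$map$territory_volume), pat$map$v_lv,
               tolerance = 1e-9)
  expect_s3_class(pat$targets, "clinical_targets")
  expect_true(validate_tree(pat$tree))
})
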