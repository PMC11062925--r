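# brute-force nearest-outlet scan (the oracle the Voronoi assignment must
# reproduce, including the lowest-id tie-break)
brute_force_labels <- function(nodes, outlets) {
  ids <- as.integer(rownames(outlets))
  vapply(seq_len(nrow(nodes)), function(i) {
    d <- sqrt(colSums((t(outlets) - nodes[i, ])^2))
    ids[which(d <= min(d) + 0)[1]]
  }, integer(1))
}

test_that("Voronoi assignment matches the brute-force oracle", {
  mesh <- fix_patient()$mesh
  for (seed in 1:3) {
    set.seed(seed)
    n_out <- sample(2:6, 1)
    outlets <- mesh$nodes[sample(nrow(mesh$nodes), n_out), , drop = FALSE]
    rownames(outlets) <- sort(sample(0:99, n_out))
    map <- assign_territories(mesh, outlets)
    expect_identical(map$nodal_label, brute_force_labels(mesh$nodes, outlets))
  }
})

test_that("degenerate and tie cases behave as specified", {
  mesh <- unit_cube_mesh(2)
  one <- matrix(c(0.5, 0.5, 0.5), 1, 3, dimnames = list("4", NULL))
  map <- assign_territories(mesh, one)
  expect_true(all(map$nodal_label == 4L))
  expect_error(assign_territories(mesh, one[0, , drop = FALSE]), "outlet")

  # two outlets mirror-symmetric about x = 0.5 on a mesh with no nodes on
  # the symmetry plane: equal label counts
  mesh3 <- unit_cube_mesh(3)
  two <- matrix(c(0, 0.5, 0.5, 1, 0.5, 0.5), 2, 3, byrow = TRUE,
                dimnames = list(c("7", "3"), NULL))
  map3 <- assign_territories(mesh3, two)
  expect_equal(sum(map3$nodal_label == 7), sum(map3$nodal_label == 3))
  # nodes exactly equidistant go to the lower id
  map2 <- assign_territories(mesh, two)
  on_plane <- abs(mesh$nodes[, 1] - 0.5) < 1e-12
  expect_true(any(on_plane))
  expect_true(all(map2$nodal_label[on_plane] == 3L))
})

test_that("territory volumes are conservative", {
  pat <- fix_patient()
  vols <- territory_volumes(pat$mesh, pat$map)
  expect_equal(sum(vols), mesh_volume(pat$mesh), tolerance = 1e-12)

  one <- matrix(colMeans(pat$mesh$nodes), 1, 3, dimnames = list("0", NULL))
  m1 <- assign_territories(pat$mesh, one)
  expect_equal(unname(territory_volumes(pat$mesh, m1)),
               mesh_volume(pat$mesh), tolerance = 1e-12)

  # half-space split of a uniform cube: close to half the volume each,
  # checked against a per-tet brute-force tally of control volumes
  mesh <- unit_cube_mesh(4)
  two <- matrix(c(0.25, 0.5, 0.5, 0.75, 0.5, 0.5), 2, 3, byrow = TRUE,
                dimnames = list(c("0", "1"), NULL))
  mp <- assign_territories(mesh, two)
  v <- territory_volumes(mesh, mp)
  cv <- node_control_volumes(mesh)
  expect_equal(unname(v["0"]), sum(cv[mp$nodal_label == 0]))
  # within one tet layer of half (the tie plane goes to the lower id)
  expect_lt(abs(unname(v["0"]) - 0.5), 0.15)
})

test_that("MBF integration uses the stated unit conversion and is linear", {
  mesh <- unit_cube_mesh(3)   # 1 mL cube
  one <- matrix(c(.5, .5, .5), 1, 3, dimnames = list("0", NULL))
  map <- assign_territories(mesh, one)
  mbf <- rep(100, nrow(mesh$nodes))  # 100 mL/min/100mL
  out <- integrate_mbf(mesh, map, mbf)
  # 100/100 * V / 60 with V = 1 mL
  expect_equal(out$q_lv, 1 / 60, tolerance = 1e-12)
  out2 <- integrate_mbf(mesh, map, 2 * mbf)
  expect_equal(out2$q_lv, 2 * out$q_lv, tolerance = 1e-12)
  expect_equal(unname(integrate_mbf(mesh, map, 0 * mbf)$territory_flow), 0)
  expect_error(integrate_mbf(mesh, map, NULL), "MBF")
})

test_that("flow fractions normalize and reject zero totals", {
  expect_equal(unname(flow_fractions(c(a = 1, b = 1))), c(0.5, 0.5))
  expect_equal(unname(flow_fractions(c(a = 3, b = 1))), c(0.75, 0.25))
  f1 <- flow_fractions(c(a = 2, b = 6, c = 2))
  expect_equal(f1, flow_fractions(10 * c(a = 2, b = 6, c = 2)))
  expect_equal(sum(f1), 1, tolerance = 1e-12)
  expect_error(flow_fractions(c(a = 0, b = 0)), "positive")
})

test_that("centerline metric gives a valid alternative partition", {
  pat <- fix_small_patient()
  map <- assign_territories(pat$mesh, outlet_points(pat$tree),
                            metric = "centerline", tree = pat$tree)
  expect_true(all(map$nodal_label %in% map$outlet_ids))
  expect_error(assign_territories(pat$mesh, outlet_points(pat$tree),
                                  metric = "centerline"), "tree")
})
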