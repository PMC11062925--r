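test_that("beta parameterization matches the hand-evaluated closed form", {
  b <- make_betas(q_lv = 2, v_lv = 100, p_src_bar = 25, p_cap = 15,
                  p_snk = 0)
  expect_equal(b$beta_src, 2 / (100 * 10 * 1333.22), tolerance = 1e-12)
  expect_equal(b$beta_snk, 2 / (100 * 15 * 1333.22), tolerance = 1e-12)
  # algebraic identity
  expect_equal(b$beta_src / b$beta_snk, 15 / 10, tolerance = 1e-12)
  b2 <- make_betas(4, 100, 25)
  expect_equal(b2$beta_src, 2 * b$beta_src, tolerance = 1e-12)
  expect_error(make_betas(2, 100, 10), "p_src_bar > p_cap")
})

test_that("source fields are piecewise constant with the right mean", {
  pat <- fix_patient()
  map <- pat$map
  ids <- map$outlet_ids
  set.seed(4)
  p_out <- setNames(stats::runif(length(ids), 20, 40), ids)
  fld <- build_source_field(map, p_out)
  expect_equal(length(unique(fld)), length(ids))
  wmean <- sum(p_out * map$territory_volume[as.character(ids)]) / map$v_lv
  cv <- node_control_volumes(pat$mesh)
  expect_equal(sum(fld * cv) / sum(cv), wmean, tolerance = 1e-12)
  expect_error(build_source_field(map, p_out[-1]), "cover")

  one <- build_source_field(map, setNames(rep(30, length(ids)), ids))
  expect_true(all(one == 30))
})

test_that("a uniform source at the mean gives p = p_cap and MBF = Q_LV", {
  pat <- fix_patient()
  map <- pat$map
  betas <- make_betas(map$q_lv, map$v_lv, p_src_bar = 25)
  ps <- build_source_field(map, setNames(rep(25, length(map$outlet_ids)),
                                         map$outlet_ids))
  sol <- solve_darcy(pat$mesh, ps, betas)
  expect_equal(sol$p, rep(15, length(sol$p)), tolerance = 1e-8)
  mb <- compute_mbf(sol, map)
  expect_equal(mb$total, map$q_lv, tolerance = 1e-8)
  expect_equal(sum(mb$territory_flow), mb$total, tolerance = 1e-12)
})

test_that("the discrete maximum principle and diffusion limits hold", {
  pat <- fix_patient()
  map <- pat$map
  ids <- map$outlet_ids
  set.seed(9)
  p_out <- setNames(stats::runif(length(ids), 18, 45), ids)
  ps <- build_source_field(map, p_out)
  p_bar <- sum(p_out * map$territory_volume[as.character(ids)]) / map$v_lv
  betas <- make_betas(map$q_lv, map$v_lv, p_bar)
  sol <- solve_darcy(pat$mesh, ps, betas)
  expect_true(all(sol$p > min(0, min(p_out)) - 1e-9))
  expect_true(all(sol$p < max(p_out) + 1e-9))

  # very large permeability flattens the field to one constant
  sol_inf <- solve_darcy(pat$mesh, ps, betas, k = 2e5)
  expect_lt(diff(range(sol_inf$p)), 1e-3)

  # global source-sink balance under zero-flux boundaries
  bal <- darcy_balance(sol)
  expect_lt(bal$imbalance, 1e-8)
})

test_that("the FEM converges at second order on a manufactured solution", {
  k <- 2e-5
  k_cgs <- k / 10
  b <- list(beta_src = 2e-6, beta_snk = 1.5e-6)
  errs <- vapply(c(4, 8), function(n) {
    mesh <- unit_cube_mesh(n)
    x <- mesh$nodes
    p_star <- cos(pi * x[, 1]) * cos(pi * x[, 2]) * cos(pi * x[, 3])
    forcing <- (3 * k_cgs * pi^2 + b$beta_src + b$beta_snk) * p_star
    sol <- solve_darcy(mesh, rep(0, nrow(x)), b, k = k, forcing = forcing)
    cv <- node_control_volumes(mesh)
    sqrt(sum(cv * (sol$p_cgs - p_star)^2) / sum(cv))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3.0)  # ~4 for second order
})

test_that("per-territory MBF integrates the density additively", {
  pat <- fix_patient()
  map <- pat$map
  ids <- map$outlet_ids
  p_out <- setNames(seq(20, 35, length.out = length(ids)), ids)
  p_bar <- sum(p_out * map$territory_volume[as.character(ids)]) / map$v_lv
  sol <- solve_darcy(pat$mesh, build_source_field(map, p_out),
                     make_betas(map$q_lv, map$v_lv, p_bar))
  mb <- compute_mbf(sol, map)
  expect_equal(sum(mb$territory_flow), mb$total, tolerance = 1e-12)
  expect_equal(mb$nodal_mbf, mb$nodal_density * 6000, tolerance = 1e-12)
  bal <- darcy_balance(sol)
  expect_equal(mb$total, bal$inflow, tolerance = 1e-12)
})
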