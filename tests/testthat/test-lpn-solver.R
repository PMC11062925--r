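test_that("an RC Windkessel matches the analytic exponential decay", {
  R <- 1000; C <- 1e-3; p0 <- 100 * 1333.22
  net <- lpn_network(period = 1)
  net <- net_add_element(net, "Rd", "R", "n1", "GND", R = R)
  net <- net_add_capacitor(net, "C1", "n1", C = C)
  res <- simulate_lpn(net, n_cycles_max = 1L, dt = 1 / 2000,
                      y0 = c(p0, 0))
  p_num <- res$pressures[, "n1"]
  p_ana <- p0 * exp(-res$time / (R * C))
  expect_lt(max(abs(p_num - p_ana)) / p0, 0.005)

  # driven by a constant inflow the pressure settles at Q R
  net2 <- lpn_network(period = 1)
  net2 <- net_add_element(net2, "src", "qsource", "GND", "n1", p1 = 5)
  net2 <- net_add_element(net2, "Rd", "R", "n1", "GND", R = R)
  net2 <- net_add_capacitor(net2, "C1", "n1", C = C)
  res2 <- simulate_lpn(net2, n_cycles_max = 15L, dt = 1 / 500)
  expect_equal(unname(res2$pressures[nrow(res2$pressures), "n1"]), 5 * R,
               tolerance = 1e-3)
})

test_that("steady solves are exact and linear", {
  net <- lpn_network()
  net <- net_add_element(net, "src", "psource", "a", "GND", p1 = 100)
  net <- net_add_element(net, "R1", "R", "a", "b", R = 30)
  net <- net_add_element(net, "R2", "R", "b", "GND", R = 70)
  s <- steady_solve(net)
  expect_equal(s$pressures[["b"]], 70)
  expect_equal(s$flows[["R1"]], 1)

  # superposition of two sources
  net2 <- lpn_network()
  net2 <- net_add_element(net2, "s1", "psource", "a", "GND", p1 = 50)
  net2 <- net_add_element(net2, "R1", "R", "a", "b", R = 10)
  net2 <- net_add_element(net2, "s2", "qsource", "GND", "b", p1 = 2)
  net2 <- net_add_element(net2, "R2", "R", "b", "GND", R = 20)
  both <- steady_solve(net2)
  only1 <- net2; only1$elements$p1[3] <- 0
  only2 <- net2; only2$elements$p1[1] <- 0
  s1 <- steady_solve(only1); s2 <- steady_solve(only2)
  expect_equal(both$pressures, s1$pressures + s2$pressures,
               tolerance = 1e-12)
  expect_error(steady_solve(assemble_closed_loop(default_lpn_params())),
               "chamber")
})

test_that("steady solve agrees with cycle-averaged integration on a coronary
           block with constant intramyocardial pressure", {
  net <- lpn_network(period = 0.8)
  net <- net_add_element(net, "src", "psource", "o", "GND", p1 = 1.2e5)
  bc <- data.frame(outlet_id = 1, R_a = 2e4, R_mu = 5e4, R_v = 1e4,
                   C_a = 1e-7, C_im = 8e-7, im_ref = NA_character_,
                   im_scale = 0, stringsAsFactors = FALSE)
  net <- attach_outlet_bcs(net, c("1" = "o"), bc)
  s <- steady_solve(net)
  res <- simulate_lpn(net, n_cycles_max = 10L, dt = 0.8 / 500)
  expect_lt(abs(mean_flows(res)[["Ra_1"]] - s$flows[["Ra_1"]]) /
              s$flows[["Ra_1"]], 0.03)
})

test_that("zero activation yields a quiescent circulation", {
  p <- default_lpn_params()
  for (nm in c("E_max_lv", "E_max_rv", "E_max_la", "E_max_ra")) {
    p[[nm]] <- p[[sub("max", "min", nm)]]
  }
  net <- assemble_closed_loop(p)
  res <- simulate_lpn(net, n_cycles_max = 80L, dt = net$period / 400,
                      periodicity_tol = 1e-5)
  expect_lt(abs(res$mean_flow[["aortic_valve"]]), 0.05)
})

test_that("halving the time step moves sbp by less than 0.2 mmHg", {
  net <- assemble_closed_loop(default_lpn_params())
  m1 <- simulate_lpn(net, dt = net$period / 2000)$metrics
  m2 <- simulate_lpn(net, dt = net$period / 4000)$metrics
  expect_lt(abs(m1$sbp - m2$sbp), 0.2)
})

test_that("cardiac metrics satisfy their identities", {
  net <- assemble_closed_loop(default_lpn_params())
  res <- simulate_lpn(net, dt = net$period / 1000)
  m <- res$metrics
  expect_equal(m$ejection_fraction * m$edv, m$stroke_volume,
               tolerance = 1e-12)
  expect_equal(m$stroke_volume, m$edv - m$esv, tolerance = 1e-12)
  # cardiac output equals mean aortic flow within 1%
  expect_lt(abs(m$cardiac_output - m$mean_aortic_flow * 60 / 1000) /
              m$cardiac_output, 0.01)
  expect_gt(m$sbp, m$dbp)
})

test_that("FFR is 1 on a lossless path, monotone on passive branches, and
           flags below 0.80", {
  # near-zero resistance: huge radii
  df <- data.frame(id = 0:1, parent = c(NA, 0L), x0 = 0, y0 = 0,
                   z0 = c(2, 1), x1 = 0, y1 = 0, z1 = c(1, 0),
                   radius = 5, origin = "image_based", perfuses_lv = TRUE)
  tree <- vessel_tree(df, root = 0L)
  frag <- build_rcl_from_tree(tree)
  net <- lpn_network()
  net$elements <- frag$elements
  net <- net_add_element(net, "src", "psource", frag$inlet_node, "GND",
                         p1 = 1e5)
  net <- net_add_element(net, "Rd", "R", frag$outlet_nodes[["1"]], "GND",
                         R = 1e5)
  s <- steady_solve(net)
  names(s$pressures)[names(s$pressures) == frag$inlet_node] <- "AO"
  ffr <- compute_ffr(s, tree, frag$seg_nodes, 1, aortic_node = "AO")
  expect_true(all(abs(ffr$ffr - 1) < 1e-6))
  expect_false(attr(ffr, "positive"))
  expect_equal(ffr$s[1], 0)
  expect_equal(ffr$s[nrow(ffr)], 1)

  # monotone non-increasing along a real hyperemic path
  pat <- fix_small_patient()
  net2 <- build_patient_network(fix_params(pat), pat$tree,
                                fix_murray(pat)$shares)
  hyper <- apply_hyperemia(net2)
  sn <- coronary_steady_network(hyper, 90 * 1333.22)
  sol <- steady_solve(sn)
  out <- pat$map$outlet_ids[1]
  ffr2 <- compute_ffr(sol, pat$tree, net2$meta$seg_nodes, out)
  expect_true(all(diff(ffr2$ffr) <= 1e-12))

  # a fabricated solution with a deep distal drop is flagged positive
  fake <- s
  fake$pressures[frag$seg_nodes[["1"]]] <- 0.7 * 1e5
  ffr3 <- compute_ffr(fake, tree, frag$seg_nodes, 1, aortic_node = "AO")
  expect_true(attr(ffr3, "positive"))
  expect_error(compute_ffr(s, tree, c("0" = "nope", "1" = "nope2"), 1,
                           aortic_node = "AO"), "path")
})
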