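test_that("segment RCL values match the hand-evaluated formulas", {
  rcl <- segment_rcl(length = 1, radius = 0.1)
  expect_equal(rcl$R, 8 * 0.04 * 1 / (pi * 0.1^4))
  expect_equal(rcl$R, 1018.59, tolerance = 1e-5)
  expect_equal(rcl$L, 1.06 * 1 / (pi * 0.01))
  expect_equal(rcl$L, 33.7408, tolerance = 1e-5)
  expect_equal(rcl$C, 3 * pi * 0.1^3 * 1 / (2 * 1.15e7 * 0.01))
  expect_error(segment_rcl(1, 0), "radius")
})

test_that("series/parallel reductions match hand values", {
  expect_equal(series_resistance(c(100, 250)), 350)
  expect_equal(parallel_resistance(c(100, 100)), 50)
  # two identical segments in series double the resistance
  df <- data.frame(id = 0:1, parent = c(NA, 0L),
                   x0 = 0, y0 = 0, z0 = c(2, 1), x1 = 0, y1 = 0,
                   z1 = c(1, 0), radius = 0.1, origin = "synthetic",
                   perfuses_lv = TRUE)
  tree <- vessel_tree(df, root = 0L, validate = FALSE)
  r1 <- segment_rcl(1, 0.1)$R
  expect_equal(tree_equivalent_resistance(tree, c("1" = 0)), 2 * r1,
               tolerance = 1e-12)
})

test_that("a single-path 0D tree equals the sum of Poiseuille resistances", {
  pat <- fix_small_patient()
  tree <- pat$tree
  frag <- build_rcl_from_tree(tree)
  net <- lpn_network()
  net$elements <- frag$elements
  p_in <- 100 * 1333.22
  net <- net_add_element(net, "src", "psource", frag$inlet_node, "GND",
                         p1 = p_in)
  # ground every outlet through a known resistance
  for (o in tree$outlet_ids) {
    net <- net_add_element(net, paste0("Rd", o), "R",
                           frag$outlet_nodes[[as.character(o)]], "GND",
                           R = 5e5)
  }
  sol <- steady_solve(net)
  q_in <- -sol$flows[["src"]]  # source flow is directed into ground
  r_eq <- tree_equivalent_resistance(
    tree, setNames(rep(5e5, length(tree$outlet_ids)), tree$outlet_ids))
  expect_equal(p_in / q_in, r_eq, tolerance = 1e-10)
})

test_that("coronary outlet blocks are Ohmic in steady state with the stated
           microvascular observable", {
  net <- lpn_network()
  net <- net_add_element(net, "src", "psource", "o", "GND", p1 = 1e5)
  bc <- data.frame(outlet_id = 7, R_a = 1000, R_mu = 2500, R_v = 500,
                   C_a = 1e-7, C_im = 8e-7, im_ref = NA_character_,
                   im_scale = 0, stringsAsFactors = FALSE)
  net <- attach_outlet_bcs(net, c("7" = "o"), bc)
  sol <- steady_solve(net)
  q <- sol$flows[["Ra_7"]]
  expect_equal(q, 1e5 / 4000, tolerance = 1e-12)
  # P_mu = P - Q R_a
  expect_equal(sol$pressures[["mu_7"]], 1e5 - q * 1000, tolerance = 1e-9)
  expect_error(attach_outlet_bcs(net, c("8" = "o"), bc), "outlets")
})

test_that("the closed loop conserves blood volume and reaches periodicity", {
  net <- assemble_closed_loop(default_lpn_params())
  res <- simulate_lpn(net, dt = net$period / 1000)
  expect_true(res$converged)
  expect_lt(utils::tail(res$conv_history, 1), 1e-3)

  # total stored volume (capacitors + chambers) is constant in time
  cp <- net$capacitors
  vol_t <- rowSums(res$volumes)
  for (k in seq_len(nrow(cp))) {
    pn <- res$pressures[, cp$node[k]]
    pref <- if (is.na(cp$ref_node[k])) 0 else
      cp$ref_scale[k] * res$pressures[, cp$ref_node[k]]
    vol_t <- vol_t + cp$C[k] * (pn - pref)
  }
  expect_lt(diff(range(vol_t)) / mean(vol_t), 1e-8)
})

test_that("flow is conserved at junctions at every recorded step", {
  pat <- fix_small_patient()
  net <- build_patient_network(fix_params(pat), pat$tree,
                               fix_murray(pat)$shares)
  res <- simulate_lpn(net, n_cycles_max = 4L, dt = net$period / 400)
  # node balance at the last backward-Euler step: flows in minus flows out
  # equals the storage rate of attached capacitors and chamber volumes
  el <- net$elements
  cp <- net$capacitors
  ch <- net$chambers
  n <- nrow(res$flows)
  dt <- res$dt
  flows <- res$flows[n, ]
  nodes <- setdiff(unique(c(el$node_a, el$node_b)), "GND")
  for (nd in nodes) {
    qin <- sum(flows[el$name[el$node_b == nd]])
    qout <- sum(flows[el$name[el$node_a == nd]])
    storage <- 0
    for (k in which(cp$node == nd)) {
      pref_n <- if (is.na(cp$ref_node[k])) c(0, 0) else
        cp$ref_scale[k] * res$pressures[(n - 1):n, cp$ref_node[k]]
      pn <- res$pressures[(n - 1):n, nd]
      storage <- storage + cp$C[k] * diff(pn - pref_n) / dt
    }
    for (k in which(ch$node == nd)) {
      storage <- storage + diff(res$volumes[(n - 1):n, ch$name[k]]) / dt
    }
    expect_lt(abs(qin - qout - storage), 1e-6 * max(abs(qin), 1))
  }
})

test_that("removing the coronary branch changes aortic flow by less than the
           coronary flow itself", {
  pat <- fix_small_patient()
  p <- fix_params(pat)
  mur <- fix_murray(pat)
  net_with <- build_patient_network(p, pat$tree, mur$shares, reduce = TRUE)
  res_with <- simulate_lpn(net_with, dt = net_with$period / 800)
  q_cor <- res_with$mean_flow[["creq_seg"]]
  net_wo <- assemble_closed_loop(p)
  res_wo <- simulate_lpn(net_wo, dt = net_wo$period / 800)
  d_co <- abs(res_with$metrics$mean_aortic_flow -
                res_wo$metrics$mean_aortic_flow)
  expect_gt(q_cor, 0)
  expect_lt(d_co, q_cor)
})

test_that("intramyocardial pressure shifts coronary inflow out of systole", {
  # the printed total coronary capacitance makes the effect weak, so the
  # mechanism is exercised with an enlarged intramyocardial compliance
  pat <- fix_small_patient()
  p <- fix_params(pat)
  p$C_cor_total <- 3e-5
  mur <- fix_murray(pat)
  p0 <- p; p0$im_scale_l <- 0; p0$im_scale_r <- 0
  net_im <- build_patient_network(p, pat$tree, mur$shares, reduce = TRUE)
  net_no <- build_patient_network(p0, pat$tree, mur$shares, reduce = TRUE)
  r_im <- simulate_lpn(net_im, dt = net_im$period / 800)
  r_no <- simulate_lpn(net_no, dt = net_no$period / 800)
  systole <- r_im$time < 0.35 * net_im$period
  sys_share <- function(r) {
    q <- r$flows[, "Ra_eq"]
    sum(q[systole]) / sum(q)
  }
  expect_lt(sys_share(r_im), sys_share(r_no))
  # chamber-pressure transmission raises the intramyocardial node swing
  amp <- function(r) diff(range(r$pressures[, "v_eq"]))
  expect_gt(amp(r_im), amp(r_no))
})

test_that("the stenosis element adds a quadratic loss", {
  net <- lpn_network()
  net <- net_add_element(net, "src", "qsource", "GND", "a", p1 = 10)
  net <- net_add_element(net, "st", "stenosis", "a", "GND", R = 100,
                         p1 = 2)
  res <- simulate_lpn(net, n_cycles_max = 2L, dt = 0.01,
                      y0 = c(0, 10, 10))
  p_fin <- unname(res$pressures[nrow(res$pressures), "a"])
  expect_equal(p_fin, 100 * 10 + 2 * 100, tolerance = 1e-6)
})
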