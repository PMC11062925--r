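test_that("initialization rules reproduce the printed constants", {
  tg <- preset_targets(2)
  init <- initialization_rules(tg, v_lv = 100)
  map_cgs <- (73 + (137 - 73) / 3) * 1333.22
  co <- tg$cardiac_output * 1000 / 60
  expect_equal(init$R_total, map_cgs / co, tolerance = 1e-12)
  expect_equal(morphometric_q_lv(1), 3.41)
  expect_equal(init$q_lv, 3.41 * 100^0.75 / 60, tolerance = 1e-12)
  expect_equal(init$q_nonlv / init$q_lv, 0.2, tolerance = 1e-12)
  expect_equal(init$ra_rmu_ratio, 0.38)
  expect_equal(init$murray_exponent, 2.6)
  expect_equal(init$hyperemia_factor, 0.24)
  expect_equal(init$C_aortic_total, 0.28e-3)
  expect_equal(init$C_cor_total, 1e-6)
})

test_that("Murray outlet resistances split flow as diameter^2.6", {
  d <- c(a = 0.2, b = 0.1)
  lvf <- c(a = TRUE, b = TRUE)
  mur <- murray_outlet_resistances(d, lvf, R_cor_total = 5e4, lv_share = 1)
  expect_equal(unname(mur$shares["a"] / mur$shares["b"]), 2^2.6,
               tolerance = 1e-12)
  expect_equal(parallel_resistance(mur$R), 5e4, tolerance = 1e-9)

  deq <- c(a = 0.15, b = 0.15, c = 0.15)
  mur2 <- murray_outlet_resistances(deq, c(a = TRUE, b = TRUE, c = TRUE),
                                    1e4, lv_share = 1)
  expect_equal(unname(mur2$R), rep(3e4, 3), tolerance = 1e-9)

  # grouped: non-LV outlets share 20% of the LV flow
  d3 <- c(a = 0.2, b = 0.2, r = 0.2)
  mur3 <- murray_outlet_resistances(d3, c(a = TRUE, b = TRUE, r = FALSE),
                                    1e4)
  expect_equal(unname(sum(mur3$shares[c("a", "b")]) / mur3$shares[["r"]]),
               5, tolerance = 1e-12)
})

test_that("hyperemia scales distal coronary resistance by exactly 0.24", {
  net <- lpn_network()
  net <- net_add_element(net, "src", "psource", "o", "GND", p1 = 1e5)
  bc <- data.frame(outlet_id = 1, R_a = 400, R_mu = 450, R_v = 150,
                   C_a = 1e-7, C_im = 8e-7, im_ref = NA_character_,
                   im_scale = 0, stringsAsFactors = FALSE)
  net <- attach_outlet_bcs(net, c("1" = "o"), bc)
  before <- with(net$meta$coronary_bcs, R_a + R_mu + R_v)
  h <- apply_hyperemia(net)
  after <- with(h$meta$coronary_bcs, R_a + R_mu + R_v)
  expect_equal(after / before, 0.24, tolerance = 1e-15)
  expect_equal(after, 240, tolerance = 1e-12)  # baseline total was 1000

  expect_warning(apply_hyperemia(h), "already")
  restored <- apply_hyperemia(h, factor = 1 / 0.24)
  expect_equal(restored$meta$coronary_bcs$R_a, bc$R_a, tolerance = 1e-12)
  expect_equal(with(restored$meta$coronary_bcs, R_a + R_mu + R_v), before,
               tolerance = 1e-12)
  ident <- apply_hyperemia(net, factor = 1)
  expect_equal(ident$elements$R, net$elements$R, tolerance = 1e-15)
})

test_that("flow targets follow the stated formulas in both modes", {
  pat <- fix_patient()
  map <- pat$map
  tg <- build_flow_targets(map, pat$tree, map$v_lv, mode = "mpi")
  q_lv <- morphometric_q_lv(map$v_lv) / 60
  expect_equal(sum(tg$q_reqd), q_lv, tolerance = 1e-12)
  expect_equal(unname(tg$q_reqd / q_lv),
               unname(map$flow_fraction[as.character(map$outlet_ids)]),
               tolerance = 1e-12)

  # Eq.-4 inversion: flow proportional to volume gives p_src = p_src_bar
  map_u <- map
  map_u$flow_fraction <- map$territory_volume / sum(map$territory_volume)
  tg_u <- build_flow_targets(map_u, pat$tree, map$v_lv, mode = "mpi",
                             p_src_bar = 25)
  expect_equal(unname(tg_u$p_src), rep(25, length(map$outlet_ids)),
               tolerance = 1e-9)
  # and the volume-weighted mean is always the stated p_src_bar
  wm <- sum(tg$p_src * map$territory_volume[as.character(map$outlet_ids)]) /
    map$v_lv
  expect_equal(wm, 25, tolerance = 1e-9)

  tgm <- build_flow_targets(map, pat$tree, map$v_lv, mode = "murray")
  seg <- pat$tree$segments
  d <- 2 * seg$radius[match(map$outlet_ids, seg$id)]
  expect_equal(unname(tgm$fractions), d^2.6 / sum(d^2.6), tolerance = 1e-12)
})

test_that("with-trees loop formulas match their hand evaluations", {
  expect_equal(required_outlet_resistance(1000, 5, 1, 800), 4200)
  expect_equal(dilation_factor(2000, 1250), 1.6^0.25, tolerance = 1e-12)
  expect_equal(dilation_factor(2000, 1250), 1.1247, tolerance = 1e-4)
  expect_error(dilation_factor(2000, -5), "> 0")
})

test_that("nelder_mead minimizes within bounds", {
  fn <- function(x) sum((x - c(0.3, -0.2))^2)
  fit <- nelder_mead(fn, c(0.9, 0.9), lower = c(-1, -1), upper = c(1, 1),
                     tol = 1e-10, maxit = 500)
  expect_equal(fit$par, c(0.3, -0.2), tolerance = 1e-3)
  # bounds respected when the optimum lies outside
  fit2 <- nelder_mead(function(x) sum((x - 2)^2), 0.5, lower = 0,
                      upper = 1, tol = 1e-10, maxit = 200)
  expect_equal(fit2$par, 1, tolerance = 1e-6)
})

test_that("stage-1 recovers self-consistent targets and respects bounds", {
  pat <- fix_small_patient()
  net <- build_patient_network(fix_params(pat), pat$tree,
                               fix_murray(pat)$shares, reduce = TRUE)
  # targets = the model's own forward output at the tuning time step
  res <- simulate_lpn(net, n_cycles_max = 16L, dt = net$period / 500)
  m <- res$metrics
  self_tgt <- clinical_targets(sbp = m$sbp, dbp = m$dbp,
                               stroke_volume = m$stroke_volume,
                               ejection_fraction = m$ejection_fraction,
                               heart_rate = 60 / net$period)
  fit <- stage1_tune(net, self_tgt, restarts = 1, patience = 1, seed = 1)
  expect_lt(min(fit$trace$best), 0.1)
  spec <- default_stage1_spec()
  expect_true(all(fit$params[spec$name] >= spec$lower - 1e-12))
  expect_true(all(fit$params[spec$name] <= spec$upper + 1e-12))
})

test_that("stage-1 reaches the published error level on patient-2 targets", {
  fit <- fix_small_stage1()
  expect_lt(fit$value, 6.84)
  expect_equal(length(fit$per_target), 4)
})

test_that("stage-2 without trees recovers imaged fractions and microvascular
           pressures", {
  pat <- fix_small_patient()
  s1 <- fix_small_stage1()
  mur <- fix_murray(pat)
  net <- build_patient_network(s1$params, pat$tree, mur$shares)
  tg <- build_flow_targets(pat$map, pat$tree, pat$map$v_lv, mode = "mpi")
  s2 <- stage2_no_trees(net, tg, restarts = 3, seed = 1)
  expect_lt(s2$fraction_error, 5)
  expect_lt(s2$pmu_error, 5)

  # the Murray-law model misses the dispersed truth by more
  hyperm <- apply_hyperemia(build_patient_network(s1$params, pat$tree,
                                                  mur$shares))
  resm <- simulate_lpn(hyperm, n_cycles_max = 12L,
                       dt = hyperm$period / 600)
  summ <- outlet_summary(hyperm, resm)
  lv_ids <- names(tg$fractions)
  rows <- match(as.integer(lv_ids), summ$outlet_id)
  f_mur <- summ$Q[rows] / sum(summ$Q[rows])
  err_mur <- mean(abs(f_mur - tg$fractions) / tg$fractions) * 100
  expect_gt(err_mur, s2$fraction_error)

  # total outlet resistance preserved through the rescaling
  bc0 <- apply_hyperemia(net)$meta$coronary_bcs
  bc1 <- s2$network$meta$coronary_bcs
  lvf <- bc0$outlet_id %in% as.integer(lv_ids)
  r0 <- parallel_resistance((bc0$R_a + bc0$R_mu + bc0$R_v)[lvf])
  r1 <- parallel_resistance((bc1$R_a + bc1$R_mu + bc1$R_v)[lvf])
  expect_lt(abs(r1 - r0) / r0, 0.02)

  # fixed point: targets equal to the model's own Murray output
  tg_fix <- tg
  tg_fix$fractions <- setNames(as.numeric(f_mur), lv_ids)
  s2f <- stage2_no_trees(net, tg_fix, restarts = 2, seed = 1)
  expect_lt(s2f$fraction_error, 1)
})

test_that("stage-2 with trees terminates below tolerance on a small patient", {
  pat <- fix_small_patient()
  syn <- grow_synthetic_trees(pat$tree, pat$mesh, pat$map,
                              cco_config(total_terminals = 40, seed = 1))
  fit <- stage2_with_trees(syn$combined, syn$outlet_of_synthetic, pat$map,
                           pat$targets, pat$map$v_lv, mode = "mpi")
  expect_true(fit$converged)
  expect_lte(fit$eps_flow, 0.05)
  expect_lte(fit$eps_pressure, 0.05)
  expect_true(all(fit$outlet_R[as.character(as.integer(
    names(fit$outlet_of_synthetic)))] > 0))
  # error metrics are non-negative and the log tracks the outer loop
  expect_true(all(fit$log$eps_flow >= 0))
  expect_true(all(fit$log$eps_pressure >= 0))
  # total aortic-to-venous resistance stays at its target value
  expect_lt(abs(fit$q_lv * fit$r_tot -
                  mean_arterial_pressure(pat$targets) * 1333.22) /
              (fit$q_lv * fit$r_tot), 0.02)
})
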