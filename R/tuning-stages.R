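#' Bounded Nelder-Mead minimizer
#'
#' Plain Nelder-Mead with box bounds enforced by projection, an initial
#' simplex stepping a fixed fraction of each parameter's range, and
#' convergence when the simplex function-value spread falls below `tol`.
#'
#' @param fn objective, called with a numeric vector.
#' @param x0 start point.
#' @param lower,upper bounds.
#' @param tol function-spread convergence tolerance (default 0.1).
#' @param maxit maximum iterations (default 200).
#' @param step_frac initial simplex step as a fraction of range (default
#'   0.1).
#' @return list `par`, `value`, `evals`, `iterations`, `converged`.
#' @export
nelder_mead <- function(fn, x0, lower, upper, tol = 0.1, maxit = 200,
                        step_frac = 0.1) {
  n <- length(x0)
  clamp <- function(x) pmin(upper, pmax(lower, x))
  rng <- upper - lower
  evals <- 0L
  best_x <- NULL; best_f <- Inf
  # evaluate at the projected point plus a violation penalty, so the
  # simplex keeps volume instead of collapsing onto an active bound
  f <- function(x) {
    evals <<- evals + 1L
    xc <- clamp(x)
    val <- fn(xc)
    if (val < best_f) { best_f <<- val; best_x <<- xc }
    val + 1e4 * sum(((x - xc) / rng)^2)
  }
  simplex <- matrix(rep(x0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) {
    simplex[i + 1, i] <- clamp(x0 + step_frac * rng * (seq_len(n) == i))[i]
    if (simplex[i + 1, i] == simplex[1, i]) {
      simplex[i + 1, i] <- clamp(x0 - step_frac * rng *
                                   (seq_len(n) == i))[i]
    }
  }
  fv <- apply(simplex, 1, f)
  it <- 0L
  converged <- FALSE
  while (it < maxit) {
    it <- it + 1L
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]; fv <- fv[ord]
    if (fv[n + 1] - fv[1] < tol) { converged <- TRUE; break }
    centroid <- colMeans(simplex[1:n, , drop = FALSE])
    xr <- centroid + (centroid - simplex[n + 1, ])
    fr <- f(xr)
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - simplex[n + 1, ])
      fe <- f(xe)
      if (fe < fr) { simplex[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      xc <- centroid + 0.5 * (simplex[n + 1, ] - centroid)
      fc <- f(xc)
      if (fc < fv[n + 1]) { simplex[n + 1, ] <- xc; fv[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          fv[i] <- f(simplex[i, ])
        }
      }
    }
  }
  list(par = best_x, value = best_f, evals = evals,
       iterations = it, converged = converged)
}

#' Default Stage-1 parameter specification
#'
#' The tunable closed-loop parameters governing cardiac function: chamber
#' elastances and LV unstressed volume, activation duration, systemic
#' resistance and compliances, pulmonary resistance, venous filling
#' pressure (which sets the stressed blood volume) and the total distal
#' coronary resistance. Bounds are physiological ranges; the roles mirror
#' the full heart/pulmonary/boundary parameter set of closed-loop coronary
#' LPN models, collapsed to the degrees of freedom that the four
#' cardiac-function targets can identify.
#'
#' @param params baseline parameter list (for initial values).
#' @return data.frame with `name`, `lower`, `upper`, `init`.
#' @export
default_stage1_spec <- function(params = default_lpn_params()) {
  mm <- MMHG_DYNCM2
  spec <- data.frame(
    name = c("E_max_lv", "E_min_lv", "V0_lv", "E_max_rv",
             "R_sys", "C_sys", "C_ao", "p0_ven", "vent_dur_frac", "R_pul"),
    lower = c(0.8 * mm, 0.03 * mm, 0, 0.2 * mm,
              600, 2e-4, 5e-5, 3 * mm, 0.22, 40),
    upper = c(12 * mm, 0.5 * mm, 40, 2.0 * mm,
              6000, 6e-3, 1.5e-3, 22 * mm, 0.45, 500))
  spec$init <- vapply(spec$name, function(nm) params[[nm]], 0)
  spec$init <- pmin(spec$upper, pmax(spec$lower, spec$init))
  spec
}

#' Stage-1 cardiac-function tuning
#'
#' Personalizes the closed-loop model to measured systolic/diastolic
#' pressure, stroke volume and ejection fraction by restarted Nelder-Mead
#' over `param_spec`, minimizing the mean relative error (in percent)
#' across the four targets. Each objective evaluation rebuilds the network
#' and integrates it to periodicity from a cold start at a coarsened time
#' step (the tuned result is re-verified at a fine step). Restarts jitter
#' the incumbent with seeded noise; the restart loop exits early once
#' further restarts stop improving the objective by more than `tol`.
#'
#' @param net a network from [build_patient_network()] (its builder
#'   metadata drives the rebuilds; for speed build it with `reduce = TRUE`).
#' @param targets a `clinical_targets`.
#' @param param_spec data.frame from [default_stage1_spec()]; by default
#'   built from the network's own baseline parameters.
#' @param tol Nelder-Mead convergence tolerance on the objective spread,
#'   in percent (default 0.1).
#' @param maxit iterations per restart (default 200).
#' @param step_frac simplex step as a fraction of range (default 0.1).
#' @param restarts maximum restarts (default 50).
#' @param seed seed for restart jitter.
#' @param dt_frac tuning-time step as a fraction of the period (default
#'   1/500).
#' @param patience restarts without improvement before stopping early
#'   (default 6).
#' @param verbose print restart progress.
#' @return list: tuned `params`, `network`, `value` (mean error, %),
#'   `per_target` errors (%), `metrics`, `trace` (per restart), `evals`.
#' @export
stage1_tune <- function(net, targets, param_spec = NULL,
                        tol = 0.1, maxit = 200, step_frac = 0.1,
                        restarts = 50, seed = 1L, dt_frac = 1 / 500,
                        patience = 6L, verbose = FALSE) {
  base_params <- net$meta$params
  if (is.null(param_spec)) param_spec <- default_stage1_spec(base_params)
  tgt <- c(sbp = targets$sbp, dbp = targets$dbp,
           sv = targets$stroke_volume, ef = targets$ejection_fraction)
  # every evaluation starts cold: in a closed loop the initial state fixes
  # the total blood volume, so warm-starting across parameter sets would
  # sever the link between the filling parameters and the converged state
  eval_params <- function(theta, dt, n_cycles) {
    p <- utils::modifyList(base_params, stats::setNames(as.list(theta),
                                                        param_spec$name))
    nn <- rebuild_network(net, p)
    res <- tryCatch(
      simulate_lpn(nn, n_cycles_max = n_cycles, dt = nn$period * dt,
                   periodicity_tol = 1e-3),
      error = function(e) NULL)
    if (is.null(res) || any(!is.finite(unlist(res$metrics)))) {
      return(list(err = 1e4, per = NULL, res = NULL))
    }
    m <- res$metrics
    sim <- c(sbp = m$sbp, dbp = m$dbp, sv = m$stroke_volume,
             ef = m$ejection_fraction)
    per <- abs(sim - tgt) / tgt * 100
    list(err = mean(per), per = per, res = res, params = p, network = nn)
  }
  objective <- function(theta) eval_params(theta, dt_frac, 16L)$err

  x0 <- param_spec$init
  lower <- param_spec$lower; upper <- param_spec$upper
  best <- list(par = x0, value = Inf)
  trace <- list()
  stall <- 0L
  for (r in seq_len(restarts)) {
    start <- if (r == 1L) x0 else {
      set.seed(seed + r)
      pmin(upper, pmax(lower, best$par +
                         stats::rnorm(length(x0), 0, 0.05 * (upper - lower))))
    }
    fit <- nelder_mead(objective, start, lower, upper, tol = tol,
                       maxit = maxit, step_frac = step_frac)
    improved <- fit$value < best$value - tol
    if (fit$value < best$value) best <- fit
    trace[[r]] <- data.frame(restart = r, value = fit$value,
                             best = best$value, evals = fit$evals)
    if (verbose) {
      message(sprintf("restart %d: %.3f%% (best %.3f%%)", r, fit$value,
                      best$value))
    }
    stall <- if (improved) 0L else stall + 1L
    if (best$value < tol || stall >= patience) break
  }
  # final verification at a finer time step
  final <- eval_params(best$par, 1 / 1500, 25L)
  list(params = final$params, network = final$network,
       value = final$err, per_target = final$per,
       metrics = final$res$metrics, result = final$res,
       trace = do.call(rbind, trace),
       evals = sum(vapply(trace, function(t) t$evals, 0)))
}

# per-outlet LV flow fractions from a solved coronary surrogate
lv_fractions <- function(net, sol, lv_ids) {
  Q <- mean_flows(sol)[paste0("Ra_", lv_ids)]
  q <- stats::setNames(as.numeric(Q), lv_ids)
  q / sum(q)
}

#' Stage-2 flow-distribution tuning without synthetic trees
#'
#' First matches the imaged flow fractions by Nelder-Mead over per-outlet
#' resistance scale factors constrained to \[0.5, 2.0\] and renormalized at
#' every evaluation so the parallel total outlet resistance is preserved;
#' the inner model is the hyperemic steady coronary surrogate. Then the
#' proximal-to-microvascular split R_a/R_mu at each outlet is updated twice
#' directly from pulsatile simulations:
#' `R_a = (P_outlet - p_src) / Q_outlet` holding each outlet's total
#' resistance fixed, driving the simulated microvascular pressure toward
#' the source pressure required by the perfusion model.
#'
#' @param net Stage-1-tuned closed-loop network (rest state, full coronary
#'   fragment).
#' @param flow_targets list from [build_flow_targets()] (`fractions`,
#'   `p_src` over LV outlets).
#' @param hyperemia_factor resistance factor (default 0.24).
#' @param tol,maxit,step_frac,restarts,seed Nelder-Mead settings (defaults
#'   0.1%, 200, 0.1, 50).
#' @param dt_frac pulsatile time step fraction for the R_a/R_mu updates.
#' @param patience early-exit restart patience.
#' @return list: `network` (hyperemic, tuned), `scales`, `fraction_error`
#'   (%), `pmu_error` (%), `summary` (per outlet), `nm` trace.
#' @export
stage2_no_trees <- function(net, flow_targets, hyperemia_factor = 0.24,
                            tol = 0.1, maxit = 200, step_frac = 0.1,
                            restarts = 50, seed = 1L, dt_frac = 1 / 600,
                            patience = 4L) {
  hyper <- apply_hyperemia(net, hyperemia_factor)
  bc <- hyper$meta$coronary_bcs
  lv_flag <- bc$outlet_id %in% names(flow_targets$fractions)
  lv_ids <- bc$outlet_id[lv_flag]
  f_t <- flow_targets$fractions[as.character(lv_ids)]
  # perfusion pressure for the surrogate: the stage-1 model's own MAP
  p_ao <- hyper$meta$params$p0_ao
  steady_net <- coronary_steady_network(hyper, p_ao)
  R0 <- bc$R_a + bc$R_mu + bc$R_v
  names(R0) <- bc$outlet_id
  R_par0 <- parallel_resistance(R0[lv_flag])

  apply_scales <- function(snet, s) {
    R_new <- R0
    R_new[lv_flag] <- R0[lv_flag] * s
    R_new[lv_flag] <- R_new[lv_flag] *
      (R_par0 / parallel_resistance(R_new[lv_flag]))
    for (k in which(lv_flag)) {
      i <- bc$outlet_id[k]
      ratio <- R_new[k] / R0[k]
      for (pre in c("Ra_", "Rmu_", "Rv_")) {
        row <- match(paste0(pre, i), snet$elements$name)
        snet$elements$R[row] <- snet$elements$R[row] * ratio
      }
    }
    snet
  }
  objective <- function(s) {
    sol <- tryCatch(steady_solve(apply_scales(steady_net, s)),
                    error = function(e) NULL)
    if (is.null(sol)) return(1e4)
    f_sim <- lv_fractions(hyper, sol, lv_ids)
    mean(abs(f_sim - f_t) / f_t) * 100
  }
  n <- sum(lv_flag)
  best <- list(par = rep(1, n), value = objective(rep(1, n)))
  trace <- list(data.frame(restart = 0L, value = best$value,
                           best = best$value, evals = 1L))
  stall <- 0L
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    start <- if (r == 1L) best$par else
      pmin(2, pmax(0.5, best$par + stats::rnorm(n, 0, 0.075)))
    fit <- nelder_mead(objective, start, rep(0.5, n), rep(2, n), tol = tol,
                       maxit = maxit, step_frac = step_frac)
    improved <- fit$value < best$value - tol
    if (fit$value < best$value) best <- fit
    trace[[r + 1L]] <- data.frame(restart = r, value = fit$value,
                                  best = best$value, evals = fit$evals)
    stall <- if (improved) 0L else stall + 1L
    if (best$value < tol || stall >= patience) break
  }
  # commit the optimized scales to the full pulsatile network
  R_new <- R0
  R_new[lv_flag] <- R0[lv_flag] * best$par
  R_new[lv_flag] <- R_new[lv_flag] *
    (R_par0 / parallel_resistance(R_new[lv_flag]))
  for (k in which(lv_flag)) {
    ratio <- R_new[k] / R0[k]
    i <- bc$outlet_id[k]
    hyper <- set_outlet_resistances(hyper, i,
                                    R_a = bc$R_a[k] * ratio,
                                    R_mu = bc$R_mu[k] * ratio,
                                    R_v = bc$R_v[k] * ratio)
  }

  # two direct R_a/R_mu updates from pulsatile simulations
  p_src_t <- mmHg_to_cgs(flow_targets$p_src[as.character(lv_ids)])
  pmu_err <- NA_real_
  for (round in 1:2) {
    res <- simulate_lpn(hyper, n_cycles_max = 12L,
                        dt = hyper$period * dt_frac)
    summ <- outlet_summary(hyper, res)
    for (k in which(lv_flag)) {
      i <- bc$outlet_id[k]
      row <- match(i, summ$outlet_id)
      bck <- hyper$meta$coronary_bcs
      tot_am <- bck$R_a[k] + bck$R_mu[k]
      Ra_new <- (summ$P[row] - p_src_t[[as.character(i)]]) / summ$Q[row]
      Ra_new <- min(max(Ra_new, 0.02 * tot_am), 0.98 * tot_am)
      hyper <- set_outlet_resistances(hyper, i, R_a = Ra_new,
                                      R_mu = tot_am - Ra_new)
    }
  }
  res <- simulate_lpn(hyper, n_cycles_max = 12L, dt = hyper$period * dt_frac)
  summ <- outlet_summary(hyper, res)
  rows <- match(lv_ids, summ$outlet_id)
  f_sim <- summ$Q[rows] / sum(summ$Q[rows])
  pmu_sim <- summ$P_mu[rows]
  summary_df <- data.frame(outlet_id = lv_ids,
                           fraction_target = as.numeric(f_t),
                           fraction_sim = f_sim,
                           p_src_target_mmHg = cgs_to_mmHg(p_src_t),
                           p_mu_sim_mmHg = cgs_to_mmHg(pmu_sim))
  list(network = hyper, scales = stats::setNames(best$par, lv_ids),
       fraction_error = mean(abs(f_sim - f_t) / f_t) * 100,
       pmu_error = mean(abs(pmu_sim - p_src_t) / p_src_t) * 100,
       summary = summary_df, nm = do.call(rbind, trace), result = res)
}

#' Stage-2 flow-distribution tuning with synthetic trees
#'
#' Iterative personalization of a tree-augmented model: (1) sub-iterations
#' match the required per-outlet flows by setting each synthetic outlet's
#' distal resistance to `R_tot Q_LV / Q_reqd - R_path`, dilating synthetic
#' trees (radius factor `alpha = (R_path_syn / R_path_syn_reqd)^(1/4)`
#' propagated by max-of-daughters with parent capping) wherever that
#' resistance would be non-positive; (2) the outlet pressure distribution
#' is compared with the targets required by the perfusion model
#' (`P_reqd = p_src + Q_reqd R_a`) and all trees are dilated/constricted to
#' achieve the required path resistances; the two phases repeat until the
#' mean flow and pressure errors are both below `tol`. The inner model is
#' the hyperemic steady 0D surrogate driven by the measured mean aortic
#' pressure.
#'
#' @param combined combined epicardial + synthetic `vessel_tree` (from
#'   [grow_synthetic_trees()]).
#' @param outlet_of_synthetic named map synthetic outlet id -> epicardial
#'   outlet id.
#' @param map epicardial `territory_map` (volumes + flow fractions).
#' @param targets a `clinical_targets` (supplies the aortic perfusion
#'   pressure).
#' @param v_lv LV volume \[mL\].
#' @param mode `"mpi"` (imaged fractions) or `"murray"` (diameter law).
#' @param tol termination threshold on both mean errors (default 0.05).
#' @param max_outer maximum outer iterations (default 30).
#' @param max_flow_iter flow sub-iterations per outer cycle (default 25).
#' @param hyperemia_factor distal resistance factor (default 0.24).
#' @param p_src_bar mean microvascular source pressure at hyperemia
#'   \[mmHg\] (default 25).
#' @param p_cap capillary pressure \[mmHg\] (default 15).
#' @param fluid a [fluid_properties()].
#' @param margin minimum outlet resistance as a fraction of the mean
#'   (default 0.05).
#' @return list of class `stage2_trees_fit`: `tree` (rescaled), `outlet_R`,
#'   `eps_flow`, `eps_pressure`, `converged`, `iterations`, `log`,
#'   `q_reqd`, `p_src` \[mmHg\], `steady` (final surrogate solution),
#'   `steady_net`, `r_tot`, `q_lv`.
#' @export
stage2_with_trees <- function(combined, outlet_of_synthetic, map, targets,
                              v_lv, mode = c("mpi", "murray"), tol = 0.05,
                              max_outer = 30L, max_flow_iter = 25L,
                              hyperemia_factor = 0.24, p_src_bar = 25,
                              p_cap = 15, fluid = fluid_properties(),
                              margin = 0.05) {
  mode <- match.arg(mode)
  seg <- combined$segments
  syn_ids <- as.integer(names(outlet_of_synthetic))
  epi_of <- stats::setNames(as.integer(outlet_of_synthetic),
                            names(outlet_of_synthetic))
  leaves <- combined$outlet_ids
  nonlv <- setdiff(leaves, syn_ids)
  p_ao <- mmHg_to_cgs(mean_arterial_pressure(targets))
  init <- initialization_rules(targets, v_lv)

  # required flow fractions per synthetic outlet: territory fraction split
  # equally over that tree's terminals (mpi) or diameter-law shares (murray)
  n_term <- table(factor(epi_of, levels = map$outlet_ids))
  if (mode == "mpi") {
    f_epi <- map$flow_fraction[as.character(map$outlet_ids)]
    f_syn <- as.numeric(f_epi[as.character(epi_of)]) /
      as.numeric(n_term[as.character(epi_of)])
  } else {
    d <- 2 * seg$radius[match(syn_ids, seg$id)]
    f_syn <- d^2.6 / sum(d^2.6)
  }
  f_syn <- stats::setNames(f_syn / sum(f_syn), syn_ids)
  # perfusion volume of each synthetic outlet: its territory's share
  v_syn <- stats::setNames(
    as.numeric(map$territory_volume[as.character(epi_of)]) /
      as.numeric(n_term[as.character(epi_of)]), syn_ids)

  # initial distal resistances: diameter-law split at rest, then hyperemia
  dia <- stats::setNames(2 * seg$radius[match(leaves, seg$id)], leaves)
  lvf <- stats::setNames(leaves %in% syn_ids, leaves)
  mur <- murray_outlet_resistances(dia, lvf, init$R_cor_total,
                                   exponent = init$murray_exponent,
                                   lv_share = init$lv_flow_share)
  R_out <- mur$R * hyperemia_factor

  # steady surrogate network: built once, resistances updated in place
  frag <- build_rcl_from_tree(combined, fluid)
  snet <- lpn_network(period = 60 / targets$heart_rate)
  snet$elements <- rbind(
    data.frame(name = "AO_src", type = "psource", node_a = "AO",
               node_b = "GND", R = 0, L = 0, p1 = p_ao, p2 = 0, p3 = 0,
               stringsAsFactors = FALSE),
    within(frag$elements, {
      node_a[node_a == "cor_inlet"] <- "AO"
    }),
    data.frame(name = paste0("Rout_", leaves), type = "R",
               node_a = unname(frag$outlet_nodes[as.character(leaves)]),
               node_b = "GND", R = as.numeric(R_out[as.character(leaves)]),
               L = 0, p1 = 0, p2 = 0, p3 = 0, stringsAsFactors = FALSE))
  seg_elem <- stats::setNames(paste0("cor_seg", seg$id), seg$id)
  rout_row <- match(paste0("Rout_", leaves), snet$elements$name)
  names(rout_row) <- leaves

  set_tree_resistances <- function(snet, tr) {
    r <- segment_rcl(tr$segments$length, tr$segments$radius, fluid)$R
    rows <- match(paste0("cor_seg", tr$segments$id), snet$elements$name)
    snet$elements$R[rows] <- r
    snet
  }
  snet <- set_tree_resistances(snet, combined)

  # path bookkeeping: epicardial outlet node upstream of each synthetic leaf
  epi_nodes <- stats::setNames(
    unname(frag$outlet_nodes[as.character(syn_ids)]), syn_ids)
  epi_nodes <- stats::setNames(paste0("cor_n", epi_of[as.character(syn_ids)]),
                               syn_ids)
  syn_nodes <- stats::setNames(
    unname(frag$outlet_nodes[as.character(syn_ids)]), syn_ids)

  solve_surrogate <- function(snet) {
    sol <- steady_solve(snet)
    P <- sol$pressures
    Q <- sol$flows
    Qs <- stats::setNames(as.numeric(Q[paste0("Rout_", syn_ids)]), syn_ids)
    Ps <- stats::setNames(as.numeric(P[syn_nodes]), syn_ids)
    Pepi <- stats::setNames(as.numeric(P[epi_nodes]), syn_ids)
    list(sol = sol, Q = Qs, P = Ps, P_epi = Pepi)
  }

  sur <- solve_surrogate(snet)
  q_lv_target <- sum(sur$Q)
  q_reqd <- f_syn * q_lv_target
  r_tot <- p_ao / q_lv_target
  p_src <- p_cap + (q_reqd / v_syn) * (v_lv / q_lv_target) *
    (p_src_bar - p_cap)   # mmHg, volume-weighted mean = p_src_bar

  tree_cur <- combined
  log_rows <- list()
  eps_flow <- Inf; eps_pressure <- Inf
  converged <- FALSE
  outer <- 0L

  ra_share <- function(R) {   # small-artery share of a total distal R
    f_am <- 1 - 0.16
    R * f_am * 0.38 / 1.38
  }

  while (outer < max_outer) {
    outer <- outer + 1L
    # ---- (1) flow matching sub-iterations ----
    for (fi in seq_len(max_flow_iter)) {
      sur <- solve_surrogate(snet)
      R_path <- (p_ao - sur$P) / sur$Q
      R_path_syn <- (sur$P_epi - sur$P) / sur$Q
      R_reqd <- required_outlet_resistance(r_tot, q_lv_target, q_reqd, R_path)
      floor_R <- margin * mean(R_out[as.character(syn_ids)])
      neg <- which(R_reqd < floor_R)
      if (length(neg) > 0) {
        # dilate the synthetic paths that demand non-positive resistance
        R_epi_path <- R_path[neg] - R_path_syn[neg]
        R_syn_reqd <- r_tot * q_lv_target / q_reqd[neg] -
          R_epi_path - floor_R
        if (any(R_syn_reqd <= 0)) {
          bad <- names(R_syn_reqd)[R_syn_reqd <= 0][1]
          stop("infeasible path resistance at synthetic outlet ", bad,
               " (epicardial path already exceeds the required total)")
        }
        alpha <- pmax(dilation_factor(R_path_syn[neg], R_syn_reqd), 1)
        tree_cur <- apply_radius_scaling(tree_cur,
                                         stats::setNames(alpha, names(neg)))
        snet <- set_tree_resistances(snet, tree_cur)
        R_reqd <- pmax(R_reqd, floor_R)
      }
      R_out[as.character(syn_ids)] <- pmax(R_reqd, floor_R)
      snet$elements$R[rout_row[as.character(syn_ids)]] <-
        as.numeric(R_out[as.character(syn_ids)])
      sur <- solve_surrogate(snet)
      eps_flow <- mean(abs(sur$Q - q_reqd) / q_reqd)
      if (eps_flow <= tol && length(neg) == 0) break
    }
    # ---- (2) pressure matching ----
    R_a <- ra_share(R_out[as.character(syn_ids)])
    P_reqd <- mmHg_to_cgs(p_src) + q_reqd * R_a
    eps_pressure <- mean(abs(sur$P - P_reqd) / P_reqd)
    log_rows[[outer]] <- data.frame(iteration = outer,
                                    eps_flow = eps_flow,
                                    eps_pressure = eps_pressure)
    if (eps_flow <= tol && eps_pressure <= tol) { converged <- TRUE; break }
    R_path <- (p_ao - sur$P) / sur$Q
    R_path_syn <- (sur$P_epi - sur$P) / sur$Q
    R_path_reqd <- (p_ao - P_reqd) / q_reqd
    R_syn_reqd <- R_path_reqd - (R_path - R_path_syn)
    if (any(R_syn_reqd <= 0)) {
      bad <- names(R_syn_reqd)[R_syn_reqd <= 0][1]
      stop("infeasible required synthetic path resistance at outlet ", bad)
    }
    alpha <- dilation_factor(R_path_syn, R_syn_reqd)
    tree_cur <- apply_radius_scaling(tree_cur,
                                     stats::setNames(alpha, syn_ids))
    snet <- set_tree_resistances(snet, tree_cur)
  }

  sur <- solve_surrogate(snet)
  structure(list(
    tree = tree_cur, outlet_R = R_out, eps_flow = eps_flow,
    eps_pressure = eps_pressure, converged = converged,
    iterations = outer, log = do.call(rbind, log_rows),
    q_reqd = q_reqd, p_src = p_src, fractions = f_syn,
    steady = sur, steady_net = snet, r_tot = r_tot,
    q_lv = sum(sur$Q), outlet_of_synthetic = epi_of,
    v_syn = v_syn), class = "stage2_trees_fit")
}

#' @export
print.stage2_trees_fit <- function(x, ...) {
  cat(sprintf(
    "stage2_trees_fit: %s in %d iterations (eps_flow %.2f%%, eps_pressure %.2f%%)\n",
    if (x$converged) "converged" else "NOT converged", x$iterations,
    100 * x$eps_flow, 100 * x$eps_pressure))
  invisible(x)
}
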