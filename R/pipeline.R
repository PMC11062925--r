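#' Pipeline configuration
#'
#' Settings for an end-to-end personalization run: the synthetic patient,
#' the 2 x 2 model comparison design (with/without synthetic trees, flow
#' targets from perfusion imaging or from Murray's law), tree size, and
#' tolerances.
#'
#' @param seed master seed.
#' @param out_dir output directory (created); NULL for no file output.
#' @param patient a `synthetic_patient_config` (default: seeded from
#'   `seed`).
#' @param modes data.frame with columns `trees` (logical) and `targets`
#'   (`"mpi"`/`"murray"`); default the full 2 x 2 design.
#' @param total_terminals synthetic terminals (default 500).
#' @param stage1_restarts Nelder-Mead restarts for Stage 1.
#' @param tol_trees with-trees termination tolerance (default 0.05).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            patient = synthetic_patient_config(seed = seed),
                            modes = NULL, total_terminals = 500L,
                            stage1_restarts = 50L, tol_trees = 0.05) {
  if (is.null(modes)) {
    modes <- data.frame(trees = c(FALSE, FALSE, TRUE, TRUE),
                        targets = c("mpi", "murray", "mpi", "murray"))
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 patient = patient, modes = modes,
                 total_terminals = as.integer(total_terminals),
                 stage1_restarts = stage1_restarts, tol_trees = tol_trees),
            class = "pipeline_config")
}

# initial parameter set for a patient (initialization rules applied)
patient_init_params <- function(targets, v_lv) {
  init <- initialization_rules(targets, v_lv)
  p <- default_lpn_params(period = 60 / targets$heart_rate,
                          R_sys = init$R_total)
  p$R_cor_total <- init$R_cor_total
  p$C_ao <- init$C_aortic_total
  p$C_cor_total <- init$C_cor_total
  p
}

# Murray initialization shares over all outlets of a tree
murray_shares <- function(tree, init) {
  seg <- tree$segments
  leaves <- tree$outlet_ids
  dia <- stats::setNames(2 * seg$radius[match(leaves, seg$id)], leaves)
  lvf <- stats::setNames(seg$perfuses_lv[match(leaves, seg$id)], leaves)
  murray_outlet_resistances(dia, lvf, init$R_cor_total,
                            exponent = init$murray_exponent,
                            lv_share = init$lv_flow_share)
}

#' Run the full personalization pipeline
#'
#' Generates (or accepts) a synthetic patient, maps perfusion territories,
#' tunes cardiac function (Stage 1), then for every requested mode tunes
#' the flow distribution (Stage 2, with or without synthetic trees, against
#' imaging-derived or Murray targets), solves the Darcy perfusion model
#' with the resulting microvascular sources, and computes per-branch FFR.
#' Writes one directory per mode (CSV tables + VTK fields) when
#' `config$out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @param patient optionally, a pre-built patient list from
#'   [make_patient()].
#' @return list of class `pipeline_report`: `patient`, `stage1`, `runs`
#'   (one per mode: flow-fraction table, MBF table, FFR curves, errors),
#'   `comparison` (from [compare_models()]).
#' @export
run_pipeline <- function(config = pipeline_config(), patient = NULL) {
  if (is.null(patient)) patient <- make_patient(config$patient)
  map <- patient$map
  tree <- patient$tree
  targets <- patient$targets
  v_lv <- map$v_lv
  params0 <- patient_init_params(targets, v_lv)
  init <- initialization_rules(targets, v_lv)
  mur <- murray_shares(tree, init)

  net_red <- build_patient_network(params0, tree, mur$shares, reduce = TRUE)
  s1 <- stage1_tune(net_red, targets, restarts = config$stage1_restarts,
                    seed = config$seed)

  syn <- NULL
  runs <- list()
  for (k in seq_len(nrow(config$modes))) {
    trees_on <- config$modes$trees[k]
    mode <- config$modes$targets[k]
    label <- paste0(if (trees_on) "trees_" else "epi_", mode)
    if (trees_on && is.null(syn)) {
      syn <- grow_synthetic_trees(tree, patient$mesh, map,
                                  cco_config(total_terminals =
                                               config$total_terminals,
                                             seed = config$seed))
    }
    runs[[label]] <- run_mode(patient, s1, mur, trees_on, mode, config, syn)
  }
  report <- structure(list(patient = patient, stage1 = s1, runs = runs,
                           comparison = compare_models(runs),
                           config = config), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# one cell of the 2x2 design
run_mode <- function(patient, s1, mur, trees_on, mode, config, syn) {
  map <- patient$map
  tree <- patient$tree
  targets <- patient$targets
  v_lv <- map$v_lv
  ids <- map$outlet_ids
  f_meas <- map$flow_fraction[as.character(ids)]
  tgts <- build_flow_targets(map, tree, v_lv, mode = mode)

  if (!trees_on) {
    net <- build_patient_network(s1$params, tree, mur$shares, reduce = FALSE)
    if (mode == "mpi") {
      s2 <- stage2_no_trees(net, tgts, seed = config$seed,
                            restarts = min(config$stage1_restarts, 50))
      hyper <- s2$network
      res <- s2$result
    } else {
      hyper <- apply_hyperemia(net)
      res <- simulate_lpn(hyper, n_cycles_max = 12L,
                          dt = hyper$period / 600)
      s2 <- NULL
    }
    summ <- outlet_summary(hyper, res)
    rows <- match(ids, summ$outlet_id)
    q_sim <- stats::setNames(summ$Q[rows], ids)
    p_mu <- stats::setNames(cgs_to_mmHg(summ$P_mu[rows]), ids)
    steady_sol <- res
    seg_nodes <- net$meta$seg_nodes
    ffr_tree <- tree
    ffr_outlets <- ids
  } else {
    s2 <- stage2_with_trees(syn$combined, syn$outlet_of_synthetic, map,
                            targets, v_lv, mode = mode,
                            tol = config$tol_trees)
    # per-territory flow: sum of this tree's synthetic outlet flows
    epi_of <- s2$outlet_of_synthetic
    q_sim <- tapply(s2$steady$Q, factor(epi_of[names(s2$steady$Q)],
                                        levels = ids), sum, default = 0)
    q_sim <- stats::setNames(as.numeric(q_sim), ids)
    # microvascular source: P_mu = P - Q R_a at each synthetic outlet,
    # volume-aggregated per territory
    R_a <- s2$outlet_R[names(s2$steady$Q)] * 0.84 * 0.38 / 1.38
    pmu_syn <- cgs_to_mmHg(s2$steady$P - s2$steady$Q * R_a)
    p_mu <- tapply(pmu_syn, factor(epi_of[names(pmu_syn)], levels = ids),
                   mean)
    p_mu <- stats::setNames(as.numeric(p_mu), ids)
    steady_sol <- s2$steady$sol
    frag_nodes <- stats::setNames(paste0("cor_n", s2$tree$segments$id),
                                  s2$tree$segments$id)
    seg_nodes <- frag_nodes
    ffr_tree <- s2$tree
    ffr_outlets <- ids
  }

  f_sim <- q_sim / sum(q_sim)
  flow_tab <- data.frame(outlet_id = ids,
                         fraction_measured = as.numeric(f_meas),
                         fraction_sim = as.numeric(f_sim),
                         q_sim = as.numeric(q_sim),
                         p_mu_mmHg = as.numeric(p_mu))

  # Darcy perfusion with the model's own microvascular sources
  p_src_field <- build_source_field(map, p_mu)
  p_bar <- sum(p_mu * map$territory_volume[as.character(ids)]) / v_lv
  q_tot <- sum(q_sim)
  sol <- solve_darcy(patient$mesh, p_src_field,
                     make_betas(q_tot, v_lv, p_bar))
  mb <- compute_mbf(sol, map)
  mbf_frac <- mb$territory_flow / sum(mb$territory_flow)
  mbf_tab <- data.frame(outlet_id = ids,
                        mbf_fraction_measured = as.numeric(f_meas),
                        mbf_fraction_sim = as.numeric(mbf_frac[as.character(ids)]))

  # FFR along each root-to-epicardial-outlet path
  ffr <- lapply(ffr_outlets, function(o) {
    compute_ffr(steady_sol, ffr_tree, seg_nodes, o)
  })
  names(ffr) <- ffr_outlets

  list(trees = trees_on, mode = mode,
       flow = flow_tab, mbf = mbf_tab, ffr = ffr,
       flow_error = mean(abs(f_sim - f_meas) / f_meas) * 100,
       mbf_error = mean(abs(mbf_frac[as.character(ids)] - f_meas) /
                          f_meas) * 100,
       stage2 = s2, darcy = sol)
}

#' Compare personalization runs
#'
#' Per-run mean relative errors of flow fractions and MBF fractions against
#' the measured (imaging) values, and the minimum FFR per run with the
#' conventional 0.80 positivity flag.
#'
#' @param runs named list of mode runs (from [run_pipeline()]'s `runs`).
#' @return data.frame, one row per run.
#' @export
compare_models <- function(runs) {
  if (length(runs) < 1) stop("need at least one run")
  ids0 <- runs[[1]]$flow$outlet_id
  for (r in runs) {
    if (!identical(r$flow$outlet_id, ids0)) {
      stop("runs have mismatched outlet sets")
    }
  }
  do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    min_ffr <- min(vapply(r$ffr, function(f) attr(f, "min_ffr"), 0))
    data.frame(run = nm, trees = r$trees, targets = r$mode,
               flow_fraction_error_pct = r$flow_error,
               mbf_fraction_error_pct = r$mbf_error,
               min_ffr = min_ffr, ffr_positive = min_ffr < 0.80)
  }))
}

# write one report bundle to disk (CSV tables + labeled meshes + manifest)
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  patient <- report$patient
  write_mesh(patient$mesh, file.path(out_dir, "mesh.vtk"),
             fields = list(territory = as.numeric(patient$map$nodal_label)))
  write_tree(patient$tree, file.path(out_dir, "tree.json"))
  write_targets(patient$targets, file.path(out_dir, "targets.json"))
  write_territories(patient$map, file.path(out_dir, "territories.csv"))
  utils::write.csv(report$comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  for (nm in names(report$runs)) {
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    r <- report$runs[[nm]]
    utils::write.csv(r$flow, file.path(d, "flow_fractions.csv"),
                     row.names = FALSE)
    utils::write.csv(r$mbf, file.path(d, "mbf_fractions.csv"),
                     row.names = FALSE)
    ffr_tab <- do.call(rbind, lapply(names(r$ffr), function(o) {
      cbind(outlet_id = o, r$ffr[[o]])
    }))
    utils::write.csv(ffr_tab, file.path(d, "ffr.csv"), row.names = FALSE)
    write_mesh(patient$mesh, file.path(d, "mbf_sim.vtk"),
               fields = list(MBF_sim = compute_mbf(r$darcy)$nodal_mbf,
                             p_mmHg = r$darcy$p))
  }
  manifest <- list(seed = report$config$seed,
                   modes = report$config$modes,
                   total_terminals = report$config$total_terminals,
                   stage1_error_pct = report$stage1$value,
                   package_version =
                     as.character(utils::packageVersion("myoperf")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report: stage-1 error", sprintf("%.2f%%", x$stage1$value),
      "\n")
  print(x$comparison)
  invisible(x)
}
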