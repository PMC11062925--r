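#' Morphometric total LV flow
#'
#' Scaling rule for resting total LV-perfusing coronary flow as a function
#' of LV myocardial volume: `Q_LV = 3.41 * V_LV^0.75` in mL/min.
#'
#' @param v_lv LV myocardial volume \[mL\].
#' @return flow \[mL/min\].
#' @export
morphometric_q_lv <- function(v_lv) 3.41 * v_lv^0.75

#' Boundary-condition initialization rules
#'
#' Deterministic starting values for personalization: total vascular
#' resistance from mean arterial pressure over cardiac output; total LV
#' coronary flow from the morphometric rule with a 20% supplement for
#' branches not perfusing the LV; total coronary resistance from mean
#' pressure over total coronary flow; canonical totals for aortic
#' (0.28e-3 cm5/dyn) and coronary (1e-6 cm5/dyn) distal capacitance;
#' diameter exponent 2.6 for flow splitting; initial R_a/R_mu = 0.38; and
#' hyperemic resistance factor 0.24.
#'
#' @param targets a `clinical_targets`.
#' @param v_lv LV myocardial volume \[mL\].
#' @return named list of initial values (resistances in dyn s/cm5, flows in
#'   mL/s).
#' @export
initialization_rules <- function(targets, v_lv) {
  map_cgs <- mmHg_to_cgs(mean_arterial_pressure(targets))
  co_mls <- targets$cardiac_output * 1000 / 60
  q_lv <- morphometric_q_lv(v_lv) / 60
  q_nonlv <- 0.2 * q_lv
  q_cor <- q_lv + q_nonlv
  list(R_total = map_cgs / co_mls,
       q_lv = q_lv, q_nonlv = q_nonlv, q_cor = q_cor,
       R_cor_total = map_cgs / q_cor,
       C_aortic_total = 0.28e-3, C_cor_total = 1e-6,
       ra_rmu_ratio = 0.38, murray_exponent = 2.6,
       hyperemia_factor = 0.24,
       lv_flow_share = q_lv / q_cor, nonlv_flow_share = q_nonlv / q_cor)
}

#' Murray's-law distal outlet resistances
#'
#' Flow shares proportional to outlet diameter^`exponent` within each group
#' (LV-perfusing outlets share `lv_share` of total coronary flow; the rest
#' goes to non-LV outlets), and per-outlet resistance
#' `R_i = R_cor_total / share_i`, so the parallel combination of all
#' outlets reproduces `R_cor_total` exactly.
#'
#' @param diameters named outlet diameters \[cm\].
#' @param lv_flags named logical: does this outlet perfuse the LV?
#' @param R_cor_total total distal coronary resistance \[dyn s/cm5\].
#' @param exponent diameter exponent (default 2.6).
#' @param lv_share fraction of coronary flow perfusing the LV (default
#'   1/1.2, i.e. non-LV flow is 20% of LV flow).
#' @return list `shares` (sum to 1) and `R` (named resistances).
#' @export
murray_outlet_resistances <- function(diameters, lv_flags, R_cor_total,
                                      exponent = 2.6, lv_share = 1 / 1.2) {
  stopifnot(all(diameters > 0))
  ids <- names(diameters)
  lv_flags <- lv_flags[ids]
  w <- diameters^exponent
  shares <- numeric(length(w))
  names(shares) <- ids
  if (!any(lv_flags)) lv_share <- 0
  if (!any(!lv_flags)) lv_share <- 1
  if (any(lv_flags)) {
    shares[lv_flags] <- lv_share * w[lv_flags] / sum(w[lv_flags])
  }
  if (any(!lv_flags)) {
    shares[!lv_flags] <- (1 - lv_share) * w[!lv_flags] / sum(w[!lv_flags])
  }
  list(shares = shares, R = R_cor_total / shares)
}

#' Switch coronary boundary conditions to hyperemia
#'
#' Multiplies every coronary outlet's R_a, R_mu and R_v by `factor`
#' (default 0.24, maximal pharmacologic vasodilation); aortic/systemic
#' elements are untouched. Applying a vasodilating factor twice is guarded;
#' applying the reciprocal factor restores rest and clears the flag.
#'
#' @param net an `lpn_network` with coronary BCs.
#' @param factor resistance scale (default 0.24).
#' @return the updated network.
#' @export
apply_hyperemia <- function(net, factor = 0.24) {
  bc <- net$meta$coronary_bcs
  if (is.null(bc)) stop("network has no coronary outlet BCs")
  if (factor < 1 && isTRUE(net$meta$hyperemic)) {
    warning("network is already hyperemic; not applying the factor twice")
    return(net)
  }
  for (k in seq_len(nrow(bc))) {
    i <- bc$outlet_id[k]
    for (pre in c("Ra_", "Rmu_", "Rv_")) {
      row <- match(paste0(pre, i), net$elements$name)
      net$elements$R[row] <- net$elements$R[row] * factor
    }
  }
  bc$R_a <- bc$R_a * factor; bc$R_mu <- bc$R_mu * factor
  bc$R_v <- bc$R_v * factor
  net$meta$coronary_bcs <- bc
  net$meta$hyperemic <- if (factor < 1) TRUE else FALSE
  net
}

#' Set the distal resistances of one coronary outlet
#'
#' @param net an `lpn_network`.
#' @param outlet_id outlet id.
#' @param R_a,R_mu,R_v new resistances \[dyn s/cm5\] (NULL keeps current).
#' @return updated network.
#' @export
set_outlet_resistances <- function(net, outlet_id, R_a = NULL, R_mu = NULL,
                                   R_v = NULL) {
  bc <- net$meta$coronary_bcs
  k <- match(outlet_id, bc$outlet_id)
  if (is.na(k)) stop("unknown outlet: ", outlet_id)
  vals <- list(Ra_ = R_a, Rmu_ = R_mu, Rv_ = R_v)
  cols <- c(Ra_ = "R_a", Rmu_ = "R_mu", Rv_ = "R_v")
  for (pre in names(vals)) {
    if (is.null(vals[[pre]])) next
    row <- match(paste0(pre, outlet_id), net$elements$name)
    net$elements$R[row] <- vals[[pre]]
    bc[[cols[[pre]]]][k] <- vals[[pre]]
  }
  net$meta$coronary_bcs <- bc
  net
}

#' Required distal outlet resistance in the with-trees loop
#'
#' `R_out_reqd = R_tot Q_LV / Q_reqd - R_path`: the distal resistance that
#' makes an aorta-to-outlet path carry its required flow, given the total
#' model resistance `R_tot` referenced to the total LV flow.
#'
#' @param r_tot total model resistance \[dyn s/cm5\].
#' @param q_lv total LV flow \[mL/s\].
#' @param q_reqd required outlet flow \[mL/s\].
#' @param r_path aorta-to-outlet path resistance \[dyn s/cm5\].
#' @return required distal resistance \[dyn s/cm5\] (may be negative,
#'   signalling that the path must be dilated).
#' @export
required_outlet_resistance <- function(r_tot, q_lv, q_reqd, r_path) {
  r_tot * q_lv / q_reqd - r_path
}

#' Radius dilation factor from path resistances
#'
#' Poiseuille resistance scales as radius^-4, so achieving a required
#' synthetic-path resistance from the current one takes a radius factor
#' `alpha = (R_path_syn / R_path_syn_reqd)^(1/4)` (> 1 dilates).
#'
#' @param r_path_syn current synthetic-path resistance.
#' @param r_path_syn_reqd required synthetic-path resistance (> 0).
#' @return radius scale factor.
#' @export
dilation_factor <- function(r_path_syn, r_path_syn_reqd) {
  if (any(r_path_syn_reqd <= 0)) stop("required path resistance must be > 0")
  (r_path_syn / r_path_syn_reqd)^(1 / 4)
}

#' Per-outlet flow and pressure-source targets
#'
#' In `"mpi"` mode the required flow at each LV outlet is its imaged
#' territory flow fraction times the morphometric total LV flow, and the
#' required microvascular source pressure follows from inverting the MBF
#' integral: `p_src_i = MBF_i / (beta_src V_i) + p_cap`. In `"murray"` mode
#' flow shares follow outlet diameter^2.6. Outlets not perfusing the LV
#' always receive Murray targets.
#'
#' @param map a `territory_map` with `flow_fraction` and
#'   `territory_volume` (mpi mode).
#' @param tree the epicardial `vessel_tree` (for diameters).
#' @param v_lv LV volume \[mL\].
#' @param mode `"mpi"` or `"murray"`.
#' @param p_src_bar mean source-pressure guess \[mmHg\] (default 25; the
#'   derived p_src field is self-consistent with this mean).
#' @param p_cap capillary target pressure \[mmHg\].
#' @return list: `q_reqd` \[mL/s\] and `p_src` \[mmHg\] per LV outlet,
#'   `fractions`, `q_lv` \[mL/s\].
#' @export
build_flow_targets <- function(map, tree, v_lv, mode = c("mpi", "murray"),
                               p_src_bar = 25, p_cap = 15) {
  mode <- match.arg(mode)
  ids <- map$outlet_ids
  q_lv <- morphometric_q_lv(v_lv) / 60
  if (mode == "mpi") {
    frac <- map$flow_fraction[as.character(ids)]
  } else {
    seg <- tree$segments
    d <- 2 * seg$radius[match(ids, seg$id)]
    frac <- stats::setNames(d^2.6 / sum(d^2.6), ids)
  }
  q_reqd <- frac * q_lv
  v_i <- map$territory_volume[as.character(ids)]
  # Eq.-4 inversion: p_src_i = MBF_i/(beta_src V_i) + p_cap, with beta_src
  # fixed by the mean-source parameterization
  p_src <- p_cap + (q_reqd / v_i) * (v_lv / q_lv) * (p_src_bar - p_cap)
  list(q_reqd = q_reqd, p_src = stats::setNames(as.numeric(p_src), ids),
       fractions = frac, q_lv = q_lv)
}
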