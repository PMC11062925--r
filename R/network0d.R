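#' Lumped-parameter (0D) hemodynamic networks
#'
#' A network is a circuit of nodes (pressures) and elements (flows):
#' resistors, resistor-inductor vessel segments, smooth-diode valves,
#' pressure/flow sources and optional quadratic stenosis elements, plus
#' capacitors attached at nodes (optionally referenced to a scaled chamber
#' pressure, which models intramyocardial pumping) and time-varying
#' elastance heart chambers. The ground node is named `"GND"` and is held at
#' zero pressure. All values are CGS: dyn s/cm5, cm5/dyn, dyn s2/cm5, mL/s.
#'
#' @param period cardiac period T \[s\].
#' @return an empty object of class `lpn_network`.
#' @export
lpn_network <- function(period = 1.0) {
  structure(list(
    period = period,
    elements = empty_elements(),
    capacitors = empty_capacitors(),
    chambers = empty_chambers(),
    meta = list()
  ), class = "lpn_network")
}

empty_elements <- function() {
  data.frame(name = character(), type = character(),
             node_a = character(), node_b = character(),
             R = numeric(), L = numeric(),
             p1 = numeric(), p2 = numeric(), p3 = numeric(),
             stringsAsFactors = FALSE)
}
empty_capacitors <- function() {
  data.frame(name = character(), node = character(), C = numeric(),
             ref_node = character(), ref_scale = numeric(),
             stringsAsFactors = FALSE)
}
empty_chambers <- function() {
  data.frame(name = character(), node = character(),
             E_max = numeric(), E_min = numeric(), V0 = numeric(),
             t_on = numeric(), duration = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.lpn_network <- function(x, ...) {
  cat("lpn_network: T =", x$period, "s,",
      nrow(x$elements), "elements,",
      nrow(x$capacitors), "capacitors,",
      nrow(x$chambers), "chambers\n")
  invisible(x)
}

#' Add a flow element
#'
#' @param net an `lpn_network`.
#' @param name unique element name.
#' @param type one of `"R"` (resistor), `"RL"` (resistor + inertance),
#'   `"valve"` (smooth diode), `"psource"` (pressure source),
#'   `"qsource"` (flow source, optionally sinusoidal),
#'   `"stenosis"` (linear + quadratic loss).
#' @param node_a,node_b terminal node names (flow runs a -> b); `"GND"` is
#'   ground.
#' @param R resistance (or open resistance for valves) \[dyn s/cm5\].
#' @param L inertance \[dyn s2/cm5\].
#' @param p1,p2,p3 type-specific parameters: valve `p1` = leak resistance,
#'   `p2` = smoothing width \[dyn/cm2\]; psource `p1` = source pressure;
#'   qsource `p1` = mean flow, `p2` = sine amplitude, `p3` = angular
#'   frequency; stenosis `p1` = quadratic coefficient.
#' @return the updated network.
#' @export
net_add_element <- function(net, name, type, node_a, node_b,
                            R = 0, L = 0, p1 = 0, p2 = 0, p3 = 0) {
  stopifnot(type %in% c("R", "RL", "valve", "psource", "qsource", "stenosis"))
  if (name %in% net$elements$name) stop("duplicate element name: ", name)
  net$elements <- rbind(net$elements, data.frame(
    name = name, type = type, node_a = node_a, node_b = node_b,
    R = R, L = L, p1 = p1, p2 = p2, p3 = p3, stringsAsFactors = FALSE))
  net
}

#' Add a capacitor at a node
#'
#' The capacitor stores volume `C * (P_node - ref_scale * P_ref)`; with no
#' reference it is grounded. A chamber-referenced capacitor models the
#' intramyocardial pressure acting on intramural coronary vessels.
#'
#' @param net an `lpn_network`.
#' @param name unique name.
#' @param node node the capacitor charges.
#' @param C compliance \[cm5/dyn\], strictly positive.
#' @param ref_node optional reference node (e.g. the LV chamber node).
#' @param ref_scale scale applied to the reference pressure.
#' @return the updated network.
#' @export
net_add_capacitor <- function(net, name, node, C, ref_node = NA_character_,
                              ref_scale = 1) {
  if (C <= 0) stop("capacitance must be positive")
  if (name %in% net$capacitors$name) stop("duplicate capacitor name: ", name)
  net$capacitors <- rbind(net$capacitors, data.frame(
    name = name, node = node, C = C, ref_node = ref_node,
    ref_scale = ref_scale, stringsAsFactors = FALSE))
  net
}

#' Add a time-varying elastance chamber
#'
#' Chamber pressure `P = E(t) (V - V0)` with
#' `E(t) = E_min + (E_max - E_min) a(t)` and a raised-cosine activation
#' `a(t) = (1 - cos(2 pi s)) / 2` for phase `s = ((t - t_on) mod T)/duration`
#' in \[0, 1\], zero otherwise.
#'
#' @param net an `lpn_network`.
#' @param name chamber name.
#' @param node node carrying the chamber pressure.
#' @param E_max,E_min peak/baseline elastance \[dyn/cm2/mL\], `E_max >= E_min > 0`.
#' @param V0 unstressed volume \[mL\].
#' @param t_on activation onset within the cycle \[s\].
#' @param duration activation duration \[s\].
#' @return the updated network.
#' @export
net_add_chamber <- function(net, name, node, E_max, E_min, V0, t_on, duration) {
  if (!(E_max >= E_min && E_min > 0)) stop("need E_max >= E_min > 0")
  if (name %in% net$chambers$name) stop("duplicate chamber name: ", name)
  net$chambers <- rbind(net$chambers, data.frame(
    name = name, node = node, E_max = E_max, E_min = E_min, V0 = V0,
    t_on = t_on, duration = duration, stringsAsFactors = FALSE))
  net
}

#' Poiseuille resistance, inertance and compliance of a cylindrical segment
#'
#' `R = 8 mu l / (pi r^4)`, `L = rho l / (pi r^2)`,
#' `C = 3 pi r^3 l / (2 E h)` (thin-walled linear elasticity), with wall
#' thickness `h = h_ratio * r`.
#'
#' @param length segment length \[cm\].
#' @param radius lumen radius \[cm\].
#' @param fluid a [fluid_properties()].
#' @param elastic_modulus wall Young's modulus \[dyn/cm2\]; default
#'   1.15e7 (coronary wall).
#' @param h_ratio wall thickness as a fraction of the radius (default 0.1).
#' @return list with `R`, `L`, `C`.
#' @export
segment_rcl <- function(length, radius, fluid = fluid_properties(),
                        elastic_modulus = 1.15e7, h_ratio = 0.1) {
  if (any(radius <= 0)) stop("zero or negative radius")
  list(R = 8 * fluid$viscosity * length / (pi * radius^4),
       L = fluid$density * length / (pi * radius^2),
       C = 3 * pi * radius^3 * length / (2 * elastic_modulus *
                                           h_ratio * radius))
}

#' Build the RCL fragment of a vessel tree
#'
#' Each segment becomes a resistor-inductor branch from its proximal node to
#' its distal node plus a grounded capacitor at the distal node; junctions
#' are ideal (pressure continuity, flow conservation). Node names are
#' `<prefix>n<id>` for the distal node of segment `id`, and
#' `<prefix>inlet` for the proximal node of the root.
#'
#' @param tree a `vessel_tree`.
#' @param fluid a [fluid_properties()].
#' @param prefix node/element name prefix (allows several fragments in one
#'   network).
#' @inheritParams segment_rcl
#' @return list with `elements`, `capacitors`, `inlet_node`, `outlet_nodes`
#'   (named by outlet id) and `seg_nodes` (named by segment id).
#' @export
build_rcl_from_tree <- function(tree, fluid = fluid_properties(),
                                prefix = "cor_", elastic_modulus = 1.15e7,
                                h_ratio = 0.1) {
  seg <- tree$segments
  rcl <- segment_rcl(seg$length, seg$radius, fluid, elastic_modulus, h_ratio)
  node_of <- function(id) paste0(prefix, "n", id)
  prox <- ifelse(is.na(seg$parent), paste0(prefix, "inlet"),
                 node_of(seg$parent))
  elements <- data.frame(
    name = paste0(prefix, "seg", seg$id), type = "RL",
    node_a = prox, node_b = node_of(seg$id),
    R = rcl$R, L = rcl$L, p1 = 0, p2 = 0, p3 = 0, stringsAsFactors = FALSE)
  capacitors <- data.frame(
    name = paste0(prefix, "segC", seg$id), node = node_of(seg$id),
    C = rcl$C, ref_node = NA_character_, ref_scale = 1,
    stringsAsFactors = FALSE)
  outlet_nodes <- stats::setNames(node_of(tree$outlet_ids),
                                  tree$outlet_ids)
  list(elements = elements, capacitors = capacitors,
       inlet_node = paste0(prefix, "inlet"),
       outlet_nodes = outlet_nodes,
       seg_nodes = stats::setNames(node_of(seg$id), seg$id),
       seg_ids = seg$id)
}

#' Coronary outlet boundary-condition parameter table
#'
#' Distributes a total distal coronary resistance and capacitance over
#' outlets. Flow shares within each group (LV-perfusing vs not) follow the
#' supplied `shares`; per-outlet total resistance is `R_group_parallel /
#' share`. The total is split into small-artery, microvascular and venous
#' parts with `R_a/R_mu = ra_rmu_ratio` and a fixed venous fraction.
#' Capacitance is distributed proportional to outlet area.
#'
#' @param outlet_ids integer outlet ids.
#' @param radii outlet radii \[cm\] (for areas).
#' @param shares named flow shares summing to 1 across all outlets.
#' @param R_total total distal coronary resistance (all outlets in
#'   parallel) \[dyn s/cm5\].
#' @param C_total total coronary distal capacitance \[cm5/dyn\].
#' @param ra_rmu_ratio ratio R_a/R_mu (default 0.38).
#' @param rv_fraction venous fraction of each outlet's total resistance
#'   (default 0.16).
#' @param im_ref,im_scale intramyocardial pressure reference chamber node
#'   and scale per outlet (recycled).
#' @return data.frame with one row per outlet: R_a, R_mu, R_v, C_a, C_im,
#'   im_ref, im_scale.
#' @export
coronary_bc_table <- function(outlet_ids, radii, shares, R_total,
                              C_total = 1e-6, ra_rmu_ratio = 0.38,
                              rv_fraction = 0.16,
                              im_ref = "LV", im_scale = 1.0) {
  stopifnot(length(outlet_ids) == length(radii))
  shares <- shares[as.character(outlet_ids)]
  if (anyNA(shares)) stop("shares must cover every outlet id")
  stopifnot(abs(sum(shares) - 1) < 1e-8)
  R_i <- R_total / shares
  f_am <- 1 - rv_fraction
  area <- radii^2
  C_i <- C_total * area / sum(area)
  data.frame(
    outlet_id = outlet_ids,
    R_a = R_i * f_am * ra_rmu_ratio / (1 + ra_rmu_ratio),
    R_mu = R_i * f_am / (1 + ra_rmu_ratio),
    R_v = R_i * rv_fraction,
    C_a = C_i * 0.11, C_im = C_i * 0.89,  # intramyocardial pool dominates
    im_ref = rep(im_ref, length.out = length(outlet_ids)),
    im_scale = rep(im_scale, length.out = length(outlet_ids)),
    stringsAsFactors = FALSE)
}

#' Attach coronary outlet boundary conditions
#'
#' For each outlet: `outlet -- R_a -- mu -- R_mu -- v -- R_v -- venous`,
#' with `C_a` grounded at the `mu` node and `C_im` at the `v` node
#' referenced to the intramyocardial pressure (a scaled chamber pressure).
#' The `mu` node is the microvascular pressure observable
#' `P_mu = P_outlet - Q R_a` in steady state.
#'
#' @param net an `lpn_network`.
#' @param outlet_nodes named character vector (outlet id -> node name).
#' @param bc a data.frame from [coronary_bc_table()].
#' @param venous_node node receiving coronary venous return (default
#'   `"GND"`; use the right-atrial node in a closed loop).
#' @return the updated network, with BC bookkeeping in
#'   `net$meta$coronary_bcs`.
#' @export
attach_outlet_bcs <- function(net, outlet_nodes, bc, venous_node = "GND") {
  ids <- names(outlet_nodes)
  if (!all(as.character(bc$outlet_id) %in% ids)) {
    stop("bc table contains outlets not present in outlet_nodes")
  }
  if (!all(ids %in% as.character(bc$outlet_id))) {
    stop("missing boundary condition for some outlets")
  }
  rows <- list()
  for (k in seq_len(nrow(bc))) {
    i <- as.character(bc$outlet_id[k])
    o_node <- outlet_nodes[[i]]
    mu <- paste0("mu_", i); vv <- paste0("v_", i)
    net <- net_add_element(net, paste0("Ra_", i), "R", o_node, mu,
                           R = bc$R_a[k])
    net <- net_add_element(net, paste0("Rmu_", i), "R", mu, vv,
                           R = bc$R_mu[k])
    net <- net_add_element(net, paste0("Rv_", i), "R", vv, venous_node,
                           R = bc$R_v[k])
    net <- net_add_capacitor(net, paste0("Ca_", i), mu, bc$C_a[k])
    net <- net_add_capacitor(net, paste0("Cim_", i), vv, bc$C_im[k],
                             ref_node = bc$im_ref[k],
                             ref_scale = bc$im_scale[k])
    rows[[k]] <- data.frame(outlet_id = bc$outlet_id[k], outlet_node = o_node,
                            mu_node = mu, v_node = vv,
                            stringsAsFactors = FALSE)
  }
  meta <- cbind(do.call(rbind, rows),
                bc[c("R_a", "R_mu", "R_v", "C_a", "C_im", "im_ref",
                     "im_scale")])
  meta$hyperemic <- FALSE
  net$meta$coronary_bcs <- rbind(net$meta$coronary_bcs, meta)
  net
}

#' Default closed-loop circulation parameters
#'
#' Physiologically initialized parameter set for [assemble_closed_loop()].
#' Elastances are in dyn/cm2/mL, resistances in dyn s/cm5, compliances in
#' cm5/dyn, times in seconds. These are starting values; Stage-1 tuning
#' adjusts them per patient.
#'
#' @param period cardiac period \[s\].
#' @param R_sys total systemic resistance \[dyn s/cm5\].
#' @return named list of parameters.
#' @export
default_lpn_params <- function(period = 60 / 70, R_sys = 1600) {
  mm <- MMHG_DYNCM2
  list(
    period = period,
    # chambers: elastance peaks/baselines (dyn/cm2/mL)
    E_max_lv = 2.8 * mm, E_min_lv = 0.10 * mm, V0_lv = 10,
    E_max_rv = 0.6 * mm, E_min_rv = 0.05 * mm, V0_rv = 10,
    E_max_la = 0.25 * mm, E_min_la = 0.15 * mm, V0_la = 5,
    E_max_ra = 0.20 * mm, E_min_ra = 0.12 * mm, V0_ra = 5,
    # activation timing (fractions of the period)
    vent_dur_frac = 0.35, atria_onset_frac = 0.85, atria_dur_frac = 0.12,
    # valves
    R_valve = 10, R_leak = 1e9, valve_width = 20,
    # systemic circuit
    R_sys = R_sys, sys_prox_frac = 0.06, C_ao = 0.28e-3, C_sys = 1.2e-3,
    C_ven = 0.08, R_ven = 80,
    # pulmonary circuit
    R_pul = 140, C_pa = 3e-3, C_pv = 8e-3, R_pv = 40,
    # coronary block (distal totals; distributed per outlet)
    R_cor_total = 60000, C_cor_total = 1e-6,
    im_scale_l = 1.0, im_scale_r = 0.5,
    # initial pressures (dyn/cm2) used to seed the periodic solve
    p0_ao = 90 * mm, p0_sys = 85 * mm, p0_ven = 9 * mm,
    p0_pa = 16 * mm, p0_pv = 9 * mm
  )
}

#' Assemble the closed-loop circulation network
#'
#' Four elastance chambers with smooth-diode valves, aortic and systemic
#' Windkessel compartments, a venous return compartment, a pulmonary RC
#' circuit, and (optionally) a coronary fragment whose inlet is tied to the
#' aortic root node `"AO"` and whose outlet boundary conditions drain into
#' the venous compartment.
#'
#' @param params parameter list, see [default_lpn_params()].
#' @param coronary optional list with `fragment` (from
#'   [build_rcl_from_tree()]) and `bc` (from [coronary_bc_table()]); or
#'   `NULL` for a heart + systemic + pulmonary loop only.
#' @return an `lpn_network` ready for [simulate_lpn()].
#' @export
assemble_closed_loop <- function(params = default_lpn_params(),
                                 coronary = NULL) {
  p <- params
  T_ <- p$period
  net <- lpn_network(period = T_)
  vd <- p$vent_dur_frac * T_
  ad <- p$atria_dur_frac * T_
  at <- p$atria_onset_frac * T_
  net <- net_add_chamber(net, "LV", "LV", p$E_max_lv, p$E_min_lv, p$V0_lv,
                         0, vd)
  net <- net_add_chamber(net, "RV", "RV", p$E_max_rv, p$E_min_rv, p$V0_rv,
                         0, vd)
  net <- net_add_chamber(net, "LA", "LA", p$E_max_la, p$E_min_la, p$V0_la,
                         at, ad)
  net <- net_add_chamber(net, "RA", "RA", p$E_max_ra, p$E_min_ra, p$V0_ra,
                         at, ad)
  vw <- p$valve_width
  net <- net_add_element(net, "mitral", "valve", "LA", "LV",
                         R = p$R_valve, p1 = p$R_leak, p2 = vw)
  net <- net_add_element(net, "aortic_valve", "valve", "LV", "AO",
                         R = p$R_valve, p1 = p$R_leak, p2 = vw)
  net <- net_add_element(net, "tricuspid", "valve", "RA", "RV",
                         R = p$R_valve, p1 = p$R_leak, p2 = vw)
  net <- net_add_element(net, "pulmonic", "valve", "RV", "PA",
                         R = p$R_valve, p1 = p$R_leak, p2 = vw)
  # systemic: AO -(Rp)- SA -(Rd)- VEN -(Rven)- RA
  net <- net_add_capacitor(net, "C_ao", "AO", p$C_ao)
  net <- net_add_element(net, "R_sys_p", "R", "AO", "SA",
                         R = p$R_sys * p$sys_prox_frac)
  net <- net_add_capacitor(net, "C_sys", "SA", p$C_sys)
  net <- net_add_element(net, "R_sys_d", "R", "SA", "VEN",
                         R = p$R_sys * (1 - p$sys_prox_frac))
  net <- net_add_capacitor(net, "C_ven", "VEN", p$C_ven)
  net <- net_add_element(net, "R_ven", "R", "VEN", "RA", R = p$R_ven)
  # pulmonary: PA -(Rpul)- PV -(Rpv)- LA
  net <- net_add_capacitor(net, "C_pa", "PA", p$C_pa)
  net <- net_add_element(net, "R_pul", "R", "PA", "PV", R = p$R_pul)
  net <- net_add_capacitor(net, "C_pv", "PV", p$C_pv)
  net <- net_add_element(net, "R_pv", "R", "PV", "LA", R = p$R_pv)

  if (!is.null(coronary)) {
    frag <- coronary$fragment
    # tie the fragment inlet to the aortic root
    frag$elements$node_a[frag$elements$node_a == frag$inlet_node] <- "AO"
    frag$elements$node_b[frag$elements$node_b == frag$inlet_node] <- "AO"
    net$elements <- rbind(net$elements, frag$elements)
    net$capacitors <- rbind(net$capacitors, frag$capacitors)
    net <- attach_outlet_bcs(net, frag$outlet_nodes, coronary$bc,
                             venous_node = "VEN")
    net$meta$tree_fragment <- frag
  }
  net$meta$params <- p
  net$meta$aortic_node <- "AO"
  net
}

#' Series and parallel resistor combination
#'
#' Small helpers used when reducing resistive fragments.
#' @param r numeric vector of resistances.
#' @return combined resistance.
#' @export
series_resistance <- function(r) sum(r)

#' @rdname series_resistance
#' @export
parallel_resistance <- function(r) 1 / sum(1 / r)

#' Equivalent steady resistance of a tree + outlet BC fragment
#'
#' Reduces the coronary fragment (Poiseuille resistances of all segments
#' with their distal boundary resistances) to one equivalent resistance as
#' seen from the inlet, by leaf-to-root series/parallel reduction.
#'
#' @param tree a `vessel_tree`.
#' @param outlet_R named vector: total distal resistance per outlet id.
#' @param fluid a [fluid_properties()].
#' @return equivalent resistance \[dyn s/cm5\].
#' @export
tree_equivalent_resistance <- function(tree, outlet_R,
                                       fluid = fluid_properties()) {
  seg <- tree$segments
  rseg <- segment_rcl(seg$length, seg$radius, fluid)$R
  kids <- tree_children(tree)
  req <- function(id) {
    i <- match(id, seg$id)
    ch <- kids[[as.character(id)]]
    down <- if (length(ch) == 0) {
      r <- outlet_R[[as.character(id)]]
      if (is.null(r)) stop("no outlet resistance for leaf ", id)
      r
    } else {
      parallel_resistance(vapply(ch, req, 0))
    }
    rseg[i] + down
  }
  req(tree$root)
}
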