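#' Left/right side of each coronary outlet
#'
#' The root's child whose subtree contains leaves not perfusing the LV is
#' taken as the right coronary main; outlets below it are `"R"`, all others
#' `"L"` (everything is `"L"` when no such leaves exist).
#'
#' @param tree a `vessel_tree`.
#' @return named character vector over outlet ids.
#' @export
tree_outlet_sides <- function(tree) {
  seg <- tree$segments
  leaves <- tree$outlet_ids
  kids <- tree_children(tree)
  root_children <- kids[[as.character(tree$root)]]
  side <- stats::setNames(rep("L", length(leaves)), leaves)
  nonlv <- leaves[!seg$perfuses_lv[match(leaves, seg$id)]]
  if (length(nonlv) == 0 || length(root_children) < 2) return(side)
  anc1 <- function(id) {
    path <- tree_path(tree, id)
    if (length(path) >= 2) path[2] else path[1]
  }
  right_main <- unique(vapply(nonlv, anc1, 0L))[1]
  for (l in leaves) if (anc1(l) == right_main) side[as.character(l)] <- "R"
  side
}

#' Build a personalized closed-loop network for a patient
#'
#' Combines the closed-loop circulation with the coronary tree: the full
#' RCL fragment of the (epicardial or combined) tree, or a reduced
#' single-branch equivalent (exact steady resistance, lumped compliance)
#' used to keep Stage-1 cardiac-function tuning fast. Distal coronary
#' boundary conditions take the total resistance/capacitance from `params`
#' and distribute them over outlets by the supplied flow shares.
#' Intramyocardial pressure is referenced to the LV chamber with scale
#' `im_scale_l` for left-tree outlets and `im_scale_r` for right-tree
#' outlets.
#'
#' @param params parameter list ([default_lpn_params()] style, with
#'   `R_cor_total`, `C_cor_total`, `im_scale_l`, `im_scale_r`).
#' @param tree a `vessel_tree`.
#' @param shares named outlet flow shares (sum to 1, e.g. from
#'   [murray_outlet_resistances()]).
#' @param reduce use the lumped coronary equivalent (default FALSE).
#' @param fluid a [fluid_properties()].
#' @return an `lpn_network` with rebuild information in `meta$builder`.
#' @export
build_patient_network <- function(params, tree, shares, reduce = FALSE,
                                  fluid = fluid_properties()) {
  seg <- tree$segments
  leaves <- tree$outlet_ids
  radii <- seg$radius[match(leaves, seg$id)]
  sides <- tree_outlet_sides(tree)
  outlet_R <- params$R_cor_total / shares[as.character(leaves)]

  if (reduce) {
    R_eq <- tree_equivalent_resistance(tree, outlet_R, fluid)
    R_epi <- max(R_eq - params$R_cor_total, 1)
    frag <- list(
      elements = data.frame(name = "creq_seg", type = "RL",
                            node_a = "creq_inlet", node_b = "creq_n0",
                            R = R_epi, L = 1.0, p1 = 0, p2 = 0, p3 = 0,
                            stringsAsFactors = FALSE),
      capacitors = empty_capacitors(),
      inlet_node = "creq_inlet",
      outlet_nodes = c(eq = "creq_n0"))
    bc <- coronary_bc_table(outlet_ids = "eq", radii = 1,
                            shares = c(eq = 1),
                            R_total = params$R_cor_total,
                            C_total = params$C_cor_total,
                            im_ref = "LV", im_scale = params$im_scale_l)
    bc$outlet_id <- "eq"
  } else {
    frag <- build_rcl_from_tree(tree, fluid)
    im_scale <- ifelse(sides[as.character(leaves)] == "R",
                       params$im_scale_r, params$im_scale_l)
    bc <- coronary_bc_table(outlet_ids = leaves, radii = radii,
                            shares = shares,
                            R_total = params$R_cor_total,
                            C_total = params$C_cor_total,
                            im_ref = "LV", im_scale = im_scale)
  }
  net <- assemble_closed_loop(params, coronary = list(fragment = frag,
                                                      bc = bc))
  net$meta$builder <- list(tree = tree, shares = shares, reduce = reduce,
                           fluid = fluid)
  net$meta$seg_nodes <- frag$seg_nodes
  net
}

#' Rebuild a patient network with updated parameters
#'
#' @param net a network from [build_patient_network()].
#' @param params replacement parameter list.
#' @return a new `lpn_network`.
#' @export
rebuild_network <- function(net, params) {
  b <- net$meta$builder
  if (is.null(b)) stop("network carries no builder metadata")
  build_patient_network(params, b$tree, b$shares, reduce = b$reduce,
                        fluid = b$fluid)
}

#' Source-driven steady surrogate of the coronary circuit
#'
#' Extracts the coronary fragment and outlet resistance chains from a
#' closed-loop network, drives the aortic node with a constant pressure
#' source, and grounds the venous return; used as the fast inner model of
#' the flow-distribution tuning loops. Capacitors drop out (they carry no
#' mean flow) and the intramyocardial pressure has zero cycle-mean effect
#' in this surrogate.
#'
#' @param net an `lpn_network` with coronary BCs.
#' @param p_ao aortic perfusion pressure \[dyn/cm2\].
#' @return an `lpn_network` suitable for [steady_solve()].
#' @export
coronary_steady_network <- function(net, p_ao) {
  el <- net$elements
  keep <- grepl("^(cor_|creq_)", el$name) |
    grepl("^(Ra_|Rmu_|Rv_)", el$name)
  el <- el[keep, ]
  el$node_a[el$node_a == "VEN"] <- "GND"
  el$node_b[el$node_b == "VEN"] <- "GND"
  out <- lpn_network(period = net$period)
  out$elements <- rbind(data.frame(name = "AO_src", type = "psource",
                                   node_a = "AO", node_b = "GND",
                                   R = 0, L = 0, p1 = p_ao, p2 = 0, p3 = 0,
                                   stringsAsFactors = FALSE),
                        el)
  out$meta$coronary_bcs <- net$meta$coronary_bcs
  out$meta$aortic_node <- "AO"
  out
}
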