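TYPE_CODES <- c(R = 0L, RL = 1L, valve = 2L, psource = 3L, qsource = 4L,
                stenosis = 5L)

#' Compile a network for the integrator
#'
#' Indexes nodes, flows and chambers and packs element tables into the flat
#' arrays consumed by the C++ backward-Euler stepper. Exposed mainly for
#' testing; [simulate_lpn()] calls it internally.
#'
#' @param net an `lpn_network`.
#' @return a compiled spec (list) with index maps in `$nodes`,
#'   `$flow_names`, `$chamber_names`.
#' @export
network_compile <- function(net) {
  el <- net$elements
  cp <- net$capacitors
  ch <- net$chambers
  nodes <- setdiff(unique(c(el$node_a, el$node_b, cp$node,
                            cp$ref_node[!is.na(cp$ref_node)], ch$node)),
                   "GND")
  if (length(nodes) == 0L) stop("network has no nodes")
  nid <- function(x) {
    out <- ifelse(x == "GND", -1L, match(x, nodes) - 1L)
    if (anyNA(out)) stop("unknown node: ", paste(x[is.na(out)], collapse = ", "))
    as.integer(out)
  }
  m <- nrow(el)
  elem_i <- cbind(type = TYPE_CODES[el$type],
                  a = nid(el$node_a), b = nid(el$node_b),
                  f = seq_len(m) - 1L)
  elem_p <- cbind(el$R, el$L, el$p1, el$p2, el$p3)
  ref_idx <- rep(-1L, nrow(cp))
  has_ref <- !is.na(cp$ref_node)
  ref_idx[has_ref] <- nid(cp$ref_node[has_ref])
  cap_i <- cbind(nid(cp$node), ref_idx)
  cap_p <- cbind(cp$C, cp$ref_scale)
  storage.mode(elem_i) <- "integer"
  storage.mode(cap_i) <- "integer"
  list(n_nodes = length(nodes), n_flows = m, n_chambers = nrow(ch),
       elem_i = elem_i, elem_p = elem_p,
       cap_i = matrix(cap_i, ncol = 2), cap_p = matrix(cap_p, ncol = 2),
       ch_node = nid(ch$node),
       ch_p = matrix(cbind(ch$E_max, ch$E_min, ch$V0, ch$t_on, ch$duration),
                     ncol = 5),
       period = net$period,
       nodes = nodes, flow_names = el$name, chamber_names = ch$name)
}

#' Initial state for a closed-loop simulation
#'
#' Seeds node pressures from the `p0_*` entries of the network's parameter
#' list (aortic/systemic/venous/pulmonary compartments; coronary nodes start
#' at aortic pressure) and chamber volumes consistent with baseline
#' elastance at those filling pressures. The initial state fixes the total
#' blood volume of the closed loop, which is conserved thereafter.
#'
#' @param net an `lpn_network`.
#' @param spec compiled spec from [network_compile()].
#' @return numeric state vector.
#' @export
initial_state <- function(net, spec = network_compile(net)) {
  p <- net$meta$params
  n <- spec$n_nodes + spec$n_flows + spec$n_chambers
  y <- numeric(n)
  P <- numeric(spec$n_nodes)
  if (!is.null(p)) {
    defaults <- c(AO = p$p0_ao, SA = p$p0_sys, VEN = p$p0_ven,
                  PA = p$p0_pa, PV = p$p0_pv,
                  LV = p$p0_pv, LA = p$p0_pv, RV = p$p0_ven, RA = p$p0_ven)
    P <- rep(p$p0_ao, spec$n_nodes)  # coronary tree nodes near aortic
    named <- intersect(names(defaults), spec$nodes)
    P[match(named, spec$nodes)] <- defaults[named]
    mu_like <- grepl("^(mu|v)_", spec$nodes)
    P[mu_like] <- 0.4 * p$p0_ao
  }
  y[seq_len(spec$n_nodes)] <- P
  if (spec$n_chambers > 0) {
    ch <- net$chambers
    pch <- P[match(ch$node, spec$nodes)]
    y[spec$n_nodes + spec$n_flows + seq_len(spec$n_chambers)] <-
      ch$V0 + pch / ch$E_min
  }
  y
}

#' Integrate a network to periodic convergence
#'
#' Backward-Euler time integration (Newton per step, step halving on
#' divergence) of the network DAE, cycle by cycle, until the largest
#' blockwise relative cycle-to-cycle state change drops below
#' `periodicity_tol` or `n_cycles_max` is reached. The returned waveforms
#' cover the final (converged) cycle.
#'
#' @param net an `lpn_network`.
#' @param n_cycles_max maximum number of cardiac cycles (default 20).
#' @param dt time step \[s\]; default `period/2000`.
#' @param periodicity_tol relative periodicity tolerance (default 1e-3).
#' @param y0 optional initial state (default [initial_state()]).
#' @return object of class `lpn_result`: `time`, `pressures` (matrix, one
#'   column per node, mmHg columns? no - CGS), `flows` \[mL/s\], `volumes`
#'   \[mL\], cycle-averaged `mean_pressure`/`mean_flow`, `converged`,
#'   `cycles`, `metrics` (via [cardiac_metrics()] when the network has an
#'   aortic node and LV chamber).
#' @export
simulate_lpn <- function(net, n_cycles_max = 20L, dt = NULL,
                         periodicity_tol = 1e-3, y0 = NULL) {
  spec <- network_compile(net)
  if (is.null(dt)) dt <- net$period / 2000
  steps <- max(2L, as.integer(round(net$period / dt)))
  dt <- net$period / steps
  if (is.null(y0)) y0 <- initial_state(net, spec)
  raw <- .lpn_run_cpp(spec, y0, dt, steps, as.integer(n_cycles_max),
                      periodicity_tol)
  traj <- raw$traj
  nn <- spec$n_nodes; nf <- spec$n_flows; nc <- spec$n_chambers
  pressures <- traj[, seq_len(nn), drop = FALSE]
  colnames(pressures) <- spec$nodes
  flows <- traj[, nn + seq_len(nf), drop = FALSE]
  colnames(flows) <- spec$flow_names
  volumes <- if (nc > 0) {
    v <- traj[, nn + nf + seq_len(nc), drop = FALSE]
    colnames(v) <- spec$chamber_names
    v
  } else NULL
  # trapezoid cycle averages on the uniform grid
  w <- c(0.5, rep(1, steps - 1), 0.5) / steps
  res <- structure(list(
    time = seq(0, net$period, length.out = steps + 1),
    dt = dt, period = net$period,
    pressures = pressures, flows = flows, volumes = volumes,
    mean_pressure = colSums(pressures * w),
    mean_flow = colSums(flows * w),
    converged = raw$converged, cycles = raw$cycles,
    conv_history = raw$conv_history[seq_len(raw$cycles)],
    y_end = as.numeric(raw$y_end),
    network = net
  ), class = "lpn_result")
  if ("AO" %in% spec$nodes && "LV" %in% spec$chamber_names) {
    res$metrics <- cardiac_metrics(res)
  }
  res
}

#' @export
print.lpn_result <- function(x, ...) {
  cat("lpn_result:", x$cycles, "cycles,",
      if (x$converged) "periodic" else "NOT converged", "\n")
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  BP %.1f/%.1f mmHg, SV %.1f mL, EF %.3f, CO %.2f L/min\n",
                m$sbp, m$dbp, m$stroke_volume, m$ejection_fraction,
                m$cardiac_output))
  }
  invisible(x)
}

#' Clinical metrics from a converged result
#'
#' Systolic/diastolic pressure are the max/min aortic pressure over the
#' final cycle (mmHg); stroke volume is EDV - ESV of the LV chamber, the
#' ejection fraction SV/EDV, and cardiac output SV times heart rate.
#'
#' @param result an `lpn_result` from a network with an `"AO"` node and an
#'   `"LV"` chamber.
#' @param aortic_node aortic node name (default `"AO"`).
#' @return list: sbp, dbp \[mmHg\], stroke_volume, edv, esv \[mL\],
#'   ejection_fraction, cardiac_output \[L/min\], mean_aortic_flow \[mL/s\].
#' @export
cardiac_metrics <- function(result, aortic_node = "AO") {
  pao <- result$pressures[, aortic_node]
  vlv <- result$volumes[, "LV"]
  edv <- max(vlv); esv <- min(vlv)
  sv <- edv - esv
  hr <- 60 / result$period
  qao <- if ("aortic_valve" %in% colnames(result$flows))
    result$mean_flow[["aortic_valve"]] else NA_real_
  list(sbp = cgs_to_mmHg(max(pao)), dbp = cgs_to_mmHg(min(pao)),
       stroke_volume = sv, edv = edv, esv = esv,
       ejection_fraction = sv / edv,
       cardiac_output = sv * hr / 1000,
       mean_aortic_flow = qao)
}

#' Steady (cycle-averaged surrogate) solve of a resistive network
#'
#' Solves the linear resistive skeleton: capacitors carry no flow, inductors
#' are short circuits, valves are taken at their open resistance, and
#' pressure/flow sources keep their mean values. Exact for pure-resistor
#' networks; networks containing chambers are rejected (drive them with a
#' `psource` instead).
#'
#' @param net an `lpn_network`.
#' @return list with named `pressures` \[dyn/cm2\] and `flows` \[mL/s\].
#' @export
steady_solve <- function(net) {
  if (nrow(net$chambers) > 0) {
    stop("steady_solve requires a source-driven network without chambers")
  }
  el <- net$elements
  nodes <- setdiff(unique(c(el$node_a, el$node_b)), "GND")
  nn <- length(nodes); m <- nrow(el)
  n <- nn + m
  nid <- function(x) ifelse(x == "GND", NA_integer_, match(x, nodes))
  ia <- nid(el$node_a); ib <- nid(el$node_b)
  rows <- nn + seq_len(m)
  resistive <- el$type %in% c("R", "RL", "stenosis", "valve")
  pres <- el$type == "psource"
  qsrc <- el$type == "qsource"
  drops <- resistive | pres
  # triplets: node balances, pressure-drop rows, flow-definition rows
  trip_i <- c(ia[!is.na(ia)], ib[!is.na(ib)],
              rows[drops & !is.na(ia)], rows[drops & !is.na(ib)],
              rows[resistive], rows[qsrc])
  trip_j <- c(rows[!is.na(ia)], rows[!is.na(ib)],
              ia[drops & !is.na(ia)], ib[drops & !is.na(ib)],
              rows[resistive], rows[qsrc])
  trip_x <- c(rep(-1, sum(!is.na(ia))), rep(1, sum(!is.na(ib))),
              rep(1, sum(drops & !is.na(ia))),
              rep(-1, sum(drops & !is.na(ib))),
              -el$R[resistive], rep(1, sum(qsrc)))
  rhs <- numeric(n)
  rhs[rows[pres]] <- el$p1[pres]
  rhs[rows[qsrc]] <- el$p1[qsrc]
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, n))
  sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                  error = function(e) stop("singular steady-state system: ",
                                           conditionMessage(e)))
  list(pressures = stats::setNames(sol[seq_len(nn)], nodes),
       flows = stats::setNames(sol[nn + seq_len(m)], el$name))
}

#' Cycle-mean pressures from a result or steady solution
#' @param x an `lpn_result` or the list returned by [steady_solve()].
#' @return named vector of mean nodal pressures \[dyn/cm2\].
#' @export
mean_pressures <- function(x) {
  if (inherits(x, "lpn_result")) x$mean_pressure else x$pressures
}

#' Cycle-mean flows from a result or steady solution
#' @param x an `lpn_result` or a [steady_solve()] return value.
#' @return named vector of mean element flows \[mL/s\].
#' @export
mean_flows <- function(x) {
  if (inherits(x, "lpn_result")) x$mean_flow else x$flows
}

#' Fractional flow reserve along a branch
#'
#' FFR at a point is the cycle-mean pressure there divided by the mean
#' aortic pressure, computed at every 0D node along the root-to-outlet path
#' and reported against the normalized arc length s in \[0, 1\] (0 = ostium,
#' 1 = outlet). Must be evaluated on a hyperemic solution to carry its
#' clinical meaning; the conventional positivity threshold is 0.80.
#'
#' @param x an `lpn_result` or [steady_solve()] solution (hyperemic).
#' @param tree the `vessel_tree` the network embeds.
#' @param seg_nodes named map segment id -> network node (from
#'   [build_rcl_from_tree()]).
#' @param outlet_id target outlet segment id.
#' @param aortic_node network node holding aortic pressure.
#' @return data.frame with `s`, `node`, `pressure_mmHg`, `ffr`, plus
#'   attributes `min_ffr` and `positive` (min FFR < 0.80).
#' @export
compute_ffr <- function(x, tree, seg_nodes, outlet_id, aortic_node = "AO") {
  P <- mean_pressures(x)
  path <- tree_path(tree, outlet_id)
  nodes <- c(aortic_node, unname(seg_nodes[as.character(path)]))
  if (anyNA(nodes) || !all(nodes %in% names(P))) {
    stop("path nodes missing from the solution (non-contiguous path?)")
  }
  lens <- tree$segments$length[match(path, tree$segments$id)]
  s <- c(0, cumsum(lens)) / sum(lens)
  ffr <- as.numeric(P[nodes] / P[[aortic_node]])
  out <- data.frame(s = s, node = nodes,
                    pressure_mmHg = cgs_to_mmHg(as.numeric(P[nodes])),
                    ffr = ffr)
  attr(out, "min_ffr") <- min(ffr)
  attr(out, "positive") <- min(ffr) < 0.80
  out
}

#' Per-outlet cycle-averaged summary
#'
#' Mean outlet pressure, flow (through the small-artery resistance) and
#' microvascular pressure for every coronary outlet boundary condition in
#' the network.
#'
#' @param net an `lpn_network` with coronary BCs attached.
#' @param x an `lpn_result` or [steady_solve()] solution on that network.
#' @return data.frame: outlet_id, P \[dyn/cm2\], Q \[mL/s\], P_mu
#'   \[dyn/cm2\].
#' @export
outlet_summary <- function(net, x) {
  bc <- net$meta$coronary_bcs
  if (is.null(bc)) stop("network has no coronary outlet BCs")
  P <- mean_pressures(x); Q <- mean_flows(x)
  data.frame(outlet_id = bc$outlet_id,
             P = as.numeric(P[bc$outlet_node]),
             Q = as.numeric(Q[paste0("Ra_", bc$outlet_id)]),
             P_mu = as.numeric(P[bc$mu_node]))
}
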