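#' Synthetic patient configuration
#'
#' Describes the stated world of the generator: a truncated prolate-spheroid
#' LV shell, an epicardial coronary tree with a prescribed number of
#' LV-perfusing outlets, ground-truth outlet flows that deviate from the
#' diameter (Murray) law by a lognormal dispersion, an MBF field consistent
#' with those flows, and cardiac-function targets.
#'
#' @param seed integer seed controlling every random choice.
#' @param n_lv_outlets number of LV-perfusing epicardial outlets (default 16,
#'   the typical count resolvable from coronary CT angiography).
#' @param n_nonlv_outlets proximal right-coronary outlets not perfusing the
#'   LV (default 2).
#' @param sigma lognormal dispersion of true flows about the Murray split
#'   (default 0.4; 0 makes truth equal Murray).
#' @param mbf_noise_cv multiplicative noise CV of the nodal MBF field
#'   (default 0.2).
#' @param targets `clinical_targets` (default [preset_targets()] patient 2).
#' @param lv geometry list: outer semi-axes `a` (short) and `c` (long)
#'   \[cm\], wall `thickness` \[cm\], `base_frac` (truncation height as a
#'   fraction of `c`), and mesh resolution `nu`, `nv`, `nw` (circumferential,
#'   longitudinal, transmural cell counts).
#' @return object of class `synthetic_patient_config`.
#' @export
synthetic_patient_config <- function(seed = 1L,
                                     n_lv_outlets = 16L,
                                     n_nonlv_outlets = 2L,
                                     sigma = 0.4,
                                     mbf_noise_cv = 0.2,
                                     targets = preset_targets(2L),
                                     lv = list()) {
  lv_def <- list(a = 3.5, c = 4.5, thickness = 1.05, base_frac = 0.25,
                 nu = 24L, nv = 12L, nw = 3L)
  lv <- utils::modifyList(lv_def, lv)
  stopifnot(n_lv_outlets >= 2L, sigma >= 0, mbf_noise_cv >= 0)
  if (lv$thickness <= 0) stop("wall thickness must be positive")
  if (lv$thickness >= min(lv$a, lv$c)) stop("wall thicker than semi-axes")
  structure(list(seed = as.integer(seed),
                 n_lv_outlets = as.integer(n_lv_outlets),
                 n_nonlv_outlets = as.integer(n_nonlv_outlets),
                 sigma = sigma, mbf_noise_cv = mbf_noise_cv,
                 targets = targets, lv = lv),
            class = "synthetic_patient_config")
}

#' Generate the LV shell mesh
#'
#' Builds a truncated prolate-spheroid myocardial shell (long axis along z,
#' apex at negative z, base plane at `base_frac * c`) by structured
#' parametric subdivision into hexahedra, each split into six conforming
#' tetrahedra. Fully deterministic.
#'
#' @param config a `synthetic_patient_config`.
#' @return an `lv_mesh`.
#' @export
make_lv_mesh <- function(config) {
  g <- config$lv
  nu <- g$nu; nv <- g$nv; nw <- g$nw
  if (nu * (nv + 1) * (nw + 1) < 500) stop("resolution must yield >= 500 nodes")
  a_out <- g$a; c_out <- g$c
  a_in <- g$a - g$thickness; c_in <- g$c - g$thickness
  th_base <- acos(g$base_frac)
  th_apex <- pi * 0.97  # leave a tiny apical opening; avoids the pole singularity
  phi <- 2 * pi * (0:(nu - 1)) / nu
  theta <- seq(th_base, th_apex, length.out = nv + 1)
  wfrac <- (0:nw) / nw

  idx <- function(i, j, k) {
    # i wraps circumferentially; j in 0..nv; k in 0..nw; 1-based node index
    ii <- i %% nu
    ii + nu * (j + (nv + 1) * k) + 1L
  }
  nodes <- matrix(0, nu * (nv + 1) * (nw + 1), 3)
  for (k in 0:nw) {
    aa <- a_in + wfrac[k + 1] * (a_out - a_in)
    cc <- c_in + wfrac[k + 1] * (c_out - c_in)
    for (j in 0:nv) {
      st <- sin(theta[j + 1]); ct <- cos(theta[j + 1])
      rows <- idx(0:(nu - 1), j, k)
      nodes[rows, ] <- cbind(aa * st * cos(phi), aa * st * sin(phi),
                             cc * ct)
    }
  }

  # six-tet decomposition of each hex along the (0,6) diagonal; the split is
  # face-conforming across neighbors, including the circumferential wrap
  tet_local <- matrix(c(1, 2, 3, 7,
                        1, 3, 4, 7,
                        1, 4, 8, 7,
                        1, 8, 5, 7,
                        1, 5, 6, 7,
                        1, 6, 2, 7), ncol = 4, byrow = TRUE)
  tets <- matrix(0L, 6L * nu * nv * nw, 4)
  row <- 0L
  for (k in 0:(nw - 1)) for (j in 0:(nv - 1)) for (i in 0:(nu - 1)) {
    corners <- c(idx(i, j, k), idx(i + 1, j, k), idx(i + 1, j + 1, k),
                 idx(i, j + 1, k), idx(i, j, k + 1), idx(i + 1, j, k + 1),
                 idx(i + 1, j + 1, k + 1), idx(i, j + 1, k + 1))
    tets[row + 1:6, ] <- matrix(corners[t(tet_local)], ncol = 4, byrow = TRUE)
    row <- row + 6L
  }
  mesh <- lv_mesh(nodes, tets, validate = FALSE)
  vols <- tet_volumes(mesh)
  flip <- vols < 0
  if (any(flip)) {
    tmp <- mesh$tets[flip, 3]
    mesh$tets[flip, 3] <- mesh$tets[flip, 4]
    mesh$tets[flip, 4] <- tmp
  }
  lv_mesh(mesh$nodes, mesh$tets)
}

# evenly spread points on the outer epicardial surface (golden-angle spiral
# in the (theta, phi) parameter patch), with small seeded jitter
epicardial_points <- function(config, n, rng_offset = 0L) {
  g <- config$lv
  th_base <- acos(g$base_frac)
  th_lo <- th_base + 0.12 * (pi - th_base)
  th_hi <- th_base + 0.92 * (pi * 0.97 - th_base)
  set.seed(config$seed + rng_offset)
  golden <- pi * (3 - sqrt(5))
  u <- ((0:(n - 1)) + 0.5) / n
  theta <- th_lo + u * (th_hi - th_lo) + stats::runif(n, -0.02, 0.02)
  phi <- ((0:(n - 1)) * golden) %% (2 * pi) + stats::runif(n, -0.05, 0.05)
  cbind(x = g$a * sin(theta) * cos(phi),
        y = g$a * sin(theta) * sin(phi),
        z = g$c * cos(theta))
}

# recursive binary clustering of outlet targets into an epicardial tree;
# returns a list of segment rows; ids assigned later
cluster_tree <- function(points, start, lift) {
  n <- nrow(points)
  if (n == 1L) {
    return(list(list(p0 = start, p1 = points[1, ], terminal = TRUE,
                     point_row = as.integer(rownames(points)[1]))))
  }
  ctr <- colMeans(points)
  dev <- sweep(points, 2, ctr)
  pc <- svd(dev, nu = 0, nv = 1)$v[, 1]
  proj <- as.numeric(dev %*% pc)
  left <- proj <= stats::median(proj)
  if (all(left) || !any(left)) left <- seq_len(n) <= n / 2
  mk_way <- function(sub) {
    w <- colMeans(sub)
    w * lift  # push the waypoint outward, off the epicardial surface
  }
  out <- list()
  for (side in list(points[left, , drop = FALSE],
                    points[!left, , drop = FALSE])) {
    way <- if (nrow(side) == 1L) side[1, ] else mk_way(side)
    child <- list(p0 = start, p1 = way, terminal = nrow(side) == 1L,
                  point_row = if (nrow(side) == 1L)
                    as.integer(rownames(side)[1]) else NA_integer_)
    if (nrow(side) == 1L) {
      out <- c(out, list(child))
    } else {
      out <- c(out, list(child), lapply(cluster_tree(side, way, lift),
                                        function(s) s))
    }
  }
  out
}

# rebuild parent links: cluster_tree returns segments whose p0 matches the
# parent's p1 exactly; link by coordinates
link_segments <- function(segs, root_p1) {
  n <- length(segs)
  parent <- rep(NA_integer_, n)
  p1s <- t(vapply(segs, function(s) s$p1, numeric(3)))
  for (i in seq_len(n)) {
    p0 <- segs[[i]]$p0
    if (sqrt(sum((p0 - root_p1)^2)) < 1e-12) next
    d <- sqrt(rowSums(sweep(p1s, 2, p0)^2))
    j <- which(d < 1e-9)
    parent[i] <- j[1]
  }
  parent
}

#' Generate the epicardial coronary tree
#'
#' Aortic root feeding left and right coronary mains; the left main and the
#' distal right coronary bifurcate recursively toward `n_lv_outlets` outlets
#' on the epicardial surface. Proximal right-coronary leaves are flagged as
#' not perfusing the LV. Radii are assigned top-down by Murray's bifurcation
#' law (gamma = 3) with flow shares proportional to subtree leaf counts.
#'
#' @param config a `synthetic_patient_config`.
#' @param mesh the matching `lv_mesh` (defines the epicardial surface).
#' @return a `vessel_tree`.
#' @export
make_epicardial_tree <- function(config, mesh) {
  g <- config$lv
  n_lv <- config$n_lv_outlets
  n_rv <- config$n_nonlv_outlets
  pts <- epicardial_points(config, n_lv)
  rownames(pts) <- seq_len(n_lv)
  # split outlets into a left (LCA) and right (RCA) sector by azimuth
  phi <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  right <- phi > 4 * pi / 3
  if (!any(right)) right[which.max(phi)] <- TRUE
  if (all(right)) right[which.min(phi)] <- FALSE
  lift <- 1.12  # waypoints course just above the epicardium

  base_z <- g$base_frac * g$c
  ostium <- c(0.9, 0.0, base_z + 1.4)
  lm_end <- c(1.8, 1.2, base_z + 0.2)
  rca_end <- c(1.6, -1.6, base_z + 0.1)

  segs <- list()
  add <- function(p0, p1, terminal = FALSE, point_row = NA_integer_) {
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, terminal = terminal,
                                       point_row = point_row)
    length(segs)
  }
  parent <- integer(0)
  add_linked <- function(p0, p1, par, terminal = FALSE,
                         point_row = NA_integer_) {
    i <- add(p0, p1, terminal, point_row)
    parent[i] <<- par
    i
  }
  root_i <- add(ostium + c(0, 0, 1.2), ostium)   # aortic root stub
  parent[root_i] <- NA_integer_
  lm_i <- add_linked(ostium, lm_end, root_i)
  rca_i <- add_linked(ostium, rca_end, root_i)

  attach_cluster <- function(points, start, par) {
    sub <- cluster_tree(points, start, lift)
    sub_parent <- link_segments(sub, start)
    base <- length(segs)
    for (s in sub) add(s$p0, s$p1, s$terminal, s$point_row)
    for (k in seq_along(sub)) {
      parent[base + k] <<- if (is.na(sub_parent[k])) par else base + sub_parent[k]
    }
  }
  attach_cluster(pts[!right, , drop = FALSE], lm_end, lm_i)

  # proximal RCA: chain of bifurcations shedding non-LV (right ventricular)
  # marginal branches before reaching the right LV sector
  cur <- rca_i
  cur_end <- rca_end
  for (k in seq_len(n_rv)) {
    t_frac <- k / (n_rv + 1)
    nxt_end <- cur_end + c(-0.4, -0.6, -0.9)
    marg_end <- cur_end + c(0.9 + 0.15 * k, -1.1, -0.8 * k)
    m_i <- add_linked(cur_end, marg_end, cur, terminal = TRUE)  # non-LV leaf
    c_i <- add_linked(cur_end, nxt_end, cur)
    cur <- c_i
    cur_end <- nxt_end
  }
  attach_cluster(pts[right, , drop = FALSE], cur_end, cur)

  n <- length(segs)
  df <- data.frame(
    id = 0:(n - 1L),
    parent = ifelse(is.na(parent), NA_integer_, parent - 1L),
    x0 = vapply(segs, function(s) s$p0[1], 0),
    y0 = vapply(segs, function(s) s$p0[2], 0),
    z0 = vapply(segs, function(s) s$p0[3], 0),
    x1 = vapply(segs, function(s) s$p1[1], 0),
    y1 = vapply(segs, function(s) s$p1[2], 0),
    z1 = vapply(segs, function(s) s$p1[3], 0),
    radius = 0.1,
    origin = "image_based",
    perfuses_lv = TRUE
  )
  term <- vapply(segs, function(s) s$terminal, TRUE)
  has_point <- !is.na(vapply(segs, function(s) s$point_row, 0L))
  df$perfuses_lv <- TRUE
  df$perfuses_lv[term & !has_point] <- FALSE  # RV marginals

  # leaf counts below each segment -> Murray radii top-down
  nleaf <- integer(n)
  order_desc <- rev(topo_order(df))
  kids <- split(seq_len(n)[!is.na(parent)], parent[!is.na(parent)])
  for (i in order_desc) {
    ch <- kids[[as.character(i)]]
    nleaf[i] <- if (is.null(ch)) 1L else sum(nleaf[ch])
  }
  radius <- numeric(n)
  radius[root_i] <- 0.45          # aortic root stub
  radius[lm_i] <- 0.22            # left main
  radius[rca_i] <- 0.20           # right coronary
  for (i in topo_order(df)) {
    ch <- kids[[as.character(i)]]
    if (is.null(ch) || i == root_i) next
    radius[ch] <- pmin(radius[i] * (nleaf[ch] / sum(nleaf[ch]))^(1 / 3),
                       radius[i])
  }
  df$radius <- radius
  vessel_tree(df, root = 0L)
}

# topological order (parents before children) over 1-based row indices of a
# segment frame with 0-based ids
topo_order <- function(df) {
  n <- nrow(df)
  parent_row <- match(df$parent, df$id)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (!is.na(parent_row[j])) { d <- d + 1L; j <- parent_row[j] }
    depth[i] <- d
  }
  order(depth)
}

#' Ground-truth outlet flows
#'
#' Murray-law flow shares (proportional to outlet diameter^2.6) perturbed by
#' seeded lognormal multipliers and renormalized, then scaled to the
#' morphometric total LV flow. With `sigma = 0` the truth equals the Murray
#' split exactly; with `sigma > 0` the true flow distribution deviates from
#' any diameter law, emulating the clinically observed absence of a
#' consistent diameter-flow relationship.
#'
#' @param config a `synthetic_patient_config`.
#' @param tree the epicardial `vessel_tree`.
#' @param v_lv LV myocardial volume \[mL\] (for the morphometric total).
#' @return named vector of true flows \[mL/s\] over LV outlet ids, with
#'   attribute `fractions`.
#' @export
make_ground_truth_flows <- function(config, tree, v_lv) {
  op <- outlet_points(tree, lv_only = TRUE)
  ids <- as.integer(rownames(op))
  d <- 2 * tree$segments$radius[match(ids, tree$segments$id)]
  murray <- d^2.6 / sum(d^2.6)
  set.seed(config$seed + 1000L)
  mult <- stats::rlnorm(length(ids), meanlog = 0, sdlog = config$sigma)
  frac <- murray * mult
  frac <- frac / sum(frac)
  q_lv <- morphometric_q_lv(v_lv) / 60  # mL/min -> mL/s
  flows <- stats::setNames(frac * q_lv, ids)
  attr(flows, "fractions") <- stats::setNames(frac, ids)
  flows
}

#' Synthesize the nodal MBF field
#'
#' Piecewise-uniform MBF per territory whose control-volume integral equals
#' each true flow, multiplied by lognormal noise with coefficient of
#' variation `mbf_noise_cv`, then renormalized per territory so the
#' integrals are preserved exactly. Units: mL/min per 100 mL tissue.
#'
#' @param config a `synthetic_patient_config`.
#' @param mesh an `lv_mesh`.
#' @param map a `territory_map` covering the mesh.
#' @param true_flows named per-outlet flows \[mL/s\].
#' @return numeric nodal MBF vector.
#' @export
make_mbf_field <- function(config, mesh, map, true_flows) {
  cv_node <- node_control_volumes(mesh)
  vol <- territory_volumes(mesh, map)
  ids <- map$outlet_ids
  if (!all(as.character(ids) %in% names(true_flows))) {
    stop("true_flows must cover every territory outlet")
  }
  base <- true_flows[as.character(map$nodal_label)] * 60 * 100 /
    vol[as.character(map$nodal_label)]
  set.seed(config$seed + 2000L)
  cvn <- config$mbf_noise_cv
  noise <- if (cvn > 0) {
    sdl <- sqrt(log(1 + cvn^2))
    stats::rlnorm(length(base), meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, length(base))
  mbf <- as.numeric(base * noise)
  # exact renormalization territory by territory
  for (i in ids) {
    sel <- map$nodal_label == i
    integral <- sum(mbf[sel] * cv_node[sel] / 100) / 60
    mbf[sel] <- mbf[sel] * true_flows[[as.character(i)]] / integral
  }
  mbf
}

#' Generate a complete synthetic patient
#'
#' Runs the generator end to end: LV mesh, epicardial tree, Voronoi
#' territories, ground-truth flows, and a consistent noisy MBF field
#' attached to the mesh.
#'
#' @param config a `synthetic_patient_config`.
#' @return list with `mesh` (MBF attached), `tree`, `map`, `true_flows`,
#'   `targets`, `config`.
#' @export
make_patient <- function(config = synthetic_patient_config()) {
  mesh <- make_lv_mesh(config)
  tree <- make_epicardial_tree(config, mesh)
  map <- assign_territories(mesh, outlet_points(tree, lv_only = TRUE))
  map$territory_volume <- territory_volumes(mesh, map)
  v_lv <- sum(map$territory_volume)
  true_flows <- make_ground_truth_flows(config, tree, v_lv)
  mesh$nodal_mbf <- make_mbf_field(config, mesh, map, true_flows)
  mb <- integrate_mbf(mesh, map)
  map$territory_flow <- mb$territory_flow
  map$q_lv <- mb$q_lv
  map$flow_fraction <- flow_fractions(mb$territory_flow)
  map$v_lv <- v_lv
  list(mesh = mesh, tree = tree, map = map, true_flows = true_flows,
       targets = config$targets, config = config)
}
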