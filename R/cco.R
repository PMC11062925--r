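#' CCO growth configuration
#'
#' Controls constrained constructive optimization: total terminal count
#' across all territories, the Murray bifurcation exponent used for radii,
#' the candidate/connection search effort, and the terminal radius floor
#' (about 300 um diameter, the smallest caliber the lumped representation
#' is meant to cover).
#'
#' @param total_terminals terminals across all trees (default 500).
#' @param murray_gamma bifurcation radius exponent (default 3).
#' @param candidate_attempts rejection-sampling attempts before the spacing
#'   threshold is relaxed (default 10).
#' @param k_neighbors candidate segments tried per insertion (default 5).
#' @param seed base seed; tree for outlet `i` uses `seed + i`.
#' @param min_terminal_radius radius floor \[cm\] (default 0.015).
#' @param d_thresh_coef spacing coefficient `c` in
#'   `d_thresh = c (V/n)^(1/3)` (default 0.5).
#' @return object of class `cco_config`.
#' @export
cco_config <- function(total_terminals = 500L, murray_gamma = 3,
                       candidate_attempts = 10L, k_neighbors = 5L,
                       seed = 1L, min_terminal_radius = 0.015,
                       d_thresh_coef = 0.5) {
  stopifnot(total_terminals >= 1L, murray_gamma > 0)
  structure(list(total_terminals = as.integer(total_terminals),
                 murray_gamma = murray_gamma,
                 candidate_attempts = as.integer(candidate_attempts),
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed),
                 min_terminal_radius = min_terminal_radius,
                 d_thresh_coef = d_thresh_coef),
            class = "cco_config")
}

#' Allocate terminals to territories
#'
#' Counts proportional to territory volumes, rounded by largest remainder so
#' they sum exactly to `total_terminals`, with every territory receiving at
#' least one terminal.
#'
#' @param territory_volumes named positive volumes \[mL\].
#' @param total_terminals total terminal count.
#' @return named integer vector summing to `total_terminals`.
#' @export
allocate_terminals <- function(territory_volumes, total_terminals) {
  v <- territory_volumes
  stopifnot(all(v > 0))
  n <- length(v)
  if (total_terminals < n) {
    stop("total_terminals must be at least the number of territories")
  }
  quota <- v / sum(v) * total_terminals
  base <- floor(quota)
  rem <- total_terminals - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  while (any(base == 0)) {
    base[which.max(base)] <- base[which.max(base)] - 1
    base[which(base == 0)[1]] <- 1
  }
  stats::setNames(as.integer(base), names(v))
}

# total intravascular volume of a growing tree (flows = leaf counts)
cco_tree_volume <- function(lengths, nleaf, n_total, root_radius, gamma) {
  r2 <- root_radius^2 * (nleaf / n_total)^(2 / gamma)
  sum(pi * r2 * lengths)
}

# distance from one point to each segment [p0_i, p1_i]
point_to_segments <- function(x, p0, p1) {
  d <- p1 - p0
  len2 <- rowSums(d^2)
  ap <- sweep(p0, 2, x, FUN = function(a, b) b - a)  # x - p0
  t <- rowSums(ap * d) / pmax(len2, 1e-300)
  t <- pmin(1, pmax(0, t))
  proj <- p0 + d * t
  sqrt(rowSums(sweep(proj, 2, x)^2))
}

#' Grow one synthetic vascular tree by CCO
#'
#' Greedy constrained constructive optimization inside one perfusion
#' territory: terminals are added one at a time at candidate positions kept
#' a minimum distance from the existing tree; each new terminal is connected
#' at a bifurcation point, chosen among the `k_neighbors` nearest segments,
#' that minimizes the total intravascular volume (Nelder-Mead over the
#' bifurcation position). Terminal outflows are equal, so segment flows are
#' proportional to downstream leaf counts and radii follow
#' `r = r_root (Q/Q_root)^(1/gamma)`.
#'
#' @param territory_points candidate interior points (matrix n x 3), e.g.
#'   the territory's mesh nodes.
#' @param root_point 3D origin of the tree (the feeding outlet).
#' @param root_radius radius at the tree root \[cm\].
#' @param root_flow total flow entering the tree \[mL/s\] (split equally
#'   over terminals).
#' @param n_terminals number of terminals.
#' @param config a [cco_config()]; the growth RNG is
#'   `config$seed + rng_offset`.
#' @param territory_volume territory volume \[mL\] for the spacing rule.
#' @param rng_offset added to the seed (outlet index, for per-tree
#'   reproducibility).
#' @return a `vessel_tree` (ids 0-based, origin `"synthetic"`), with a
#'   growth log in `attr(, "growth_log")` (per insertion: optimized vs
#'   naive connection volume, spacing relaxations).
#' @export
grow_tree <- function(territory_points, root_point, root_radius, root_flow,
                      n_terminals, config = cco_config(),
                      territory_volume = NULL, rng_offset = 0L) {
  stopifnot(n_terminals >= 1L, nrow(territory_points) >= 1L)
  pts <- as.matrix(territory_points)
  if (is.null(territory_volume)) {
    territory_volume <- prod(apply(pts, 2, function(c) diff(range(c)) + 1e-6))
  }
  gamma <- config$murray_gamma
  set.seed(config$seed + rng_offset)

  # state arrays (grown incrementally)
  p0 <- matrix(root_point, 1, 3)
  first <- pts[sample.int(nrow(pts), 1L), ]
  p1 <- matrix(first, 1, 3)
  parent <- NA_integer_
  nleaf <- 1L
  log_rows <- list()

  seg_len <- function() sqrt(rowSums((p1 - p0)^2))

  path_to_root <- function(j) {
    path <- integer(0)
    while (!is.na(j)) { path <- c(path, j); j <- parent[j] }
    path
  }

  for (t_new in seq_len(n_terminals)[-1]) {
    # --- candidate terminal position with minimum spacing ---
    d_thresh <- config$d_thresh_coef * (territory_volume / t_new)^(1 / 3)
    relaxations <- 0L
    x_new <- NULL
    repeat {
      ok <- FALSE
      for (a in seq_len(config$candidate_attempts)) {
        cand <- pts[sample.int(nrow(pts), 1L), ]
        if (min(point_to_segments(cand, p0, p1)) >= d_thresh) {
          x_new <- cand; ok <- TRUE; break
        }
      }
      if (ok) break
      d_thresh <- d_thresh * 0.9
      relaxations <- relaxations + 1L
      if (relaxations > 200L) stop("territory too small to place terminals")
    }

    # --- connection search over the k nearest segments ---
    dists <- point_to_segments(x_new, p0, p1)
    cand_segs <- order(dists)[seq_len(min(config$k_neighbors, length(dists)))]
    m <- nrow(p0)
    lens <- seg_len()

    eval_conn <- function(j, xb) {
      # replacing segment j (pa -> pb) with pa -> xb -> {pb, x_new}
      l_par <- sqrt(sum((xb - p0[j, ])^2))
      l_ch1 <- sqrt(sum((p1[j, ] - xb)^2))
      l_ch2 <- sqrt(sum((x_new - xb)^2))
      if (min(l_par, l_ch1, l_ch2) < 1e-4) return(1e6)
      nl <- nleaf
      nl[path_to_root(j)] <- nl[path_to_root(j)] + 1L
      lengths <- c(lens[-j], l_par, l_ch1, l_ch2)
      nls <- c(nl[-j], nl[j], nleaf[j], 1L)
      cco_tree_volume(lengths, nls, t_new, root_radius, gamma)
    }

    best <- list(vol = Inf)
    for (j in cand_segs) {
      x0 <- (p0[j, ] + p1[j, ]) / 2
      opt <- stats::optim(x0, function(x) eval_conn(j, x),
                          method = "Nelder-Mead",
                          control = list(maxit = 120, reltol = 1e-6))
      if (opt$value < best$vol) {
        best <- list(vol = opt$value, j = j, xb = opt$par)
      }
    }
    if (best$vol >= 1e6) stop("no feasible connection found")
    j_near <- cand_segs[1]
    naive_vol <- eval_conn(j_near, (p0[j_near, ] + p1[j_near, ]) / 2)

    # --- apply the winning connection ---
    j <- best$j; xb <- best$xb
    pb <- p1[j, ]
    old_children <- which(!is.na(parent) & parent == j)
    p1[j, ] <- xb
    p0 <- rbind(p0, xb, xb)
    p1 <- rbind(p1, pb, x_new)
    id_ch1 <- m + 1L; id_ch2 <- m + 2L
    parent <- c(parent, j, j)
    parent[old_children] <- id_ch1
    nleaf <- c(nleaf, nleaf[j], 1L)
    nleaf[path_to_root(j)] <- nleaf[path_to_root(j)] + 1L

    log_rows[[t_new - 1L]] <- data.frame(
      insertion = t_new, volume_opt = best$vol, volume_naive = naive_vol,
      relaxations = relaxations)
  }

  n_seg <- nrow(p0)
  radius <- root_radius * (nleaf / n_terminals)^(1 / gamma)
  clamped <- radius < config$min_terminal_radius
  radius[clamped] <- config$min_terminal_radius
  # floor clamping must not invert the parent ordering: parents first
  depth <- vapply(seq_len(n_seg), function(i) length(path_to_root(i)), 0L)
  for (i in order(depth)) {
    if (!is.na(parent[i])) radius[i] <- min(radius[i], radius[parent[i]])
  }

  df <- data.frame(id = 0:(n_seg - 1L),
                   parent = ifelse(is.na(parent), NA_integer_, parent - 1L),
                   x0 = p0[, 1], y0 = p0[, 2], z0 = p0[, 3],
                   x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
                   radius = radius, origin = "synthetic",
                   perfuses_lv = TRUE)
  tree <- vessel_tree(df, root = 0L)
  attr(tree, "growth_log") <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(insertion = integer(), volume_opt = numeric(),
               volume_naive = numeric(), relaxations = integer())
  }
  attr(tree, "n_clamped") <- sum(clamped)
  tree
}

#' Propagate outlet radius-scaling factors through a tree
#'
#' Each outlet carries a scale factor; traversing from the outlets to the
#' root, every parent receives the maximum of its daughters' factors, and
#' each segment's new radius is capped by its (new) parent radius so the
#' morphometric ordering is preserved. Only synthetic-origin segments are
#' rescaled; image-based geometry is left untouched and acts as the cap for
#' synthetic roots.
#'
#' @param tree a `vessel_tree`.
#' @param outlet_scales named positive factors, one per (synthetic) outlet
#'   segment id; missing outlets default to 1.
#' @param parent_radius cap for the tree root's new radius (default: its
#'   image-based parent's radius if it has one, else no cap).
#' @return the rescaled `vessel_tree`, with the effective per-segment scale
#'   in `attr(, "applied_scale")`.
#' @export
apply_radius_scaling <- function(tree, outlet_scales, parent_radius = NULL) {
  if (any(outlet_scales <= 0)) stop("scale factors must be positive")
  seg <- tree$segments
  n <- nrow(seg)
  scale <- rep(NA_real_, n)
  leaf_rows <- match(tree$outlet_ids, seg$id)
  scale[leaf_rows] <- 1
  given <- intersect(names(outlet_scales), as.character(tree$outlet_ids))
  scale[match(as.integer(given), seg$id)] <- outlet_scales[given]

  ord <- topo_order(seg)
  parent_row <- match(seg$parent, seg$id)
  # upward pass: parent scale = max over daughters
  for (i in rev(ord)) {
    p <- parent_row[i]
    if (!is.na(p)) {
      scale[p] <- if (is.na(scale[p])) scale[i] else max(scale[p], scale[i])
    }
  }
  # downward pass: apply, capped by the (already updated) parent radius
  new_r <- seg$radius
  for (i in ord) {
    if (seg$origin[i] != "synthetic") { scale[i] <- 1; next }
    p <- parent_row[i]
    cap <- if (!is.na(p)) new_r[p]
           else if (!is.null(parent_radius)) parent_radius
           else Inf
    new_r[i] <- min(scale[i] * seg$radius[i], cap)
    scale[i] <- new_r[i] / seg$radius[i]
  }
  seg$radius <- new_r
  out <- vessel_tree(seg, root = tree$root, validate = FALSE)
  attr(out, "applied_scale") <- stats::setNames(scale, seg$id)
  out
}

#' Grow synthetic trees for every LV territory and graft them on
#'
#' Allocates terminals by territory volume, grows one independent tree per
#' LV-perfusing epicardial outlet (rooted at the outlet point, root radius
#' equal to the outlet radius), and grafts them onto the epicardial tree
#' with globally renumbered ids.
#'
#' @param epi_tree epicardial `vessel_tree`.
#' @param mesh `lv_mesh` supplying interior points.
#' @param map `territory_map` with `territory_volume`.
#' @param config a [cco_config()].
#' @return list: `combined` (one `vessel_tree`), `trees` (per-outlet list),
#'   `terminal_counts`, and `outlet_of_synthetic` (named map from synthetic
#'   outlet id in the combined tree to its epicardial feeding outlet).
#' @export
grow_synthetic_trees <- function(epi_tree, mesh, map, config = cco_config()) {
  counts <- allocate_terminals(map$territory_volume, config$total_terminals)
  ops <- outlet_points(epi_tree, lv_only = TRUE)
  seg <- epi_tree$segments
  trees <- list()
  for (i in seq_along(map$outlet_ids)) {
    oid <- map$outlet_ids[i]
    sel <- map$nodal_label == oid
    pts <- mesh$nodes[sel, , drop = FALSE]
    root_pt <- ops[as.character(oid), ]
    r_root <- seg$radius[match(oid, seg$id)]
    trees[[as.character(oid)]] <- grow_tree(
      pts, root_pt, r_root * 0.95, root_flow = 1,
      n_terminals = counts[[as.character(oid)]], config = config,
      territory_volume = map$territory_volume[[as.character(oid)]],
      rng_offset = i)
  }
  combined <- graft_trees(epi_tree, trees)
  list(combined = combined$tree, trees = trees,
       terminal_counts = counts,
       outlet_of_synthetic = combined$outlet_of_synthetic)
}

# renumber synthetic trees and graft each onto its epicardial outlet
graft_trees <- function(epi_tree, trees) {
  seg_all <- epi_tree$segments
  seg_all$length <- NULL
  next_id <- max(seg_all$id) + 1L
  outlet_of_synthetic <- character(0)
  for (oid in names(trees)) {
    st <- trees[[oid]]$segments
    st$length <- NULL
    offset <- next_id
    st$id <- st$id + offset
    st$parent <- ifelse(is.na(st$parent), as.integer(oid), st$parent + offset)
    leaves <- tree_leaves(trees[[oid]]) + offset
    outlet_of_synthetic[as.character(leaves)] <- oid
    seg_all <- rbind(seg_all, st)
    next_id <- max(st$id) + 1L
  }
  list(tree = vessel_tree(seg_all, root = epi_tree$root),
       outlet_of_synthetic = outlet_of_synthetic)
}
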