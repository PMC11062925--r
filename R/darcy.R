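#' Conductance parameterization of the perfusion model
#'
#' The source and sink conductances of the single-compartment Darcy model
#' are set so that, at the target capillary pressure, the tissue takes up
#' exactly the total LV flow:
#' `beta_src = Q_LV / (V_LV (p_src_bar - p_cap))` and
#' `beta_snk = Q_LV / (V_LV (p_cap - p_snk))`.
#'
#' @param q_lv total LV perfusion \[mL/s\].
#' @param v_lv LV myocardial volume \[mL\].
#' @param p_src_bar spatial mean of the pressure-source field \[mmHg\].
#' @param p_cap target capillary pressure \[mmHg\] (default 15).
#' @param p_snk venous sink pressure \[mmHg\] (default 0).
#' @return list `beta_src`, `beta_snk` in CGS \[(dyn/cm2)^-1 s^-1\].
#' @export
make_betas <- function(q_lv, v_lv, p_src_bar, p_cap = 15, p_snk = 0) {
  if (!(p_src_bar > p_cap && p_cap > p_snk)) {
    stop("require p_src_bar > p_cap > p_snk")
  }
  stopifnot(q_lv > 0, v_lv > 0)
  list(beta_src = q_lv / (v_lv * mmHg_to_cgs(p_src_bar - p_cap)),
       beta_snk = q_lv / (v_lv * mmHg_to_cgs(p_cap - p_snk)))
}

#' Piecewise-constant nodal pressure-source field
#'
#' Spreads per-outlet microvascular source pressures over the mesh by
#' territory label.
#'
#' @param map a `territory_map`.
#' @param p_src_outlet named vector \[mmHg\], one entry per outlet id.
#' @return nodal p_src vector \[mmHg\].
#' @export
build_source_field <- function(map, p_src_outlet) {
  key <- as.character(map$outlet_ids)
  if (!all(key %in% names(p_src_outlet))) {
    stop("p_src_outlet must cover every territory outlet")
  }
  as.numeric(p_src_outlet[as.character(map$nodal_label)])
}

# linear-tet FEM matrices: stiffness (unit permeability) and consistent mass
fem_matrices <- function(mesh) {
  nt <- nrow(mesh$tets)
  nn <- nrow(mesh$nodes)
  ii <- integer(16 * nt); jj <- integer(16 * nt)
  kk <- numeric(16 * nt); mm <- numeric(16 * nt)
  pos <- 1L
  lm <- matrix(1, 4, 4) + diag(4)   # consistent tet mass pattern, V/20 scale
  for (e in seq_len(nt)) {
    vid <- mesh$tets[e, ]
    X <- mesh$nodes[vid, ]
    Em <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
    vol <- det(Em) / 6
    Gi <- solve(Em)                  # columns: gradients of phi_2..4
    G <- cbind(-rowSums(Gi), Gi)     # 3 x 4, gradient of each basis fn
    Ke <- vol * crossprod(G)
    Me <- vol / 20 * lm
    idx <- pos:(pos + 15L)
    ii[idx] <- rep(vid, each = 4)
    jj[idx] <- rep(vid, times = 4)
    kk[idx] <- as.numeric(Ke)
    mm[idx] <- as.numeric(Me)
    pos <- pos + 16L
  }
  list(K = Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(nn, nn)),
       M = Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(nn, nn)))
}

#' Solve the single-compartment Darcy perfusion problem
#'
#' Linear-tet FEM solution of
#' `-div(k grad p) + (beta_src + beta_snk) p = beta_src p_src +
#' beta_snk p_snk` with natural zero-flux boundaries on the whole LV
#' surface. The steady problem is linear, so one sparse SPD solve suffices.
#'
#' @param mesh an `lv_mesh`.
#' @param p_src nodal source-pressure field \[mmHg\] (e.g. from
#'   [build_source_field()]).
#' @param betas list from [make_betas()] (CGS conductances).
#' @param k permeability \[cm2 Pa^-1 s^-1\] (default 2e-5).
#' @param p_snk sink pressure \[mmHg\] (default 0).
#' @param forcing optional nodal volumetric forcing \[s^-1\] added to the
#'   right-hand side through the mass matrix (used for manufactured
#'   solutions).
#' @return object of class `darcy_solution`: nodal `p` \[mmHg\], the CGS
#'   pieces, and the relative residual of the linear solve.
#' @export
solve_darcy <- function(mesh, p_src, betas, k = 2e-5, p_snk = 0,
                        forcing = NULL) {
  nn <- nrow(mesh$nodes)
  if (length(p_src) != nn) stop("p_src must be nodal")
  if (k <= 0) stop("permeability must be positive")
  k_cgs <- k / PA_DYNCM2
  bs <- betas$beta_src; bk <- betas$beta_snk
  if (bs <= 0 || bk <= 0) stop("betas must be positive")
  fem <- fem_matrices(mesh)
  A <- k_cgs * fem$K + (bs + bk) * fem$M
  rhs_nodal <- bs * mmHg_to_cgs(p_src) + bk * mmHg_to_cgs(p_snk)
  if (!is.null(forcing)) rhs_nodal <- rhs_nodal + forcing
  b <- fem$M %*% rhs_nodal
  p_cgs <- as.numeric(Matrix::solve(A, b))
  # normwise backward error (stays meaningful for extreme permeabilities)
  rel_res <- as.numeric(Matrix::norm(A %*% p_cgs - b, "F")) /
    (as.numeric(Matrix::norm(A, "F")) * sqrt(sum(p_cgs^2)) +
       as.numeric(Matrix::norm(b, "F")) + .Machine$double.xmin)
  if (rel_res > 1e-10) {
    warning("Darcy solve residual above tolerance: ", format(rel_res))
  }
  structure(list(p = cgs_to_mmHg(p_cgs), p_cgs = p_cgs,
                 p_src = p_src, p_snk = p_snk,
                 beta_src = bs, beta_snk = bk, k = k,
                 residual = rel_res, mesh = mesh),
            class = "darcy_solution")
}

#' @export
print.darcy_solution <- function(x, ...) {
  cat(sprintf("darcy_solution: p in [%.2f, %.2f] mmHg, residual %.2e\n",
              min(x$p), max(x$p), x$residual))
  invisible(x)
}

#' Myocardial blood flow from a Darcy solution
#'
#' The perfusion density is `beta_src (p_src - p)` \[s^-1 = mL/s per mL\];
#' integrating it over node-centered control volumes gives absolute
#' territory flows. Nodal integration is exact for the linear interpolants
#' used by the FEM.
#'
#' @param sol a `darcy_solution`.
#' @param map optional `territory_map` for per-territory totals.
#' @return list: `nodal_density` \[mL/s/mL\], `nodal_mbf`
#'   \[mL/min/100 mL\], `total` \[mL/s\], and (with `map`)
#'   `territory_flow` \[mL/s\].
#' @export
compute_mbf <- function(sol, map = NULL) {
  dens <- sol$beta_src * mmHg_to_cgs(sol$p_src - sol$p)
  cv <- node_control_volumes(sol$mesh)
  out <- list(nodal_density = dens,
              nodal_mbf = dens * 60 * 100,
              total = sum(dens * cv))
  if (!is.null(map)) {
    fl <- tapply(dens * cv, factor(map$nodal_label, levels = map$outlet_ids),
                 sum, default = 0)
    out$territory_flow <- stats::setNames(as.numeric(fl), map$outlet_ids)
  }
  out
}

#' Global source-sink balance of a Darcy solution
#'
#' With zero-flux boundaries the inflow `int beta_src (p_src - p)` must
#' equal the outflow `int beta_snk (p - p_snk)`; returns both and their
#' relative imbalance.
#'
#' @param sol a `darcy_solution`.
#' @return list `inflow`, `outflow` \[mL/s\], `imbalance` (relative).
#' @export
darcy_balance <- function(sol) {
  cv <- node_control_volumes(sol$mesh)
  inflow <- sum(sol$beta_src * mmHg_to_cgs(sol$p_src - sol$p) * cv)
  outflow <- sum(sol$beta_snk * mmHg_to_cgs(sol$p - sol$p_snk) * cv)
  list(inflow = inflow, outflow = outflow,
       imbalance = abs(inflow - outflow) / max(abs(inflow), 1e-300))
}

#' Structured tetrahedral unit-cube mesh
#'
#' `n x n x n` hexahedral cells each split into six conforming tets;
#' used for convergence studies and manufactured-solution tests.
#'
#' @param n cells per edge.
#' @param scale edge length \[cm\].
#' @return an `lv_mesh`.
#' @export
unit_cube_mesh <- function(n = 4, scale = 1) {
  g <- seq(0, scale, length.out = n + 1)
  idx <- function(i, j, k) i + (n + 1) * (j + (n + 1) * k) + 1L
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  tet_local <- matrix(c(1, 2, 3, 7,
                        1, 3, 4, 7,
                        1, 4, 8, 7,
                        1, 8, 5, 7,
                        1, 5, 6, 7,
                        1, 6, 2, 7), ncol = 4, byrow = TRUE)
  tets <- matrix(0L, 6L * n^3, 4)
  row <- 0L
  for (k in 0:(n - 1)) for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
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
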