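#' Tetrahedral left-ventricle mesh
#'
#' Container for a tetrahedral LV volume mesh with an optional nodal
#' myocardial blood flow (MBF) field in clinical units
#' \[mL/min per 100 mL tissue\]. Node coordinates are in cm; tetrahedra are
#' stored 1-based and must be positively oriented.
#'
#' @param nodes numeric matrix, n x 3, node coordinates \[cm\].
#' @param tets integer matrix, m x 4, 1-based node indices per tetrahedron.
#' @param nodal_mbf optional numeric vector of length n, non-negative.
#' @param validate check orientation and field lengths (default TRUE).
#' @return an object of class `lv_mesh`.
#' @export
lv_mesh <- function(nodes, tets, nodal_mbf = NULL, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(tets) != 4L) stop("tets must be an m x 4 matrix")
  if (any(tets < 1L) || any(tets > nrow(nodes))) {
    stop("tet connectivity references nodes outside 1..n")
  }
  mesh <- structure(list(nodes = nodes, tets = tets, nodal_mbf = nodal_mbf),
                    class = "lv_mesh")
  if (validate) {
    vols <- tet_volumes(mesh)
    if (any(vols <= 0)) {
      stop(sum(vols <= 0), " tetrahedra are degenerate or negatively oriented")
    }
    if (!is.null(nodal_mbf)) {
      if (length(nodal_mbf) != nrow(nodes)) {
        stop("nodal_mbf length must equal the node count")
      }
      if (any(nodal_mbf < 0)) stop("nodal_mbf must be non-negative")
    }
  }
  mesh
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat("lv_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets,",
      "volume", format(mesh_volume(x), digits = 6), "mL",
      if (!is.null(x$nodal_mbf)) "(with MBF field)" else "", "\n")
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param mesh an `lv_mesh`.
#' @return numeric vector of per-tet volumes \[mL\] (signed; positive for a
#'   correctly oriented mesh).
#' @export
tet_volumes <- function(mesh) {
  p1 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  a <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - p1
  c_ <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - p1
  # scalar triple product a . (b x c) / 6, vectorized over tets
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
   a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Total mesh volume
#' @param mesh an `lv_mesh`.
#' @return total volume \[mL\].
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

#' Node-centered control volumes
#'
#' Each tet's volume is attributed in equal quarters to its four vertices,
#' giving an exactly conservative nodal partition of the total volume.
#'
#' @param mesh an `lv_mesh`.
#' @return numeric vector of per-node control volumes \[mL\].
#' @export
node_control_volumes <- function(mesh) {
  v4 <- tet_volumes(mesh) / 4
  cv <- numeric(nrow(mesh$nodes))
  for (k in 1:4) {
    tab <- tapply(v4, mesh$tets[, k], sum)
    idx <- as.integer(names(tab))
    cv[idx] <- cv[idx] + as.numeric(tab)
  }
  cv
}

vtk_stop <- function(lineno, msg) {
  stop(sprintf("VTK parse error at line %d: %s", lineno, msg), call. = FALSE)
}

#' Read a tetrahedral mesh from VTK legacy ASCII
#'
#' Reads a `DATASET UNSTRUCTURED_GRID` file containing only tetrahedra
#' (cell type 10). An optional `POINT_DATA` scalar named `MBF` populates
#' `nodal_mbf`; any other nodal scalar fields are returned in `$fields`.
#'
#' @param path file path.
#' @return an `lv_mesh`; additional nodal scalars, if present, in the
#'   `fields` element (named list).
#' @export
read_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  skip_blank <- function(i) {
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
    i
  }
  toks_of <- function(i) strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]

  i <- skip_blank(i)
  if (i > length(lines) || !startsWith(lines[i], "# vtk DataFile")) {
    vtk_stop(i, "missing '# vtk DataFile' header")
  }
  i <- i + 2L  # header comment + title
  i <- skip_blank(i)
  if (toupper(trimws(lines[i])) != "ASCII") vtk_stop(i, "expected ASCII format")
  i <- skip_blank(i + 1L)
  if (!grepl("UNSTRUCTURED_GRID", lines[i])) {
    vtk_stop(i, "expected DATASET UNSTRUCTURED_GRID")
  }
  i <- skip_blank(i + 1L)

  toks <- toks_of(i)
  if (toks[1] != "POINTS") vtk_stop(i, "expected POINTS")
  n_pts <- as.integer(toks[2])
  # numbers may be wrapped arbitrarily across lines
  read_numbers <- function(i, count, what) {
    vals <- numeric(0)
    while (length(vals) < count) {
      i <- skip_blank(i)
      if (i > length(lines)) vtk_stop(i, paste("unexpected EOF in", what))
      v <- suppressWarnings(as.numeric(toks_of(i)))
      if (anyNA(v)) vtk_stop(i, paste("non-numeric token in", what))
      vals <- c(vals, v)
      i <- i + 1L
    }
    if (length(vals) != count) vtk_stop(i - 1L, paste("ragged", what, "block"))
    list(values = vals, i = i)
  }
  pts <- read_numbers(i + 1L, 3L * n_pts, "POINTS")
  nodes <- matrix(pts$values, ncol = 3, byrow = TRUE)
  i <- skip_blank(pts$i)

  toks <- toks_of(i)
  if (toks[1] != "CELLS") vtk_stop(i, "expected CELLS")
  n_cells <- as.integer(toks[2])
  total <- as.integer(toks[3])
  cl <- read_numbers(i + 1L, total, "CELLS")
  i <- skip_blank(cl$i)
  if (total != 5L * n_cells) {
    vtk_stop(i, "only tetrahedral cells (4 nodes each) are supported")
  }
  cells <- matrix(cl$values, ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4)) {
    vtk_stop(i, "non-tetrahedral cell encountered (node count != 4)")
  }
  tets <- cells[, 2:5, drop = FALSE] + 1L

  toks <- toks_of(i)
  if (toks[1] != "CELL_TYPES") vtk_stop(i, "expected CELL_TYPES")
  ct <- read_numbers(i + 1L, n_cells, "CELL_TYPES")
  if (any(ct$values != 10)) {
    vtk_stop(i, "unsupported cell type (only VTK_TETRA, type 10)")
  }
  i <- skip_blank(ct$i)

  fields <- list()
  if (i <= length(lines)) {
    toks <- toks_of(i)
    if (toks[1] == "POINT_DATA") {
      n_pd <- as.integer(toks[2])
      if (n_pd != n_pts) vtk_stop(i, "POINT_DATA count mismatch")
      i <- skip_blank(i + 1L)
      while (i <= length(lines)) {
        toks <- toks_of(i)
        if (toks[1] != "SCALARS") break
        fname <- toks[2]
        i <- skip_blank(i + 1L)
        if (toks_of(i)[1] != "LOOKUP_TABLE") {
          vtk_stop(i, "expected LOOKUP_TABLE after SCALARS")
        }
        fv <- read_numbers(i + 1L, n_pts, paste("SCALARS", fname))
        fields[[fname]] <- fv$values
        i <- skip_blank(fv$i)
      }
    }
  }

  nodal_mbf <- fields[["MBF"]]
  fields[["MBF"]] <- NULL
  mesh <- lv_mesh(nodes, tets, nodal_mbf = nodal_mbf)
  if (length(fields)) mesh$fields <- fields
  mesh
}

#' Write a tetrahedral mesh to VTK legacy ASCII
#'
#' The mesh MBF field (if present) is written as a nodal scalar named `MBF`;
#' additional nodal scalar fields can be supplied through `fields`.
#'
#' @param mesh an `lv_mesh`.
#' @param path output file path.
#' @param fields named list of numeric nodal vectors to write as
#'   `POINT_DATA` scalars.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, fields = list()) {
  n <- nrow(mesh$nodes)
  if (!is.null(mesh$nodal_mbf)) {
    fields <- c(list(MBF = mesh$nodal_mbf), fields)
  }
  for (fname in names(fields)) {
    if (length(fields[[fname]]) != n) {
      stop("field '", fname, "' length does not match node count")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "myoperf LV mesh",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  }), con)
  m <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(apply(mesh$tets - 1L, 1, function(r) {
    paste(c(4L, r), collapse = " ")
  }), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (fname in names(fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", fname),
                   "LOOKUP_TABLE default",
                   formatC(fields[[fname]], format = "g", digits = 17)), con)
    }
  }
  invisible(path)
}
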