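#' Vessel tree geometry
#'
#' A directed branching tree of cylindrical vessel segments. Each segment has
#' a proximal endpoint `p0` and distal endpoint `p1` \[cm\], a single radius
#' \[cm\], an origin tag (`image_based` or `synthetic`) and a flag marking
#' whether its subtree perfuses the left ventricle. Segment ids are 0-based
#' integer labels; the parent of the root is `NA`.
#'
#' @param segments data.frame with columns `id`, `parent`, `x0`,`y0`,`z0`,
#'   `x1`,`y1`,`z1`, `radius`, `origin`, `perfuses_lv`.
#' @param root id of the root segment.
#' @param validate run structural validation (default TRUE).
#' @return an object of class `vessel_tree` with derived `length` column and
#'   `outlet_ids` (leaf segments, ordered by id).
#' @export
vessel_tree <- function(segments, root, validate = TRUE) {
  req <- c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1",
           "radius", "origin", "perfuses_lv")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols)) {
    stop("segments is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  segments <- as.data.frame(segments)[req]
  segments$id <- as.integer(segments$id)
  segments$parent <- as.integer(segments$parent)
  segments$length <- sqrt((segments$x1 - segments$x0)^2 +
                          (segments$y1 - segments$y0)^2 +
                          (segments$z1 - segments$z0)^2)
  tree <- structure(list(segments = segments, root = as.integer(root)),
                    class = "vessel_tree")
  tree$outlet_ids <- tree_leaves(tree)
  if (validate) validate_tree(tree)
  tree
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat("vessel_tree:", nrow(x$segments), "segments,",
      length(x$outlet_ids), "outlets,",
      sum(x$segments$perfuses_lv[match(x$outlet_ids, x$segments$id)]),
      "perfusing the LV\n")
  invisible(x)
}

#' Validate vessel tree structure
#'
#' Checks id uniqueness, parent references, connectivity from the root,
#' acyclicity, positive radii/lengths, and bifurcating internal nodes in
#' synthetic portions.
#'
#' @param tree a `vessel_tree`.
#' @return invisibly TRUE; stops with a structure error otherwise.
#' @export
validate_tree <- function(tree) {
  seg <- tree$segments
  if (anyDuplicated(seg$id)) stop("duplicate segment ids")
  if (!tree$root %in% seg$id) stop("root id not among segments")
  if (!is.na(seg$parent[match(tree$root, seg$id)])) {
    stop("root segment must have parent NA")
  }
  non_root <- seg$id != tree$root
  if (any(is.na(seg$parent[non_root]))) {
    stop("non-root segment with missing parent (multiple roots?)")
  }
  if (!all(seg$parent[non_root] %in% seg$id)) {
    stop("segment references a missing parent")
  }
  # connectivity/acyclicity: BFS from root must reach every segment exactly once
  kids <- tree_children(tree)
  seen <- character(0)
  frontier <- tree$root
  while (length(frontier)) {
    key <- as.character(frontier)
    if (any(key %in% seen)) stop("cycle detected in tree")
    seen <- c(seen, key)
    frontier <- unlist(kids[key], use.names = FALSE)
  }
  if (length(seen) != nrow(seg)) {
    stop("orphan segments not reachable from the root")
  }
  if (any(seg$radius <= 0)) stop("all radii must be positive")
  if (any(seg$length <= 0)) stop("all segment lengths must be positive")
  n_kids <- lengths(kids)[as.character(seg$id)]
  n_kids[is.na(n_kids)] <- 0L
  bad <- seg$origin == "synthetic" & n_kids == 1L
  if (any(bad)) {
    stop("synthetic internal segments must bifurcate (exactly 2 children)")
  }
  invisible(TRUE)
}

#' Children of every segment
#' @param tree a `vessel_tree`.
#' @return named list: for each segment id (as character), integer vector of
#'   child ids.
#' @export
tree_children <- function(tree) {
  seg <- tree$segments
  non_root <- !is.na(seg$parent)
  split(seg$id[non_root], factor(seg$parent[non_root], levels = seg$id))
}

#' Leaf (outlet) segment ids
#' @param tree a `vessel_tree`.
#' @return sorted integer vector of leaf ids.
#' @export
tree_leaves <- function(tree) {
  seg <- tree$segments
  sort(setdiff(seg$id, seg$parent[!is.na(seg$parent)]))
}

#' Root-to-segment path
#' @param tree a `vessel_tree`.
#' @param id target segment id.
#' @return integer vector of segment ids from the root down to `id`.
#' @export
tree_path <- function(tree, id) {
  seg <- tree$segments
  path <- integer(0)
  cur <- id
  repeat {
    if (!cur %in% seg$id) stop("segment ", cur, " not in tree")
    path <- c(cur, path)
    p <- seg$parent[match(cur, seg$id)]
    if (is.na(p)) break
    cur <- p
  }
  if (path[1] != tree$root) stop("path does not reach the root")
  path
}

#' Distal endpoints of outlet segments
#' @param tree a `vessel_tree`.
#' @param lv_only restrict to outlets flagged `perfuses_lv`.
#' @return matrix with rownames = outlet ids, columns x, y, z.
#' @export
outlet_points <- function(tree, lv_only = TRUE) {
  seg <- tree$segments
  ids <- tree$outlet_ids
  if (lv_only) ids <- ids[seg$perfuses_lv[match(ids, seg$id)]]
  m <- as.matrix(seg[match(ids, seg$id), c("x1", "y1", "z1")])
  rownames(m) <- ids
  colnames(m) <- c("x", "y", "z")
  m
}

#' Read a vessel tree from JSON
#'
#' Schema: `{"root": id, "segments": [{"id", "parent", "p0": [x,y,z],
#' "p1": [x,y,z], "radius", "origin", "perfuses_lv"}, ...]}` with a `null`
#' parent at the root.
#'
#' @param path file path.
#' @return a validated `vessel_tree`.
#' @export
read_tree <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$segments) || is.null(doc$root)) {
    stop("tree JSON must contain 'segments' and 'root'")
  }
  rows <- lapply(doc$segments, function(s) {
    data.frame(id = s$id,
               parent = if (is.null(s$parent)) NA_integer_ else s$parent,
               x0 = s$p0[[1]], y0 = s$p0[[2]], z0 = s$p0[[3]],
               x1 = s$p1[[1]], y1 = s$p1[[2]], z1 = s$p1[[3]],
               radius = s$radius,
               origin = s$origin,
               perfuses_lv = isTRUE(s$perfuses_lv))
  })
  vessel_tree(do.call(rbind, rows), root = doc$root)
}

#' Write a vessel tree to JSON
#' @param tree a `vessel_tree`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_tree <- function(tree, path) {
  seg <- tree$segments
  segs <- lapply(seq_len(nrow(seg)), function(i) {
    list(id = seg$id[i],
         parent = if (is.na(seg$parent[i])) NULL else seg$parent[i],
         p0 = c(seg$x0[i], seg$y0[i], seg$z0[i]),
         p1 = c(seg$x1[i], seg$y1[i], seg$z1[i]),
         radius = seg$radius[i],
         origin = seg$origin[i],
         perfuses_lv = seg$perfuses_lv[i])
  })
  jsonlite::write_json(list(root = tree$root, segments = segs), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
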