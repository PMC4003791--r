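# Tetrahedral meshes of the cylindrical imaging domain.
#
# Meshes are generated by structured extrusion: a ring-based triangulation of
# the disk cross-section is extruded along z into triangular prisms, and each
# prism is split into three tetrahedra with face diagonals chosen by the
# minimum-global-index rule so that neighbouring prisms agree on the shared
# quadrilateral faces (the classical conforming prism subdivision).

#' Construct a tetrahedral mesh object
#'
#' Builds a `tet_mesh` from node coordinates and tetrahedral connectivity.
#' Elements are reoriented so that every signed volume is positive, boundary
#' faces are extracted, and the mesh is validated (see
#' [validate_tet_mesh()]).
#'
#' @param nodes numeric matrix, one row per node, columns x, y, z in mm.
#' @param elements integer matrix, one row per tetrahedron, four 1-based node
#'   indices per row.
#' @param validate logical; run the full topology/geometry validation.
#' @return An object of class `tet_mesh` with fields `nodes`, `elements`,
#'   `boundary_faces` (outward-oriented triangles), `n_nodes`, `n_elements`,
#'   and an internal geometry cache.
#' @export
tet_mesh <- function(nodes, elements, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L) stop("invalid-argument: nodes must be an n x 3 matrix")
  if (ncol(elements) != 4L) stop("invalid-argument: elements must be an m x 4 matrix")
  if (min(elements) < 1L || max(elements) > nrow(nodes)) {
    stop("invalid-argument: element node index out of range")
  }
  # canonical orientation: positive signed volume
  sv <- signed_tet_volumes(nodes, elements)
  flip <- sv < 0
  if (any(flip)) {
    tmp <- elements[flip, 3L]
    elements[flip, 3L] <- elements[flip, 4L]
    elements[flip, 4L] <- tmp
  }
  mesh <- structure(
    list(
      nodes = nodes,
      elements = elements,
      boundary_faces = NULL,
      n_nodes = nrow(nodes),
      n_elements = nrow(elements),
      cache = new.env(parent = emptyenv())
    ),
    class = "tet_mesh"
  )
  mesh$boundary_faces <- extract_boundary_faces(mesh)
  if (validate) validate_tet_mesh(mesh)
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  bb <- apply(x$nodes, 2, range)
  cat(sprintf(
    "tet_mesh: %d nodes, %d tetrahedra, %d boundary faces\n",
    x$n_nodes, x$n_elements, nrow(x$boundary_faces)
  ))
  cat(sprintf(
    "  bounding box [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
    bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]
  ))
  cat(sprintf("  total volume %.2f mm^3\n", sum(tet_volumes(x))))
  invisible(x)
}

# signed volumes (det/6) for all elements; vectorised
signed_tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1L], , drop = FALSE]
  r1 <- nodes[elements[, 2L], , drop = FALSE] - a
  r2 <- nodes[elements[, 3L], , drop = FALSE] - a
  r3 <- nodes[elements[, 4L], , drop = FALSE] - a
  det3_rows(r1, r2, r3) / 6
}

det3_rows <- function(r1, r2, r3) {
  r1[, 1] * (r2[, 2] * r3[, 3] - r2[, 3] * r3[, 2]) -
    r1[, 2] * (r2[, 1] * r3[, 3] - r2[, 3] * r3[, 1]) +
    r1[, 3] * (r2[, 1] * r3[, 2] - r2[, 2] * r3[, 1])
}

cross_rows <- function(u, v) {
  cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
}

#' Volume of a single tetrahedron
#'
#' `|det(p2 - p1, p3 - p1, p4 - p1)| / 6`.  Returns 0 for coplanar points;
#' callers treat a (near-)zero volume as a degenerate element.
#'
#' @param tet_coords 4 x 3 numeric matrix of vertex coordinates in mm.
#' @return Volume in mm^3 (non-negative scalar).
#' @export
element_volume <- function(tet_coords) {
  tet_coords <- as.matrix(tet_coords)
  if (!all(dim(tet_coords) == c(4L, 3L))) {
    stop("invalid-argument: tet_coords must be 4 x 3")
  }
  if (nrow(unique(tet_coords)) < 4L) stop("invalid-argument: vertices must be distinct")
  e <- sweep(tet_coords[2:4, , drop = FALSE], 2, tet_coords[1, ])
  abs(det(e)) / 6
}

#' Volumes of all elements of a mesh
#'
#' @param mesh a `tet_mesh`.
#' @return Numeric vector of element volumes in mm^3.
#' @export
tet_volumes <- function(mesh) {
  abs(signed_tet_volumes(mesh$nodes, mesh$elements))
}

#' Element centroids
#'
#' @param mesh a `tet_mesh`.
#' @return n_elements x 3 matrix of centroid coordinates in mm.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1L], , drop = FALSE] +
    mesh$nodes[mesh$elements[, 2L], , drop = FALSE] +
    mesh$nodes[mesh$elements[, 3L], , drop = FALSE] +
    mesh$nodes[mesh$elements[, 4L], , drop = FALSE]) / 4
}

# ---- face bookkeeping -------------------------------------------------------

# the four faces of each tet, as a (4 * n_el) x 3 index matrix; face k of
# element e is row (e - 1) * 4 + k; local faces are opposite local node k
all_tet_faces <- function(elements) {
  n <- nrow(elements)
  f <- matrix(0L, 4L * n, 3L)
  loc <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  for (k in 1:4) {
    f[seq.int(k, by = 4L, length.out = n), ] <- elements[, loc[k, ], drop = FALSE]
  }
  f
}

face_keys <- function(faces) {
  lo <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  hi <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  mid <- faces[, 1L] + faces[, 2L] + faces[, 3L] - lo - hi
  paste(lo, mid, hi, sep = "_")
}

#' Extract outward-oriented boundary faces
#'
#' A face is on the boundary when it belongs to exactly one tetrahedron.
#' Faces are oriented so that their normal points away from the opposite
#' vertex of the owning tetrahedron, i.e. outward.
#'
#' @param mesh a `tet_mesh` (its stored `boundary_faces` is ignored; the
#'   extraction is recomputed from the connectivity).
#' @return Integer matrix with one oriented face (3 node indices) per row.
#' @export
extract_boundary_faces <- function(mesh) {
  elements <- mesh$elements
  nodes <- mesh$nodes
  faces <- all_tet_faces(elements)
  keys <- face_keys(faces)
  cnt <- table(keys)
  if (any(cnt > 2L)) stop("topology-error: face shared by more than two tetrahedra")
  bd <- faces[cnt[keys] == 1L, , drop = FALSE]
  if (nrow(bd) == 0L) stop("topology-error: mesh has no boundary")
  # orient: local face tables above are already outward for positively
  # oriented tets; verify and fix against the owning-tet opposite vertex
  own <- rep(seq_len(nrow(elements)), each = 4L)[cnt[keys] == 1L]
  opp_loc <- rep(1:4, nrow(elements))[cnt[keys] == 1L]
  opp <- elements[cbind(own, opp_loc)]
  v1 <- nodes[bd[, 2L], , drop = FALSE] - nodes[bd[, 1L], , drop = FALSE]
  v2 <- nodes[bd[, 3L], , drop = FALSE] - nodes[bd[, 1L], , drop = FALSE]
  nrm <- cross_rows(v1, v2)
  cf <- (nodes[bd[, 1L], , drop = FALSE] + nodes[bd[, 2L], , drop = FALSE] +
    nodes[bd[, 3L], , drop = FALSE]) / 3
  outwardness <- rowSums(nrm * (cf - nodes[opp, , drop = FALSE]))
  swap <- outwardness < 0
  if (any(swap)) {
    tmp <- bd[swap, 2L]
    bd[swap, 2L] <- bd[swap, 3L]
    bd[swap, 3L] <- tmp
  }
  bd
}

#' Validate a tetrahedral mesh
#'
#' Checks index ranges, strictly positive element volumes (degenerate
#' elements below 1e-12 mm^3 are rejected), interior faces shared by exactly
#' two tetrahedra, and that the boundary faces form a closed surface (every
#' boundary edge shared by exactly two boundary faces).
#'
#' @param mesh a `tet_mesh`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_tet_mesh <- function(mesh) {
  v <- tet_volumes(mesh)
  if (any(v < 1e-12)) {
    stop(sprintf(
      "degenerate-element: %d tetrahedra with volume below 1e-12 mm^3 (first: element %d)",
      sum(v < 1e-12), which(v < 1e-12)[1]
    ))
  }
  keys <- face_keys(all_tet_faces(mesh$elements))
  cnt <- table(keys)
  if (any(cnt > 2L)) stop("topology-error: a face is shared by more than two tetrahedra")
  bd <- mesh$boundary_faces
  if (is.null(bd)) bd <- extract_boundary_faces(mesh)
  # closed-surface check on boundary edges
  ed <- rbind(bd[, c(1L, 2L)], bd[, c(2L, 3L)], bd[, c(3L, 1L)])
  ek <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]), sep = "_")
  ecnt <- table(ek)
  if (any(ecnt != 2L)) {
    stop("topology-error: boundary surface is not closed (edge not shared by two faces)")
  }
  invisible(TRUE)
}

# ---- disk triangulation and prism extrusion ---------------------------------

# ring-based disk triangulation: ring i (i = 1..nr) carries 6*i nodes at
# radius i * radius / nr; annuli are stitched by an angular two-pointer sweep
disk_triangulation <- function(radius, nr) {
  pts <- matrix(c(0, 0), 1L, 2L)
  ring_idx <- vector("list", nr + 1L)
  ring_ang <- vector("list", nr + 1L)
  ring_idx[[1L]] <- 1L
  ring_ang[[1L]] <- 0
  for (i in seq_len(nr)) {
    n_i <- 6L * i
    ang <- 2 * pi * (seq_len(n_i) - 1L) / n_i
    ring_idx[[i + 1L]] <- nrow(pts) + seq_len(n_i)
    ring_ang[[i + 1L]] <- ang
    pts <- rbind(pts, (radius * i / nr) * cbind(cos(ang), sin(ang)))
  }
  tris <- NULL
  # centre fan
  out1 <- ring_idx[[2L]]
  tris <- cbind(1L, out1, c(out1[-1L], out1[1L]))
  if (nr >= 2L) {
    for (i in 2:nr) {
      tris <- rbind(tris, stitch_rings(
        ring_idx[[i]], ring_ang[[i]],
        ring_idx[[i + 1L]], ring_ang[[i + 1L]]
      ))
    }
  }
  list(points = pts, triangles = tris)
}

# triangulate the annulus between an inner and an outer ring of nodes by
# advancing whichever ring has the smaller next angle (wrap-aware)
stitch_rings <- function(inner_idx, inner_ang, outer_idx, outer_ang) {
  n1 <- length(inner_idx)
  n2 <- length(outer_idx)
  ai <- c(inner_ang, inner_ang[1L] + 2 * pi)
  ao <- c(outer_ang, outer_ang[1L] + 2 * pi)
  tris <- matrix(0L, n1 + n2, 3L)
  i <- 0L
  j <- 0L
  t <- 0L
  while (i < n1 || j < n2) {
    t <- t + 1L
    cur_i <- inner_idx[(i %% n1) + 1L]
    cur_o <- outer_idx[(j %% n2) + 1L]
    adv_outer <- j < n2 && (i >= n1 || ao[j + 2L] <= ai[i + 2L])
    if (adv_outer) {
      nxt_o <- outer_idx[((j + 1L) %% n2) + 1L]
      tris[t, ] <- c(cur_i, cur_o, nxt_o)
      j <- j + 1L
    } else {
      nxt_i <- inner_idx[((i + 1L) %% n1) + 1L]
      tris[t, ] <- c(cur_i, nxt_i, cur_o)
      i <- i + 1L
    }
  }
  tris
}

# split every prism (bottom v1 v2 v3, top v4 v5 v6, vertical pairs 1-4, 2-5,
# 3-6) into three tetrahedra; quad-face diagonals pass through the
# minimum-global-index vertex of the face, which neighbouring prisms agree on
split_prisms <- function(prisms) {
  perms <- rbind(
    c(1L, 2L, 3L, 4L, 5L, 6L),
    c(2L, 3L, 1L, 5L, 6L, 4L),
    c(3L, 1L, 2L, 6L, 4L, 5L),
    c(4L, 6L, 5L, 1L, 3L, 2L),
    c(5L, 4L, 6L, 2L, 1L, 3L),
    c(6L, 5L, 4L, 3L, 2L, 1L)
  )
  n <- nrow(prisms)
  k <- max.col(-prisms, ties.method = "first") # position of the min vertex
  p <- perms[k, , drop = FALSE]
  w <- matrix(prisms[cbind(rep(seq_len(n), 6L), as.vector(p))], n, 6L)
  cond <- pmin(w[, 2L], w[, 6L]) < pmin(w[, 3L], w[, 5L])
  tets <- matrix(0L, 3L * n, 4L)
  idx <- function(r, cols) w[r, cols, drop = FALSE]
  a <- which(cond)
  b <- which(!cond)
  if (length(a)) {
    tets[3L * (a - 1L) + 1L, ] <- idx(a, c(1L, 2L, 3L, 6L))
    tets[3L * (a - 1L) + 2L, ] <- idx(a, c(1L, 2L, 6L, 5L))
    tets[3L * (a - 1L) + 3L, ] <- idx(a, c(1L, 5L, 6L, 4L))
  }
  if (length(b)) {
    tets[3L * (b - 1L) + 1L, ] <- idx(b, c(1L, 2L, 3L, 5L))
    tets[3L * (b - 1L) + 2L, ] <- idx(b, c(1L, 5L, 3L, 6L))
    tets[3L * (b - 1L) + 3L, ] <- idx(b, c(1L, 5L, 6L, 4L))
  }
  tets
}

#' Mesh generation presets
#'
#' Named resolutions of the cylindrical mesh generator.  `nr` is the number
#' of radial rings of the disk triangulation and `nz` the number of extrusion
#' layers; the element count is `18 * nr^2 * nz`.
#'
#' @format A named list of `c(nr, nz)` integer pairs.
#' @export
cylinder_mesh_presets <- list(
  coarse = c(nr = 6L, nz = 23L),   # 14904 tetrahedra
  medium = c(nr = 7L, nz = 35L),   # 30870 tetrahedra
  fine   = c(nr = 9L, nz = 46L)    # 67068 tetrahedra
)

#' Generate a tetrahedral mesh of a cylinder
#'
#' The cylinder is centred on the z-axis with `z` in `[-height/2, height/2]`.
#' A ring-structured triangulation of the disk is extruded into prisms which
#' are split into conforming tetrahedra, giving deterministic node and
#' element counts with no external mesh generator.
#'
#' @param radius cylinder radius in mm (default 30, the standard phantom).
#' @param height cylinder height in mm (default 70).
#' @param resolution one of the preset names `"coarse"`, `"medium"`, `"fine"`
#'   (approximately 14.9k / 30.9k / 67.1k elements), a single numeric
#'   characteristic length in mm, or an integer vector `c(nr, nz)` giving the
#'   radial ring count and extrusion layer count directly.
#' @return A validated [tet_mesh()].
#' @export
generate_cylinder_mesh <- function(radius = 30, height = 70, resolution = "coarse") {
  if (!is.numeric(radius) || radius <= 0 || !is.numeric(height) || height <= 0) {
    stop("invalid-argument: radius and height must be positive")
  }
  if (is.character(resolution)) {
    if (!resolution %in% names(cylinder_mesh_presets)) {
      stop(sprintf(
        "invalid-argument: unknown preset '%s' (use %s)", resolution,
        paste(names(cylinder_mesh_presets), collapse = ", ")
      ))
    }
    res <- cylinder_mesh_presets[[resolution]]
    nr <- res[["nr"]]
    nz <- res[["nz"]]
  } else if (is.numeric(resolution) && length(resolution) == 1L) {
    if (resolution <= 0) stop("invalid-argument: characteristic length must be positive")
    nr <- max(1L, as.integer(round(radius / resolution)))
    nz <- max(1L, as.integer(round(height / resolution)))
  } else if (is.numeric(resolution) && length(resolution) == 2L) {
    nr <- as.integer(resolution[[1L]])
    nz <- as.integer(resolution[[2L]])
    if (nr < 1L || nz < 1L) stop("mesh-failure: resolution too coarse to tetrahedralize")
  } else {
    stop("invalid-argument: resolution must be a preset name, a length or c(nr, nz)")
  }
  disk <- disk_triangulation(radius, nr)
  nd <- nrow(disk$points)
  z <- seq(-height / 2, height / 2, length.out = nz + 1L)
  nodes <- cbind(
    disk$points[rep(seq_len(nd), nz + 1L), , drop = FALSE],
    rep(z, each = nd)
  )
  tri <- disk$triangles
  ntri <- nrow(tri)
  base <- rep((seq_len(nz) - 1L) * nd, each = ntri)
  bot <- tri[rep(seq_len(ntri), nz), , drop = FALSE] + base
  prisms <- cbind(bot, bot + nd)
  tet_mesh(nodes, split_prisms(prisms))
}

# ---- mesh file formats ------------------------------------------------------

#' Write a mesh to disk
#'
#' Supported formats: Gmsh MSH v2.2 ASCII (`"msh"`; tetrahedra as element
#' type 4, boundary triangles as type 2, 1-based node ids) and VTK legacy
#' ASCII unstructured grid (`"vtk"`; cell type 10, 0-based connectivity).
#'
#' @param mesh a `tet_mesh`.
#' @param path output file path.
#' @param format `"msh"` or `"vtk"`; default guessed from the file extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = guess_mesh_format(path)) {
  format <- match.arg(format, c("msh", "vtk"))
  if (format == "msh") write_mesh_msh(mesh, path) else write_mesh_vtk(mesh, path)
  invisible(path)
}

#' Read a mesh from disk
#'
#' @param path file path of a Gmsh MSH v2.2 ASCII or VTK legacy ASCII
#'   unstructured-grid file.
#' @param format `"msh"` or `"vtk"`; default guessed from the file extension.
#' @return A validated [tet_mesh()].
#' @export
read_mesh <- function(path, format = guess_mesh_format(path)) {
  format <- match.arg(format, c("msh", "vtk"))
  if (format == "msh") read_mesh_msh(path) else read_mesh_vtk(path)
}

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("msh", "vtk")) ext else stop("unsupported-format: cannot guess mesh format from '", path, "'")
}

#' Write-then-read a mesh through a file format
#'
#' Round-trips the mesh through a temporary file; useful for checking that a
#' format preserves coordinates and connectivity.
#'
#' @inheritParams write_mesh
#' @return The re-read [tet_mesh()].
#' @export
mesh_io_roundtrip <- function(mesh, format = c("msh", "vtk")) {
  format <- match.arg(format)
  path <- tempfile(fileext = paste0(".", format))
  on.exit(unlink(path))
  write_mesh(mesh, path, format)
  read_mesh(path, format)
}

write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
    as.character(mesh$n_nodes)), con)
  writeLines(sprintf(
    "%d %.17g %.17g %.17g",
    seq_len(mesh$n_nodes), mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]
  ), con)
  bd <- mesh$boundary_faces
  writeLines(c("$EndNodes", "$Elements",
    as.character(nrow(bd) + mesh$n_elements)), con)
  writeLines(sprintf(
    "%d 2 2 0 0 %d %d %d", seq_len(nrow(bd)), bd[, 1], bd[, 2], bd[, 3]
  ), con)
  el <- mesh$elements
  writeLines(sprintf(
    "%d 4 2 0 0 %d %d %d %d",
    nrow(bd) + seq_len(mesh$n_elements), el[, 1], el[, 2], el[, 3], el[, 4]
  ), con)
  writeLines("$EndElements", con)
}

msh_parse_error <- function(path, line, msg) {
  stop(sprintf("parse-error: %s (%s, line %d)", msg, path, line))
}

read_mesh_msh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) msh_parse_error(path, 1L, "empty file")
  sec <- function(name) {
    i <- match(paste0("$", name), lines)
    if (is.na(i)) msh_parse_error(path, 1L, paste0("missing $", name, " section"))
    i
  }
  i_nodes <- sec("Nodes")
  n_nodes <- suppressWarnings(as.integer(lines[i_nodes + 1L]))
  if (is.na(n_nodes)) msh_parse_error(path, i_nodes + 1L, "bad node count")
  node_rows <- lines[i_nodes + 1L + seq_len(n_nodes)]
  nm <- matrix(suppressWarnings(as.numeric(unlist(strsplit(node_rows, "\\s+")))),
    ncol = 4L, byrow = TRUE)
  if (anyNA(nm)) msh_parse_error(path, i_nodes + 2L, "malformed node line")
  nodes <- matrix(0, n_nodes, 3L)
  nodes[nm[, 1L], ] <- nm[, 2:4]
  i_el <- sec("Elements")
  n_el <- suppressWarnings(as.integer(lines[i_el + 1L]))
  if (is.na(n_el)) msh_parse_error(path, i_el + 1L, "bad element count")
  el_rows <- lines[i_el + 1L + seq_len(n_el)]
  tets <- NULL
  parsed <- strsplit(el_rows, "\\s+")
  types <- vapply(parsed, function(p) suppressWarnings(as.integer(p[2L])), integer(1))
  if (anyNA(types)) msh_parse_error(path, i_el + 2L, "malformed element line")
  keep <- which(types == 4L)
  if (length(keep) == 0L) msh_parse_error(path, i_el + 1L, "no tetrahedral (type 4) elements")
  tets <- t(vapply(parsed[keep], function(p) {
    ntags <- as.integer(p[3L])
    v <- suppressWarnings(as.integer(p[(4L + ntags):(7L + ntags)]))
    v
  }, integer(4)))
  if (anyNA(tets)) msh_parse_error(path, i_el + 2L, "malformed tetrahedron connectivity")
  tet_mesh(nodes, tets)
}

write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0", "tet_mesh", "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", mesh$n_nodes)
  ), con)
  writeLines(sprintf("%.17g %.17g %.17g",
    mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  el0 <- mesh$elements - 1L
  writeLines(sprintf("CELLS %d %d", mesh$n_elements, 5L * mesh$n_elements), con)
  writeLines(sprintf("4 %d %d %d %d", el0[, 1], el0[, 2], el0[, 3], el0[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", mesh$n_elements), con)
  writeLines(rep("10", mesh$n_elements), con)
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) msh_parse_error(path, 1L, "empty file")
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1L) msh_parse_error(path, 1L, "missing POINTS section")
  n_nodes <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  coords <- suppressWarnings(as.numeric(unlist(strsplit(
    lines[ip + seq_len(n_nodes)], "\\s+"))))
  coords <- coords[!is.na(coords)]
  if (length(coords) != 3L * n_nodes) msh_parse_error(path, ip + 1L, "malformed POINTS block")
  nodes <- matrix(coords, ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)
  if (length(ic) != 1L) msh_parse_error(path, 1L, "missing CELLS section")
  n_cells <- as.integer(strsplit(lines[ic], "\\s+")[[1L]][2L])
  cell_rows <- strsplit(lines[ic + seq_len(n_cells)], "\\s+")
  counts <- vapply(cell_rows, function(p) suppressWarnings(as.integer(p[1L])), integer(1))
  if (any(is.na(counts)) || any(counts != 4L)) {
    msh_parse_error(path, ic + 1L, "only tetrahedral cells (4 points) are supported")
  }
  tets <- t(vapply(cell_rows, function(p) as.integer(p[2:5]), integer(4))) + 1L
  tet_mesh(nodes, tets)
}

#' Write per-element scalar data on a mesh as a VTK legacy file
#'
#' Writes the mesh and one CELL_DATA scalar field (e.g. an absorption map or
#' a reconstruction iterate) for inspection in ParaView or similar viewers.
#'
#' @param mesh a `tet_mesh`.
#' @param values numeric vector, one value per element.
#' @param path output file path.
#' @param name scalar field name used in the VTK header.
#' @return `path`, invisibly.
#' @export
write_vtk_cell_data <- function(mesh, values, path, name = "mu_a") {
  if (length(values) != mesh$n_elements) {
    stop("invalid-argument: one value per element required")
  }
  write_mesh_vtk(mesh, path)
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(c(
    sprintf("CELL_DATA %d", mesh$n_elements),
    sprintf("SCALARS %s double 1", name),
    "LOOKUP_TABLE default"
  ), con)
  writeLines(sprintf("%.17g", values), con)
  invisible(path)
}
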