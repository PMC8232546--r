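#' Simplicial meshes
#'
#' Minimal triangle (2D) / tetrahedral (3D) mesh container used by all
#' assembly routines. Nodes are stored as an `n x d` coordinate matrix,
#' elements as an `ne x (d+1)` index matrix, and boundary facets (edges in
#' 2D, triangles in 3D) as an `nf x d` index matrix with one character tag
#' per facet ("wall", "inlet", "outlet1", ...).
#'
#' @param nodes numeric matrix of node coordinates (`n x d`).
#' @param elems integer matrix of element connectivity (`ne x (d+1)`).
#' @param facets integer matrix of boundary facet connectivity (`nf x d`).
#' @param facet_tag character vector of facet tags, length `nrow(facets)`.
#' @return An object of class `rbe_mesh`.
#' @export
rbe_mesh <- function(nodes, elems, facets, facet_tag) {
  nodes <- as.matrix(nodes)
  d <- ncol(nodes)
  stopifnot(d %in% c(2L, 3L))
  elems <- matrix(as.integer(as.matrix(elems)), ncol = d + 1L)
  facets <- matrix(as.integer(as.matrix(facets)), ncol = d)
  stopifnot(length(facet_tag) == nrow(facets))
  m <- structure(list(dim = d, nodes = nodes, elems = elems,
                      facets = facets, facet_tag = as.character(facet_tag)),
                 class = "rbe_mesh")
  vol <- element_volumes(m)
  if (any(vol <= 0)) {
    # repair orientation for 2D; refuse degenerate elements
    if (d == 2L) {
      flip <- which(vol < 0)
      m$elems[flip, c(2L, 3L)] <- m$elems[flip, c(3L, 2L)]
      vol <- element_volumes(m)
    }
    if (any(vol <= 0)) stop("mesh contains degenerate or inverted elements")
  }
  m
}

#' @export
print.rbe_mesh <- function(x, ...) {
  cat(sprintf("<rbe_mesh> %dD: %d nodes, %d elements, %d boundary facets (%s)\n",
              x$dim, nrow(x$nodes), nrow(x$elems), nrow(x$facets),
              paste(unique(x$facet_tag), collapse = ", ")))
  invisible(x)
}

#' Signed element volumes (areas in 2D)
#'
#' @param mesh an `rbe_mesh`.
#' @return numeric vector of signed element measures.
#' @export
element_volumes <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elems
  if (mesh$dim == 2L) {
    a <- nd[el[, 1L], , drop = FALSE]
    b <- nd[el[, 2L], , drop = FALSE]
    c <- nd[el[, 3L], , drop = FALSE]
    0.5 * ((b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
           (c[, 1L] - a[, 1L]) * (b[, 2L] - a[, 2L]))
  } else {
    a <- nd[el[, 1L], , drop = FALSE]
    b <- nd[el[, 2L], , drop = FALSE] - a
    c <- nd[el[, 3L], , drop = FALSE] - a
    d <- nd[el[, 4L], , drop = FALSE] - a
    (b[, 1L] * (c[, 2L] * d[, 3L] - c[, 3L] * d[, 2L]) -
     b[, 2L] * (c[, 1L] * d[, 3L] - c[, 3L] * d[, 1L]) +
     b[, 3L] * (c[, 1L] * d[, 2L] - c[, 2L] * d[, 1L])) / 6
  }
}

#' Structured triangulation of an axis-aligned rectangle
#'
#' Each grid cell is split into two triangles. Boundary tags follow the
#' `tags` argument in the order left (x = x0), right (x = x1),
#' bottom (y = y0), top (y = y1).
#'
#' @param nx,ny number of cells in x and y (both >= 1).
#' @param x0,x1,y0,y1 rectangle extents.
#' @param tags character(4): tags for the left, right, bottom and top sides.
#' @return an `rbe_mesh`.
#' @export
mesh_rectangle <- function(nx, ny, x0 = 0, x1 = 1, y0 = 0, y1 = 1,
                           tags = c("left", "right", "bottom", "top")) {
  stopifnot(nx >= 1, ny >= 1, x1 > x0, y1 > y0, length(tags) == 4L)
  xs <- seq(x0, x1, length.out = nx + 1L)
  ys <- seq(y0, y1, length.out = ny + 1L)
  nodes <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i  # i in 1..nx+1, j in 1..ny+1
  el <- vector("list", nx * ny)
  k <- 1L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      n00 <- idx(i, j); n10 <- idx(i + 1L, j)
      n01 <- idx(i, j + 1L); n11 <- idx(i + 1L, j + 1L)
      # split along the cell diagonal, alternating for isotropy
      if ((i + j) %% 2L == 0L) {
        el[[k]] <- rbind(c(n00, n10, n11), c(n00, n11, n01))
      } else {
        el[[k]] <- rbind(c(n00, n10, n01), c(n10, n11, n01))
      }
      k <- k + 1L
    }
  }
  elems <- do.call(rbind, el)
  fc <- list(); tg <- character(0)
  for (j in seq_len(ny)) { fc[[length(fc) + 1L]] <- c(idx(1L, j), idx(1L, j + 1L)); tg <- c(tg, tags[1L]) }
  for (j in seq_len(ny)) { fc[[length(fc) + 1L]] <- c(idx(nx + 1L, j), idx(nx + 1L, j + 1L)); tg <- c(tg, tags[2L]) }
  for (i in seq_len(nx)) { fc[[length(fc) + 1L]] <- c(idx(i, 1L), idx(i + 1L, 1L)); tg <- c(tg, tags[3L]) }
  for (i in seq_len(nx)) { fc[[length(fc) + 1L]] <- c(idx(i, ny + 1L), idx(i + 1L, ny + 1L)); tg <- c(tg, tags[4L]) }
  rbe_mesh(nodes, elems, do.call(rbind, fc), tg)
}

# Merge a list of meshes into one, collapsing duplicate nodes (distance < tol).
# Facets whose edge becomes interior (shared by two elements) are dropped.
mesh_merge <- function(meshes, tol = 1e-9) {
  d <- meshes[[1L]]$dim
  nodes <- do.call(rbind, lapply(meshes, function(m) m$nodes))
  off <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$nodes), integer(1))))
  elems <- do.call(rbind, Map(function(m, o) m$elems + o,
                              meshes, off[-length(off)]))
  facets <- do.call(rbind, Map(function(m, o) m$facets + o,
                               meshes, off[-length(off)]))
  tags <- unlist(lapply(meshes, function(m) m$facet_tag))
  # deduplicate nodes on a rounded-coordinate key
  key <- apply(round(nodes / tol) * tol, 1L, paste, collapse = "|")
  first <- !duplicated(key)
  remap <- match(key, key[first])  # index into the deduplicated node list
  nodes <- nodes[first, , drop = FALSE]
  elems[] <- remap[elems]
  facets[] <- remap[facets]
  # keep only facets that are true boundary edges of the merged mesh
  ek <- facet_keys(elems, d)
  fk <- apply(matrix(apply(facets, 1L, sort), ncol = nrow(facets)), 2L, paste, collapse = "-")
  cnt <- table(ek)
  keep <- cnt[fk] == 1L
  rbe_mesh(nodes, elems, facets[keep, , drop = FALSE], tags[keep])
}

# Keys of all element facets (edges in 2D) as "a-b" sorted strings.
facet_keys <- function(elems, d) {
  if (d == 2L) {
    e <- rbind(elems[, c(2L, 3L)], elems[, c(3L, 1L)], elems[, c(1L, 2L)])
  } else {
    e <- rbind(elems[, c(2L, 3L, 4L)], elems[, c(1L, 3L, 4L)],
               elems[, c(1L, 2L, 4L)], elems[, c(1L, 2L, 3L)])
  }
  apply(matrix(apply(e, 1L, sort), ncol = nrow(e)), 2L, paste, collapse = "-")
}

# Compact deterministic fingerprint used in archive manifests to guard
# against mixing bases with meshes they were not built on.
mesh_fingerprint <- function(mesh) {
  sprintf("%d-%d-%.12e-%d", nrow(mesh$nodes), nrow(mesh$elems),
          sum(mesh$nodes), sum(mesh$elems))
}

#' Write a mesh (with optional fields) as a VTK XML unstructured grid
#'
#' Produces an ASCII .vtu file readable by ParaView and friends.
#'
#' @param mesh an `rbe_mesh`.
#' @param file output path.
#' @param point_data named list of per-node fields (vectors, or matrices with
#'   one row per node for vector fields).
#' @param cell_data named list of per-element fields.
#' @return `file`, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  pts <- cbind(mesh$nodes, if (mesh$dim == 2L) 0 else NULL)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 12, trim = TRUE, scientific = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ne))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(t(pts)))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(t(mesh$elems) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(ne) * (mesh$dim + 1L), collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(if (mesh$dim == 2L) 5L else 10L, ne), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      if (is.matrix(v) && nc == 2L) { v <- cbind(v, 0); nc <- 3L }
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">', nm, nc))
      w(num(if (is.matrix(v)) t(v) else v))
      w('</DataArray>')
    }
    w('</PointData>')
  }
  if (length(cell_data)) {
    w('<CellData>')
    for (nm in names(cell_data)) {
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="1" format="ascii">', nm))
      w(num(cell_data[[nm]]))
      w('</DataArray>')
    }
    w('</CellData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Facet tags are exported as physical names; triangles (2D) or tetrahedra
#' carry physical tag 0.
#'
#' @param mesh an `rbe_mesh`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  tags <- unique(mesh$facet_tag)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(length(tags))
  for (i in seq_along(tags)) w(sprintf('%d %d "%s"', mesh$dim - 1L, i, tags[i]))
  w("$EndPhysicalNames")
  w("$Nodes"); w(nrow(mesh$nodes))
  nd <- cbind(mesh$nodes, if (mesh$dim == 2L) 0 else NULL)
  for (i in seq_len(nrow(nd)))
    w(sprintf("%d %.16g %.16g %.16g", i, nd[i, 1L], nd[i, 2L], nd[i, 3L]))
  w("$EndNodes")
  ftag <- match(mesh$facet_tag, tags)
  ftype <- if (mesh$dim == 2L) 1L else 2L
  etype <- if (mesh$dim == 2L) 2L else 4L
  w("$Elements"); w(nrow(mesh$facets) + nrow(mesh$elems))
  k <- 1L
  for (i in seq_len(nrow(mesh$facets))) {
    w(paste(c(k, ftype, 2L, ftag[i], ftag[i], mesh$facets[i, ]), collapse = " "))
    k <- k + 1L
  }
  for (i in seq_len(nrow(mesh$elems))) {
    w(paste(c(k, etype, 2L, 0L, 0L, mesh$elems[i, ]), collapse = " "))
    k <- k + 1L
  }
  w("$EndElements")
  invisible(file)
}

#' Read a Gmsh MSH 2.2 ASCII mesh
#'
#' Supports the subset written by [write_msh()]: one element block of
#' triangles or tetrahedra plus tagged boundary facets with physical names.
#'
#' @param file path to a .msh file.
#' @return an `rbe_mesh`.
#' @export
read_msh <- function(file) {
  ln <- readLines(file)
  sec <- function(name) {
    i0 <- which(ln == paste0("$", name)) + 1L
    i1 <- which(ln == paste0("$End", name)) - 1L
    ln[i0:i1]
  }
  pn <- sec("PhysicalNames")
  npn <- as.integer(pn[1L])
  names_map <- character(0)
  for (i in seq_len(npn)) {
    parts <- strsplit(pn[1L + i], " ")[[1L]]
    id <- as.integer(parts[2L])
    names_map[id] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
  }
  nd <- sec("Nodes")
  nn <- as.integer(nd[1L])
  nm <- do.call(rbind, lapply(nd[1L + seq_len(nn)],
                              function(s) as.numeric(strsplit(s, " ")[[1L]])))
  coords <- nm[, 2:4, drop = FALSE]
  el <- sec("Elements")
  nel <- as.integer(el[1L])
  rows <- lapply(el[1L + seq_len(nel)], function(s) as.integer(strsplit(s, " ")[[1L]]))
  types <- vapply(rows, `[`, integer(1), 2L)
  is3d <- any(types == 4L)
  d <- if (is3d) 3L else 2L
  etype <- if (is3d) 4L else 2L
  ftype <- if (is3d) 2L else 1L
  get_nodes <- function(r) r[-seq_len(3L + r[3L])]
  elems <- do.call(rbind, lapply(rows[types == etype], get_nodes))
  fr <- rows[types == ftype]
  facets <- do.call(rbind, lapply(fr, get_nodes))
  ftag <- names_map[vapply(fr, function(r) r[4L], integer(1))]
  rbe_mesh(coords[, seq_len(d), drop = FALSE], elems, facets, ftag)
}
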