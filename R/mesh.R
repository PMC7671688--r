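#' Triangulated surface mesh with per-vertex scalar fields
#'
#' Constructs a `surface_mesh`, the basic container used throughout the
#' package. Vertices are 3D coordinates in millimetres, RAS orientation
#' (x lateral+, y anterior+, z superior+). Triangles are 1-based vertex index
#' triples (R convention; file readers/writers convert from/to the 0-based
#' convention of GIFTI/PLY). Scalars are named per-vertex fields such as
#' region labels or internal hippocampal coordinates.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param scalars named list of length-n vectors (numeric, integer or
#'   character) attached to vertices.
#' @param validate check index ranges, duplicate triangles and degenerate
#'   (zero-area) faces.
#' @return object of class `surface_mesh`: a list with elements `vertices`,
#'   `triangles`, `scalars`.
#' @export
surface_mesh <- function(vertices, triangles, scalars = list(), validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  n <- nrow(vertices)
  if (validate && nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > n)
      stop("triangle indices out of range [1, ", n, "]")
    key <- apply(triangles, 1L, function(tr) paste(sort(tr), collapse = "-"))
    if (anyDuplicated(key))
      stop("duplicated triangles present (", sum(duplicated(key)), ")")
    if (any(triangles[, 1L] == triangles[, 2L] |
            triangles[, 2L] == triangles[, 3L] |
            triangles[, 1L] == triangles[, 3L]))
      stop("degenerate triangles with repeated vertex indices")
  }
  for (nm in names(scalars)) {
    if (length(scalars[[nm]]) != n)
      stop("scalar field '", nm, "' has length ", length(scalars[[nm]]),
           ", expected ", n)
  }
  structure(list(vertices = vertices, triangles = triangles,
                 scalars = scalars),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  if (length(x$scalars))
    cat("  scalars:", paste(names(x$scalars), collapse = ", "), "\n")
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a `surface_mesh`
#' @return integer vertex count
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

## Undirected edge list (each edge once, i < j).
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e), , drop = FALSE]
}

## Per-edge incident triangle count; used for manifold checks and for the
## opposite-vertex augmentation of the geodesic graph.
edge_triangle_incidence <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(1L, 3L)])
  opp <- c(tr[, 3L], tr[, 1L], tr[, 2L])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "-")
  list(edges = e, opposite = opp, key = key, tri = rep(seq_len(m), 3L))
}

#' Check that a mesh is edge-manifold
#'
#' Every edge must belong to at most two triangles.
#'
#' @param mesh a `surface_mesh`
#' @return logical; attribute `"bad_edges"` lists offending edges when FALSE.
#' @export
is_edge_manifold <- function(mesh) {
  inc <- edge_triangle_incidence(mesh)
  counts <- table(inc$key)
  bad <- names(counts)[counts > 2L]
  ok <- length(bad) == 0L
  attr(ok, "bad_edges") <- bad
  ok
}

## Triangle areas.
triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c <- vertices[triangles[, 3L], , drop = FALSE]
  u <- b - a; v <- c - a
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-vertex one-ring surface area
#'
#' Each triangle contributes one third of its area to each of its vertices
#' (barycentric lumping), the standard discrete vertex-area used by
#' equivolumetric depth placement.
#'
#' @param mesh a `surface_mesh`
#' @return numeric vector of vertex areas (mm^2)
#' @export
vertex_areas <- function(mesh) {
  ar <- triangle_areas(mesh$vertices, mesh$triangles)
  out <- numeric(n_vertices(mesh))
  for (k in 1:3) {
    s <- tapply(ar, mesh$triangles[, k], sum)
    idx <- as.integer(names(s))
    out[idx] <- out[idx] + as.numeric(s)
  }
  out / 3
}

## Weighted geodesic graph: mesh edges plus, for every interior edge, the
## connection between the two opposite vertices of its adjacent triangles.
## Weights are Euclidean lengths. Returns an igraph.
mesh_geodesic_graph <- function(mesh) {
  inc <- edge_triangle_incidence(mesh)
  e <- cbind(pmin(inc$edges[, 1L], inc$edges[, 2L]),
             pmax(inc$edges[, 1L], inc$edges[, 2L]))
  dup <- duplicated(inc$key) | duplicated(inc$key, fromLast = TRUE)
  extra <- NULL
  if (any(dup)) {
    sp <- split(seq_along(inc$key)[dup], inc$key[dup])
    pairs <- lapply(sp, function(ix) {
      if (length(ix) != 2L) return(NULL)          # non-manifold: skip
      o <- inc$opposite[ix]
      if (o[1L] == o[2L]) return(NULL)
      c(min(o), max(o))
    })
    pairs <- do.call(rbind, pairs)
    extra <- pairs
  }
  all_e <- rbind(e[!duplicated(inc$key), , drop = FALSE], extra)
  all_e <- all_e[!duplicated(all_e), , drop = FALSE]
  w <- sqrt(rowSums((mesh$vertices[all_e[, 1L], , drop = FALSE] -
                     mesh$vertices[all_e[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(all_e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_vertices(mesh) - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  g
}

#' 1-to-4 (loop-style midpoint) subdivision of a mesh
#'
#' Splits every triangle into four by inserting edge midpoints. Per-vertex
#' numeric scalars are linearly interpolated onto midpoints; character/label
#' scalars are copied from the lower-indexed endpoint.
#'
#' @param mesh a `surface_mesh`
#' @return subdivided `surface_mesh`; attribute `"parent_edges"` maps each
#'   new vertex to the (i, j) endpoints of its parent edge (i = j for
#'   original vertices).
#' @export
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(v)
  ed <- mesh_edges(mesh)
  key <- paste(ed[, 1L], ed[, 2L], sep = "-")
  mid_id <- setNames(n + seq_len(nrow(ed)), key)
  mids <- (v[ed[, 1L], , drop = FALSE] + v[ed[, 2L], , drop = FALSE]) / 2
  newv <- rbind(v, mids)
  ek <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")
  a <- tr[, 1L]; b <- tr[, 2L]; c <- tr[, 3L]
  ab <- mid_id[ek(a, b)]; bc <- mid_id[ek(b, c)]; ca <- mid_id[ek(c, a)]
  newt <- rbind(cbind(a, ab, ca), cbind(ab, b, bc),
                cbind(ca, bc, c), cbind(ab, bc, ca))
  colnames(newt) <- NULL
  sc <- lapply(mesh$scalars, function(s) {
    if (is.numeric(s)) c(s, (s[ed[, 1L]] + s[ed[, 2L]]) / 2)
    else c(s, s[ed[, 1L]])
  })
  out <- surface_mesh(newv, newt, sc, validate = FALSE)
  attr(out, "parent_edges") <- rbind(cbind(seq_len(n), seq_len(n)), ed)
  out
}

#' Connected components of a mesh
#' @param mesh a `surface_mesh`
#' @return integer membership vector, one entry per vertex
#' @export
mesh_components <- function(mesh) {
  g <- mesh_geodesic_graph(mesh)
  igraph::components(g)$membership
}

#' Icosphere mesh (subdivided icosahedron projected to a sphere)
#'
#' @param subdivisions number of 1-to-4 subdivision rounds (0 = icosahedron;
#'   4 gives 2562 vertices)
#' @param radius sphere radius
#' @return a `surface_mesh`
#' @export
icosphere <- function(subdivisions = 3L, radius = 1) {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  tr <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
              c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
              c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
              c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v / sqrt(1 + p^2), tr, validate = FALSE)
  for (i in seq_len(subdivisions)) mesh <- subdivide_mesh(mesh)
  nrm <- sqrt(rowSums(mesh$vertices^2))
  mesh$vertices <- mesh$vertices / nrm * radius
  mesh
}
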