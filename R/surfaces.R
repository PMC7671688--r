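#' Identify hippocampal bridgehead vertices
#'
#' Bridgeheads are the medial-most subicular vertices: those attaining the
#' per-row minimum of the proximal-distal internal coordinate. Rows are
#' groups of vertices sharing an anterior-posterior (y) coordinate (within
#' `tol`); within each row the vertex with minimal proximal-distal value is
#' returned, ties broken by lowest vertex index. The result is ordered by
#' anterior-posterior coordinate.
#'
#' @param allo_mesh allocortical `surface_mesh` carrying a
#'   `proximal_distal` scalar
#' @param tol tolerance for grouping anterior-posterior rows (mm)
#' @return integer vector of bridgehead vertex indices, sorted by y
#' @export
find_bridgeheads <- function(allo_mesh, tol = 1e-6) {
  pd <- allo_mesh$scalars$proximal_distal
  if (is.null(pd))
    stop("allo_mesh lacks the per-vertex 'proximal_distal' scalar field")
  if (diff(range(pd)) < 1e-12)
    stop("proximal_distal field is constant: every vertex is a candidate; ",
         "a non-degenerate proximal-distal coordinate is required")
  y <- allo_mesh$vertices[, 2]
  row_id <- match(round(y / max(tol, 1e-12)), unique(round(y / max(tol, 1e-12))))
  picks <- vapply(split(seq_along(pd), row_id), function(ix) {
    ix[which.min(pd[ix])]          # which.min takes the first = lowest index
  }, integer(1))
  picks <- as.integer(picks)
  picks[order(y[picks], picks)]
}

#' Match bridgeheads to their closest inferior isocortical vertices
#'
#' For each bridgehead, the match is the isocortical vertex minimising
#' Euclidean distance among candidates with a strictly lower z-coordinate
#' (only inferior vertices are considered, discounting the section of the
#' isocortical model that skips over the hippocampus). Optionally restricts
#' candidates to given region labels. Ties are broken by lowest vertex
#' index.
#'
#' @param bridgeheads integer indices into `allo_mesh` vertices
#' @param allo_mesh allocortical `surface_mesh` (for bridgehead coordinates)
#' @param iso_mesh isocortical `surface_mesh`
#' @param regions optional character vector of admissible `region` labels
#'   (e.g. entorhinal/parahippocampal/fusiform); NULL = all vertices
#' @return data frame with columns `bridgehead`, `iso_vertex`, `distance`
#' @export
match_bridgeheads_to_isocortex <- function(bridgeheads, allo_mesh, iso_mesh,
                                           regions = NULL) {
  cand <- seq_len(n_vertices(iso_mesh))
  if (!is.null(regions)) {
    lab <- iso_mesh$scalars$region
    if (is.null(lab)) stop("iso_mesh lacks a 'region' scalar field")
    cand <- cand[lab %in% regions]
    if (!length(cand)) stop("no isocortical vertices in regions: ",
                            paste(regions, collapse = ", "))
  }
  vc <- iso_mesh$vertices[cand, , drop = FALSE]
  out <- data.frame(bridgehead = bridgeheads, iso_vertex = NA_integer_,
                    distance = NA_real_)
  for (i in seq_along(bridgeheads)) {
    b <- allo_mesh$vertices[bridgeheads[i], ]
    ok <- vc[, 3] < b[3]
    if (!any(ok))
      stop("no inferior isocortical candidate for bridgehead ",
           bridgeheads[i], " (z = ", format(b[3]), ")")
    d2 <- rowSums(sweep(vc[ok, , drop = FALSE], 2, b)^2)
    j <- which(d2 == min(d2))[1L]         # lowest index among ties
    out$iso_vertex[i] <- cand[ok][j]
    out$distance[i] <- sqrt(d2[j])
  }
  out
}

#' Stitch isocortical and allocortical surfaces into a confluence model
#'
#' Combines the allocortical inner vertices and the mesiotemporal pial
#' vertices with their original triangles, adds bridge triangles
#' `{b_i, match(b_i), b_{i-1}}` and `{b_i, match(b_i), b_{i+1}}`
#' (deduplicated; terminal bridgeheads get a single bridge triangle), and
#' removes every isocortical vertex whose nearest bridgehead (Euclidean) is
#' inferior to it. The white/outer pair is linked by the identical triangle
#' list using matched vertex identity. Vertex coordinates are never moved.
#'
#' @param iso_pair list with `pial` and `white` surface_mesh (matched
#'   vertices)
#' @param allo_pair list with `inner` and `outer` surface_mesh
#' @param matches data frame from [match_bridgeheads_to_isocortex()]
#'   (bridgeheads must be ordered along the anterior-posterior axis)
#' @param on_nonmanifold `"warn"` (default), `"error"` or `"none"`: what to
#'   do when the stitched inner mesh is not edge-manifold along the seam.
#'   The bridging rule generically places three triangles on a seam edge
#'   when neighbouring bridgeheads have distinct matches, so strictness is
#'   configurable.
#' @return object of class `confluence_model`: `inner`, `outer`
#'   (surface_mesh sharing one triangle list), `bridgeheads` (indices into
#'   the stitched mesh), `origin` ("iso"/"allo" per vertex), `ap_mm`,
#'   `subregion`, and provenance maps `allo_index`/`iso_index`.
#' @export
stitch_confluence <- function(iso_pair, allo_pair, matches,
                              on_nonmanifold = c("warn", "error", "none")) {
  on_nonmanifold <- match.arg(on_nonmanifold)
  if (!nrow(matches)) stop("matches must be non-empty")
  allo_in <- allo_pair$inner; allo_out <- allo_pair$outer
  iso_p <- iso_pair$pial; iso_w <- iso_pair$white
  n_allo <- n_vertices(allo_in); n_iso <- n_vertices(iso_p)

  ## drop isocortical vertices whose nearest bridgehead is inferior
  bh_xyz <- allo_in$vertices[matches$bridgehead, , drop = FALSE]
  iso_xyz <- iso_p$vertices
  nearest_bh <- integer(n_iso)
  chunk <- 4096L
  for (st in seq(1L, n_iso, by = chunk)) {
    en <- min(st + chunk - 1L, n_iso)
    d2 <- outer(rowSums(iso_xyz[st:en, , drop = FALSE]^2),
                rowSums(bh_xyz^2), "+") -
      2 * iso_xyz[st:en, , drop = FALSE] %*% t(bh_xyz)
    nearest_bh[st:en] <- max.col(-d2, ties.method = "first")
  }
  drop_iso <- bh_xyz[nearest_bh, 3] < iso_xyz[, 3]
  keep_iso <- which(!drop_iso)
  keep_iso <- sort(union(keep_iso, matches$iso_vertex))  # matches survive

  ## stitched vertex numbering: allocortex first, then surviving isocortex
  iso_new <- rep(NA_integer_, n_iso)
  iso_new[keep_iso] <- n_allo + seq_along(keep_iso)
  tri_allo <- allo_in$triangles
  tri_iso <- iso_p$triangles
  tri_iso_keep <- tri_iso[rowSums(matrix(tri_iso %in% keep_iso,
                                         nrow(tri_iso))) == 3L, , drop = FALSE]
  tri_iso_new <- matrix(iso_new[tri_iso_keep], ncol = 3L)

  ## bridge triangles
  bh <- matches$bridgehead
  m_new <- iso_new[matches$iso_vertex]
  nb <- length(bh)
  mk <- function(i, j) {
    if (j < 1L || j > nb) return(NULL)
    c(bh[i], m_new[i], bh[j])
  }
  bridges <- list()
  for (i in seq_len(nb)) {
    bridges[[length(bridges) + 1L]] <- mk(i, i - 1L)
    bridges[[length(bridges) + 1L]] <- mk(i, i + 1L)
  }
  bridges <- do.call(rbind, bridges)
  if (is.null(bridges) || !nrow(bridges)) {
    warning("single bridgehead: no bridge triangles created")
    bridges <- matrix(integer(0), 0, 3)
  } else {
    key <- apply(bridges, 1L, function(tr) paste(sort(tr), collapse = "-"))
    bridges <- bridges[!duplicated(key), , drop = FALSE]
    bridges <- bridges[bridges[, 1L] != bridges[, 3L], , drop = FALSE]
  }

  tris <- rbind(tri_allo, tri_iso_new, bridges)
  verts_in <- rbind(allo_in$vertices, iso_p$vertices[keep_iso, , drop = FALSE])
  verts_out <- rbind(allo_out$vertices, iso_w$vertices[keep_iso, , drop = FALSE])

  take <- function(mesh, field, idx) {
    s <- mesh$scalars[[field]]
    if (is.null(s)) rep(NA, length(idx)) else s[idx]
  }
  ap <- c(allo_in$vertices[, 2], iso_p$vertices[keep_iso, 2])
  subregion <- c(as.character(take(allo_in, "subregion", seq_len(n_allo))),
                 as.character(take(iso_p, "region", keep_iso)))
  gt <- c(take(allo_in, "gt_axis", seq_len(n_allo)),
          take(iso_p, "gt_axis", keep_iso))
  origin <- c(rep("allo", n_allo), rep("iso", length(keep_iso)))

  inner <- surface_mesh(verts_in, tris,
                        scalars = list(origin = origin, ap = ap,
                                       subregion = subregion, gt_axis = gt),
                        validate = FALSE)
  outer <- surface_mesh(verts_out, tris, scalars = inner$scalars,
                        validate = FALSE)

  ## seam manifoldness check
  inc <- edge_triangle_incidence(inner)
  counts <- table(inc$key)
  bad <- names(counts)[counts > 2L]
  if (length(bad) && on_nonmanifold != "none") {
    msg <- paste0("stitched mesh not edge-manifold along the seam: ",
                  length(bad), " edges with >2 incident triangles (e.g. ",
                  paste(utils::head(bad, 5L), collapse = "; "), ")")
    if (on_nonmanifold == "error") stop(msg) else warning(msg)
  }

  structure(list(inner = inner, outer = outer,
                 bridgeheads = bh, origin = origin,
                 ap_mm = ap, subregion = subregion,
                 allo_index = seq_len(n_allo), iso_index = keep_iso,
                 axis_mm = NULL),
            class = "confluence_model")
}

#' @export
print.confluence_model <- function(x, ...) {
  cat("confluence_model:", n_vertices(x$inner), "vertices (",
      sum(x$origin == "allo"), "allocortical /", sum(x$origin == "iso"),
      "isocortical ),", length(x$bridgeheads), "bridgeheads\n")
  if (!is.null(x$axis_mm))
    cat("  axis range:", paste(signif(range(x$axis_mm), 4), collapse = " .. "),
        "mm\n")
  invisible(x)
}

#' Compute the signed geodesic iso-to-allocortical axis
#'
#' Multi-source shortest-path distance from the bridgehead set over the
#' inner (pial-continuous) stitched surface, on the graph of mesh edges
#' augmented with opposite-vertex connections across each interior edge.
#' The sign is negative for vertices of isocortical origin, positive for
#' allocortical origin, and exactly zero at bridgeheads.
#'
#' @param model a `confluence_model` (or a bare `surface_mesh` when
#'   `sources` is given)
#' @param sources optional integer vertex set overriding the model
#'   bridgeheads
#' @return the model with `axis_mm` filled (or, for a bare mesh, the
#'   unsigned distance vector)
#' @export
compute_axis <- function(model, sources = NULL) {
  if (inherits(model, "surface_mesh")) {
    if (is.null(sources)) stop("sources required for a bare surface_mesh")
    return(.geodesic_from(model, sources))
  }
  stopifnot(inherits(model, "confluence_model"))
  src <- if (is.null(sources)) model$bridgeheads else sources
  d <- .geodesic_from(model$inner, src)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d))
    stop("disconnected vertices unreachable from bridgeheads: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  sign <- ifelse(model$origin == "iso", -1, 1)
  model$axis_mm <- d * sign
  model$axis_mm[src] <- 0
  model$inner$scalars$axis_mm <- model$axis_mm
  model$outer$scalars$axis_mm <- model$axis_mm
  model
}

.geodesic_from <- function(mesh, sources) {
  g <- mesh_geodesic_graph(mesh)
  d <- igraph::distances(g, v = sources, algorithm = "dijkstra")
  apply(d, 2L, min)
}

#' Restrict a confluence model to an anterior-posterior range
#'
#' Drops vertices outside `ap_range`, re-indexes triangles, and preserves
#' subregion labels and axis values of surviving vertices.
#'
#' @param model a `confluence_model`
#' @param ap_range length-2 numeric (mm), inclusive
#' @param labels optional character vector: keep only vertices whose
#'   subregion label is in this set (applied after the AP restriction)
#' @return restricted `confluence_model`
#' @export
restrict_and_label <- function(model, ap_range, labels = NULL) {
  stopifnot(inherits(model, "confluence_model"), length(ap_range) == 2L)
  keep <- model$ap_mm >= min(ap_range) & model$ap_mm <= max(ap_range)
  if (!is.null(labels)) keep <- keep & model$subregion %in% labels
  if (!any(keep)) stop("restriction leaves no vertices")
  if (!any(keep & model$origin == "allo"))
    stop("restriction drops all allocortical vertices; axis undefined")
  idx <- which(keep)
  remap <- rep(NA_integer_, n_vertices(model$inner))
  remap[idx] <- seq_along(idx)
  tr <- model$inner$triangles
  tr_keep <- tr[rowSums(matrix(tr %in% idx, nrow(tr))) == 3L, , drop = FALSE]
  tr_new <- matrix(remap[tr_keep], ncol = 3L)
  sub_mesh <- function(mesh, verts) {
    sc <- lapply(mesh$scalars, function(s) s[idx])
    surface_mesh(mesh$vertices[idx, , drop = FALSE], tr_new, sc,
                 validate = FALSE)
  }
  bh <- remap[model$bridgeheads]
  bh <- bh[!is.na(bh)]
  structure(list(inner = sub_mesh(model$inner), outer = sub_mesh(model$outer),
                 bridgeheads = bh, origin = model$origin[idx],
                 ap_mm = model$ap_mm[idx], subregion = model$subregion[idx],
                 allo_index = NULL, iso_index = NULL,
                 axis_mm = if (is.null(model$axis_mm)) NULL
                           else model$axis_mm[idx]),
            class = "confluence_model")
}

#' Build a toy confluence model end to end
#'
#' Convenience wrapper: bridgehead detection, inferior matching, stitching
#' and axis computation on a [make_toy_confluence()] result.
#'
#' @param toy result of [make_toy_confluence()]
#' @param ... passed to [stitch_confluence()]
#' @return `confluence_model` with axis computed
#' @export
toy_confluence_model <- function(toy, ...) {
  bh <- find_bridgeheads(toy$allo$inner)
  matches <- match_bridgeheads_to_isocortex(bh, toy$allo$inner, toy$iso$pial)
  model <- stitch_confluence(toy$iso, toy$allo, matches, ...)
  compute_axis(model)
}
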