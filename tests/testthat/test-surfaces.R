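test_that("find_bridgeheads needs a non-degenerate proximal-distal field", {
  toy <- fx_toy()
  bare <- toy$allo$inner
  bare$scalars$proximal_distal <- NULL
  expect_error(find_bridgeheads(bare), "proximal_distal")
  const <- toy$allo$inner
  const$scalars$proximal_distal <- rep(1, n_vertices(const))
  expect_error(find_bridgeheads(const), "constant")
})

test_that("bridgeheads equal the flagged seam row, one per row, sorted by y", {
  toy <- fx_toy()
  bh <- find_bridgeheads(toy$allo$inner)
  expect_setequal(bh, which(toy$allo$inner$scalars$seam))
  expect_equal(length(bh), toy$spec$n_columns)
  expect_true(!is.unsorted(toy$allo$inner$vertices[bh, 2]))
})

test_that("matching picks nearest strictly inferior candidates", {
  allo <- surface_mesh(rbind(c(0, 0, 5), c(0, 1, 5), c(0, 2, 5)),
                       matrix(c(1, 2, 3), 1), validate = FALSE)
  # single candidate below
  iso1 <- surface_mesh(rbind(c(0, 0, 4)), matrix(c(1, 1, 1), 1),
                       validate = FALSE)
  m <- match_bridgeheads_to_isocortex(1L, allo, iso1)
  expect_equal(m$iso_vertex, 1L)
  expect_equal(m$distance, 1)
  # two equidistant inferior candidates: lowest vertex index wins
  iso2 <- surface_mesh(rbind(c(-1, 0, 4), c(1, 0, 4)),
                       matrix(c(1, 2, 2), 1), validate = FALSE)
  expect_equal(match_bridgeheads_to_isocortex(1L, allo, iso2)$iso_vertex, 1L)
  # no inferior candidate -> error naming the bridgehead
  iso3 <- surface_mesh(rbind(c(0, 0, 6)), matrix(c(1, 1, 1), 1),
                       validate = FALSE)
  expect_error(match_bridgeheads_to_isocortex(2L, allo, iso3),
               "bridgehead 2")
  # region restriction
  iso4 <- surface_mesh(rbind(c(0, 0, 4), c(0, 0.1, 4.5)),
                       matrix(c(1, 2, 2), 1),
                       scalars = list(region = c("fusiform", "insula")),
                       validate = FALSE)
  m4 <- match_bridgeheads_to_isocortex(1L, allo, iso4,
                                       regions = c("entorhinal",
                                                   "parahippocampal",
                                                   "fusiform"))
  expect_equal(m4$iso_vertex, 1L)
})

test_that("toy matches equal the generator's seam correspondence", {
  toy <- fx_toy()
  bh <- find_bridgeheads(toy$allo$inner)
  m <- match_bridgeheads_to_isocortex(bh, toy$allo$inner, toy$iso$pial)
  expect_setequal(m$iso_vertex, which(toy$iso$pial$scalars$seam))
  # column alignment: matched iso vertex shares the bridgehead's y
  expect_equal(toy$iso$pial$vertices[m$iso_vertex, 2],
               toy$allo$inner$vertices[m$bridgehead, 2])
})

test_that("bridge triangles follow the neighbour rule with deduplication", {
  # hand-built configuration: 4 bridgeheads in a chain, 4 distinct matches.
  # expected triangles: {b_i, m_i, b_{i-1}} and {b_i, m_i, b_{i+1}} for all
  # i, deduplicated -> 6 distinct triangles (ends contribute one each)
  allo_v <- cbind(0, 0:3, 1)
  allo <- list(inner = surface_mesh(allo_v, rbind(c(1, 2, 3), c(2, 4, 3)),
                                    validate = FALSE),
               outer = surface_mesh(allo_v + c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1),
                                    rbind(c(1, 2, 3), c(2, 4, 3)),
                                    validate = FALSE))
  iso_v <- cbind(0.5, 0:3, 0)
  iso <- list(pial = surface_mesh(iso_v, rbind(c(1, 2, 3), c(2, 4, 3)),
                                  validate = FALSE),
              white = surface_mesh(iso_v - c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1),
                                   rbind(c(1, 2, 3), c(2, 4, 3)),
                                   validate = FALSE))
  matches <- data.frame(bridgehead = 1:4, iso_vertex = 1:4, distance = NA)
  model <- suppressWarnings(stitch_confluence(iso, allo, matches))
  n_allo <- 4L
  bridge <- model$inner$triangles[-(1:4), , drop = FALSE]  # after 2+2 sheet tris
  # brute-force oracle: enumerate {b_i, m_i, b_(i+/-1)} and deduplicate
  oracle <- list()
  for (i in 1:4) for (j in c(i - 1, i + 1)) if (j >= 1 && j <= 4)
    oracle[[length(oracle) + 1L]] <- sort(c(i, n_allo + i, j))
  oracle <- unique(oracle)
  got <- unique(lapply(seq_len(nrow(bridge)), function(r) sort(bridge[r, ])))
  expect_equal(length(got), length(oracle))
  expect_setequal(vapply(got, paste, collapse = "-", FUN.VALUE = ""),
                  vapply(oracle, paste, collapse = "-", FUN.VALUE = ""))
})

test_that("single bridgehead warns and yields no bridge triangles", {
  allo_v <- cbind(0, 0:2, 1)
  allo <- list(inner = surface_mesh(allo_v, rbind(c(1, 2, 3)), validate = FALSE),
               outer = surface_mesh(allo_v + rep(c(0, 0, 1), each = 3),
                                    rbind(c(1, 2, 3)), validate = FALSE))
  iso_v <- cbind(0.5, 0:2, 0)
  iso <- list(pial = surface_mesh(iso_v, rbind(c(1, 2, 3)), validate = FALSE),
              white = surface_mesh(iso_v - rep(c(0, 0, 1), each = 3),
                                   rbind(c(1, 2, 3)), validate = FALSE))
  matches <- data.frame(bridgehead = 2L, iso_vertex = 1L, distance = NA)
  expect_warning(model <- stitch_confluence(iso, allo, matches),
                 "single bridgehead")
  expect_equal(nrow(model$inner$triangles), 2L)
})

test_that("stitching never moves vertices and drops skipped-over isocortex", {
  toy <- fx_toy()
  bh <- find_bridgeheads(toy$allo$inner)
  m <- match_bridgeheads_to_isocortex(bh, toy$allo$inner, toy$iso$pial)
  model <- stitch_confluence(toy$iso, toy$allo, m, on_nonmanifold = "none")
  # coordinates bit-identical to inputs
  expect_identical(model$inner$vertices[model$allo_index, ],
                   toy$allo$inner$vertices)
  expect_identical(model$inner$vertices[-seq_along(model$allo_index), ],
                   toy$iso$pial$vertices[model$iso_index, ])
  expect_identical(model$outer$triangles, model$inner$triangles)
  # single connected component
  expect_equal(max(mesh_components(model$inner)), 1L)
  # the inferior-bridgehead removal rule, applied independently
  bh_xyz <- toy$allo$inner$vertices[bh, ]
  keep_oracle <- vapply(seq_len(n_vertices(toy$iso$pial)), function(i) {
    p <- toy$iso$pial$vertices[i, ]
    j <- which.min(colSums((t(bh_xyz) - p)^2))
    bh_xyz[j, 3] >= p[3]
  }, logical(1))
  expect_setequal(model$iso_index, union(which(keep_oracle), m$iso_vertex))
})

test_that("non-manifold seam detection honours the requested strictness", {
  toy <- fx_toy()
  bh <- find_bridgeheads(toy$allo$inner)
  m <- match_bridgeheads_to_isocortex(bh, toy$allo$inner, toy$iso$pial)
  expect_warning(stitch_confluence(toy$iso, toy$allo, m), "edge-manifold")
  expect_error(stitch_confluence(toy$iso, toy$allo, m,
                                 on_nonmanifold = "error"), "edge-manifold")
})

test_that("axis is zero at bridgeheads, signed by origin, metric-consistent", {
  model <- fx_model()
  expect_equal(model$axis_mm[model$bridgeheads],
               rep(0, length(model$bridgeheads)))
  expect_true(all(model$origin[model$axis_mm < 0] == "iso"))
  expect_true(all(model$origin[model$axis_mm > 0] == "allo"))
  # triangle inequality on sampled vertex triples
  g <- confluence:::mesh_geodesic_graph(model$inner)
  set.seed(1)
  vs <- sample(n_vertices(model$inner), 12)
  d <- igraph::distances(g, v = vs, to = vs)
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
})

test_that("axis recovers ground-truth arc length on the toy model", {
  model <- fx_model()
  expect_gt(stats::cor(model$axis_mm, model$inner$scalars$gt_axis,
                       method = "spearman"), 0.99)
})

test_that("graph geodesics converge under subdivision on a jittered plane", {
  strip <- flat_strip(16, 8, spacing = 1, jitter = 0.35, seed = 5)
  err <- function(mesh, edge, xs) {
    d <- compute_axis(mesh, sources = edge)
    truth <- xs                     # perpendicular distance to the x=0 line
    max(abs(d[truth > 2] - truth[truth > 2]) / truth[truth > 2])
  }
  mesh1 <- strip$mesh
  e1 <- err(mesh1, strip$edge, mesh1$vertices[, 1])
  sub <- subdivide_mesh(mesh1)
  pe <- attr(sub, "parent_edges")
  edge2 <- which(pe[, 1] %in% strip$edge & pe[, 2] %in% strip$edge)
  e2 <- err(sub, edge2, sub$vertices[, 1])
  expect_lte(e2, e1 + 1e-12)
})

test_that("restriction drops vertices and preserves labels", {
  model <- fx_model()
  full <- restrict_and_label(model, range(model$ap_mm))
  expect_equal(n_vertices(full$inner), n_vertices(model$inner))
  half <- restrict_and_label(model, c(-1, 5))
  expect_true(all(half$ap_mm <= 5))
  # vertex count halves within one row of columns
  expect_lt(abs(n_vertices(half$inner) - n_vertices(model$inner) / 2),
            n_vertices(model$inner) / fx_toy()$spec$n_columns)
  expect_true(all(half$subregion %in% unique(model$subregion)))
  expect_error(restrict_and_label(model, c(99, 100)), "no vertices")
  # dropping all allocortical vertices leaves the axis undefined
  expect_error(restrict_and_label(model, range(model$ap_mm),
                                  labels = "entorhinal"), "allocortical")
})
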