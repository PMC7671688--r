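#' Specification of a synthetic (toy) cortical confluence
#'
#' The toy emulates the mesiotemporal configuration in which a flat-ish
#' isocortical sheet meets an in-rolling allocortical (hippocampal) sheet at
#' the subicular bridgehead seam. The allocortical cross-section is an
#' Archimedean-spiral extrusion in the coronal (x-z) plane, constant along
#' the anterior-posterior (y) direction, so the ground-truth
#' iso-to-allocortical axis is an analytic arc length. With a curl beyond
#' half a turn, part of the isocortical sheet lies geometrically above the
#' allocortical sheet, reproducing the configuration where a conventional
#' isocortical surface skips over the allocortex.
#'
#' @param n_iso_rows,n_allo_rows number of cross-section rows per sheet
#'   (positions along the axis); both at least 2.
#' @param n_columns vertices per row along the anterior-posterior direction
#'   (at least 2).
#' @param curl_turns radians of allocortical in-rolling. Must be at least
#'   `pi`: with less than half a turn no part of the isocortical sheet lies
#'   above the allocortical sheet and the downstream bridging construction is
#'   untestable.
#' @param thickness_mm cortical thickness (inner-outer separation), > 0.
#' @param ap_extent_mm anterior-posterior extent of both sheets, > 0.
#' @param seed integer seed recorded in the spec (the construction itself is
#'   deterministic).
#' @return object of class `toy_confluence_spec`.
#' @export
toy_confluence_spec <- function(n_iso_rows = 20L, n_allo_rows = 28L,
                                n_columns = 24L, curl_turns = 4.5,
                                thickness_mm = 1.5, ap_extent_mm = 10,
                                seed = 1L) {
  stopifnot(n_iso_rows >= 2L, n_allo_rows >= 2L, n_columns >= 2L)
  if (!is.finite(curl_turns) || curl_turns < pi)
    stop("curl_turns = ", format(curl_turns), " rejected: the allocortical ",
         "sheet must in-roll by at least pi radians (half a turn) so that ",
         "part of the isocortical sheet lies above it; without infolding ",
         "the bridgehead construction is untestable")
  if (!(thickness_mm > 0)) stop("thickness_mm must be > 0")
  if (!(ap_extent_mm > 0)) stop("ap_extent_mm must be > 0")
  structure(list(n_iso_rows = as.integer(n_iso_rows),
                 n_allo_rows = as.integer(n_allo_rows),
                 n_columns = as.integer(n_columns),
                 curl_turns = curl_turns, thickness_mm = thickness_mm,
                 ap_extent_mm = ap_extent_mm, seed = as.integer(seed)),
            class = "toy_confluence_spec")
}

## Cross-section geometry constants (mm). The spiral starts at the seam
## (top of the hippocampal curl) and rolls clockwise-inward; the isocortical
## segment approaches the seam from lateral (x < 0) with a slight downward
## tilt so that candidates inferior to the bridgeheads exist.
.toy_geom <- list(R0 = 8, shrink = 0.65, L_iso = 12, tilt = 0.08,
                  gap_x = 1.3, gap_z = 2.25)

## Dense parametric cross-section: s = signed arc length (0 at bridgehead
## row, negative on the isocortical side, including the bridge hop), with
## position (x, z) and unit normal (nx, nz) pointing to the inner side.
.toy_cross_section <- function(spec, n_dense = 4000L) {
  g <- .toy_geom
  ## allocortical spiral, theta in [0, curl]
  th <- seq(0, spec$curl_turns, length.out = n_dense)
  r <- g$R0 * (1 - g$shrink * th / spec$curl_turns)
  phi <- pi / 2 - th
  x <- r * cos(phi); z <- r * sin(phi)
  dr <- -g$R0 * g$shrink / spec$curl_turns
  ## d/dtheta of position
  dx <- dr * cos(phi) + r * sin(phi)
  dz <- dr * sin(phi) - r * cos(phi)
  sp <- sqrt(dx^2 + dz^2)
  s_allo <- c(0, cumsum((sp[-1] + sp[-n_dense]) / 2 * diff(th)))
  ## outward (inner-surface) normal: radial direction, corrected for spiral
  ## pitch via rotation of the unit tangent by -90 degrees
  tx <- dx / sp; tz <- dz / sp
  nx <- -tz; nz <- tx
  ## orient outward (away from origin)
  flip <- (nx * x + nz * z) < 0
  nx[flip] <- -nx[flip]; nz[flip] <- -nz[flip]
  allo <- data.frame(s = s_allo, x = x, z = z, nx = nx, nz = nz,
                     part = "allo")
  ## isocortical straight segment; seam end at (-gap_x, R0 - gap_z)
  hop <- sqrt(g$gap_x^2 + g$gap_z^2)
  u <- seq(0, g$L_iso, length.out = n_dense)   # 0 at seam end
  dirx <- -cos(g$tilt); dirz <- -sin(g$tilt)
  ix <- -g$gap_x + u * dirx
  iz <- g$R0 - g$gap_z + u * dirz
  iso <- data.frame(s = -(hop + u), x = ix, z = iz,
                    nx = -sin(g$tilt), nz = cos(g$tilt), part = "iso")
  rbind(iso[rev(seq_len(n_dense)), ], allo)
}

.strip_triangles <- function(n_rows, n_cols) {
  vid <- function(r, c) (r - 1L) * n_cols + c
  tris <- vector("list", (n_rows - 1L) * (n_cols - 1L))
  k <- 0L
  for (r in seq_len(n_rows - 1L)) {
    for (c in seq_len(n_cols - 1L)) {
      k <- k + 1L
      tris[[k]] <- rbind(c(vid(r, c), vid(r + 1L, c), vid(r, c + 1L)),
                         c(vid(r, c + 1L), vid(r + 1L, c), vid(r + 1L, c + 1L)))
    }
  }
  do.call(rbind, tris)
}

#' Generate a synthetic confluent mesh pair with known ground truth
#'
#' Produces an isocortical pial/white surface pair (labelled entorhinal /
#' parahippocampal / fusiform by distance from the seam) and an allocortical
#' inner/outer pair carrying the internal anterior-posterior, proximal-distal
#' and inner-outer coordinates, plus the ground-truth iso-to-allocortical
#' axis (arc length along the sheet, negative on the isocortical side of the
#' seam). The seam row is flagged: the first allocortical row are the true
#' bridgeheads and the last isocortical row their true matches.
#'
#' @param spec a [toy_confluence_spec()]
#' @return list with elements `iso` (list `pial`, `white`), `allo` (list
#'   `inner`, `outer`), `spec`, and `cross_section` (dense parametric
#'   cross-section used by [make_intensity_volume()]). Ground truth is in the
#'   mesh scalars: `gt_axis` (mm), `seam` (flag), plus labels/coordinates.
#' @export
make_toy_confluence <- function(spec) {
  if (!inherits(spec, "toy_confluence_spec"))
    spec <- do.call(toy_confluence_spec, spec)
  g <- .toy_geom
  cs <- .toy_cross_section(spec)
  ycols <- seq(0, spec$ap_extent_mm, length.out = spec$n_columns)
  t2 <- spec$thickness_mm / 2

  build_sheet <- function(rows_s, extra_scalars = list()) {
    ## rows_s: data.frame rows of the dense cross-section at row positions
    nr <- nrow(rows_s); nc <- spec$n_columns
    rep_rows <- rows_s[rep(seq_len(nr), each = nc), ]
    y <- rep(ycols, times = nr)
    inner <- cbind(rep_rows$x + t2 * rep_rows$nx, y,
                   rep_rows$z + t2 * rep_rows$nz)
    outer <- cbind(rep_rows$x - t2 * rep_rows$nx, y,
                   rep_rows$z - t2 * rep_rows$nz)
    tris <- .strip_triangles(nr, nc)
    sc <- c(list(gt_axis = rep_rows$s, ap = y), extra_scalars)
    list(inner = inner, outer = outer, tris = tris, scalars = sc)
  }

  ## row positions: interpolate dense cross-section at target arc lengths
  interp_rows <- function(target_s) {
    out <- data.frame(s = target_s,
                      x = stats::approx(cs$s, cs$x, target_s)$y,
                      z = stats::approx(cs$s, cs$z, target_s)$y,
                      nx = stats::approx(cs$s, cs$nx, target_s)$y,
                      nz = stats::approx(cs$s, cs$nz, target_s)$y)
    nrm <- sqrt(out$nx^2 + out$nz^2)
    out$nx <- out$nx / nrm; out$nz <- out$nz / nrm
    out
  }

  hop <- sqrt(g$gap_x^2 + g$gap_z^2)
  s_iso <- -(hop + seq(g$L_iso, 0, length.out = spec$n_iso_rows))
  s_allo <- seq(0, max(cs$s), length.out = spec$n_allo_rows)

  iso_rows <- interp_rows(s_iso)
  allo_rows <- interp_rows(s_allo)

  ## isocortical region labels by thirds of distance from the seam
  d_seam <- abs(s_iso + hop)
  lab_row <- cut(d_seam, breaks = stats::quantile(d_seam, c(0, 1/3, 2/3, 1)),
                 labels = c("entorhinal", "parahippocampal", "fusiform"),
                 include.lowest = TRUE)
  iso_lab <- rep(as.character(lab_row), each = spec$n_columns)
  iso_seam <- rep(seq_len(spec$n_iso_rows) == spec$n_iso_rows,
                  each = spec$n_columns)
  iso <- build_sheet(iso_rows,
                     extra_scalars = list(region = iso_lab, seam = iso_seam))

  ## allocortical subfield labels along the proximal-distal coordinate
  fr <- s_allo / max(s_allo)
  sub_row <- cut(fr, breaks = c(-Inf, 0.25, 0.55, 0.65, 0.8, Inf),
                 labels = c("subiculum", "CA1", "CA2", "CA3", "CA4"))
  allo_lab <- rep(as.character(sub_row), each = spec$n_columns)
  allo_seam <- rep(seq_len(spec$n_allo_rows) == 1L, each = spec$n_columns)
  pd <- rep(s_allo, each = spec$n_columns)
  allo <- build_sheet(allo_rows,
                      extra_scalars = list(subregion = allo_lab,
                                           seam = allo_seam,
                                           proximal_distal = pd))

  mesh_of <- function(sheet, which, io_value) {
    sc <- sheet$scalars
    sc$inner_outer <- rep(io_value, nrow(sheet[[which]]))
    surface_mesh(sheet[[which]], sheet$tris, sc, validate = FALSE)
  }
  out <- list(
    iso = list(pial = mesh_of(iso, "inner", 0),
               white = mesh_of(iso, "outer", 1)),
    allo = list(inner = mesh_of(allo, "inner", 0),
                outer = mesh_of(allo, "outer", 1)),
    spec = spec,
    cross_section = cs)
  class(out) <- "toy_confluence"
  out
}

#' @export
print.toy_confluence <- function(x, ...) {
  cat("toy_confluence:", n_vertices(x$iso$pial), "isocortical +",
      n_vertices(x$allo$inner), "allocortical vertices per surface\n")
  invisible(x)
}
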