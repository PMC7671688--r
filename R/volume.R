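#' Scalar volume with RAS affine
#'
#' Minimal 3D/4D image container: a numeric array plus a 4 x 4 voxel-to-world
#' affine. The affine maps 0-based voxel indices to world (RAS, mm)
#' coordinates, matching the NIfTI convention; R-side indexing is 1-based.
#'
#' @param data 3D (or 4D, with time last) numeric array
#' @param affine 4 x 4 voxel-to-world matrix
#' @return object of class `volume`
#' @export
volume <- function(data, affine = diag(4)) {
  stopifnot(length(dim(data)) %in% c(3L, 4L),
            all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, affine = affine), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("volume:", paste(dim(x$data), collapse = " x "),
      "| voxel", paste(signif(diag(x$affine)[1:3], 3), collapse = " x "),
      "mm\n")
  invisible(x)
}

## world (n x 3) -> continuous 0-based voxel coordinates (n x 3)
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind(t(as.matrix(xyz)), 1)
  t(solve(vol$affine) %*% xyz)[, 1:3, drop = FALSE]
}

## 0-based voxel coordinates -> world
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind(t(as.matrix(ijk)), 1)
  t(vol$affine %*% ijk)[, 1:3, drop = FALSE]
}

#' Trilinear interpolation of a 3D volume at world coordinates
#'
#' @param vol a 3D [volume()]
#' @param xyz n x 3 matrix of world coordinates (mm)
#' @return numeric vector of interpolated values
#' @details Errors if any point falls outside the volume bounds; the error
#'   names the offending point indices.
#' @export
sample_volume <- function(vol, xyz) {
  stopifnot(length(dim(vol$data)) == 3L)
  v <- world_to_voxel(vol, xyz)
  dm <- dim(vol$data)
  bad <- which(v[, 1] < 0 | v[, 1] > dm[1] - 1 |
               v[, 2] < 0 | v[, 2] > dm[2] - 1 |
               v[, 3] < 0 | v[, 3] > dm[3] - 1)
  if (length(bad))
    stop("sample points outside volume bounds: indices ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  i0 <- pmin(floor(v[, 1]), dm[1] - 2); fx <- v[, 1] - i0
  j0 <- pmin(floor(v[, 2]), dm[2] - 2); fy <- v[, 2] - j0
  k0 <- pmin(floor(v[, 3]), dm[3] - 2); fz <- v[, 3] - k0
  at <- function(di, dj, dk)
    vol$data[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
              fy       * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
  fz       * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
              fy       * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
}
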