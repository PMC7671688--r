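## Minimal neuroimaging I/O. No NIfTI/GIFTI package is available in the
## supported environment, so the package carries its own small readers and
## writers: NIfTI-1 (.nii / .nii.gz, float32 data, sform affine), GIFTI
## (ASCII-encoded DataArrays), ASCII PLY, and TSV with header row.

.nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume as NIfTI-1
#'
#' Float32 data, sform affine (code 1), single file `.nii` or `.nii.gz`.
#'
#' @param vol a [volume()] (3D or 4D)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_nifti <- function(vol, path) {
  dm <- dim(vol$data)
  nd <- length(dm)
  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  w <- function(x, size, what = "integer") writeBin(x, con, size = size,
                                                   endian = "little")
  pad <- function(n) writeBin(raw(n), con)
  w(348L, 4L)                                   # sizeof_hdr
  pad(36L)                                      # data_type..dim_info
  w(as.integer(c(nd, dm, rep(1L, 7L - nd))), 2L)  # dim[8]
  w(c(0, 0, 0), 4L); writeBin(raw(2), con)      # intent_p1..3, intent_code
  w(c(16L, 32L, 0L), 2L)                        # datatype float32, bitpix
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  w(c(1, vox, rep(1, 7 - length(vox) - 1), 0)[1:8], 4L)  # pixdim[8]
  w(352, 4L); w(1, 4L); w(0, 4L)                # vox_offset, scl_slope/inter
  w(0L, 2L); writeBin(raw(2), con)              # slice_end, slice_code+units
  w(c(0, 0, 0, 0), 4L)                          # cal_max..toffset
  w(c(0L, 0L), 4L)                              # glmax/glmin
  pad(80L + 24L)                                # descrip, aux_file
  w(c(0L, 1L), 2L)                              # qform_code=0, sform_code=1
  w(rep(0, 6), 4L)                              # quatern/qoffset
  w(as.numeric(t(vol$affine[1:3, ])), 4L)       # srow_x/y/z
  pad(16L)                                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#' @param path `.nii` or `.nii.gz` file
#' @return a [volume()]
#' @export
read_nifti <- function(path) {
  con <- .nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  rd <- function(off, n, what, size) readBin(hdr[(off + 1):(off + n * size)],
                                             what, n = n, size = size,
                                             endian = "little")
  if (rd(0, 1, "integer", 4) != 348L) stop("not a NIfTI-1 file: ", path)
  dim8 <- rd(40, 8, "integer", 2)
  nd <- dim8[1]
  dm <- dim8[2:(1 + nd)]
  datatype <- rd(70, 1, "integer", 2)
  vox_offset <- rd(108, 1, "numeric", 4)
  sform <- rd(254, 1, "integer", 2)
  srow <- matrix(rd(280, 12, "numeric", 4), 3, 4, byrow = TRUE)
  aff <- rbind(srow, c(0, 0, 0, 1))
  if (sform == 0) {
    pixdim <- rd(76, 8, "numeric", 4)
    aff <- diag(c(pixdim[2:4], 1))
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dm)
  data <- switch(as.character(datatype),
                 "2" = as.numeric(readBin(con, "integer", n, size = 1L,
                                          signed = FALSE)),
                 "4" = as.numeric(readBin(con, "integer", n, size = 2L,
                                          endian = "little")),
                 "8" = as.numeric(readBin(con, "integer", n, size = 4L,
                                          endian = "little")),
                 "16" = readBin(con, "numeric", n, size = 4L,
                                endian = "little"),
                 "64" = readBin(con, "numeric", n, size = 8L,
                                endian = "little"),
                 stop("unsupported NIfTI datatype ", datatype))
  volume(array(data, dim = dm), aff)
}

.gifti_data_array <- function(values, intent, dims, datatype) {
  paste0('<DataArray Intent="', intent, '" DataType="', datatype,
         '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="',
         length(dims), '" ',
         paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
               collapse = " "),
         ' Encoding="ASCII" Endian="LittleEndian"><Data>',
         paste(values, collapse = " "), "</Data></DataArray>")
}

#' Write a surface mesh as GIFTI
#'
#' ASCII-encoded POINTSET + TRIANGLE arrays (0-based indices).
#'
#' @param mesh a `surface_mesh`
#' @param path output `.surf.gii` path
#' @return `path`, invisibly
#' @export
write_gifti_surface <- function(mesh, path) {
  v <- .gifti_data_array(format(as.vector(t(mesh$vertices)), digits = 9,
                                trim = TRUE, scientific = FALSE),
                         "NIFTI_INTENT_POINTSET",
                         c(nrow(mesh$vertices), 3L), "NIFTI_TYPE_FLOAT32")
  tr <- .gifti_data_array(as.vector(t(mesh$triangles)) - 1L,
                          "NIFTI_INTENT_TRIANGLE",
                          c(nrow(mesh$triangles), 3L), "NIFTI_TYPE_INT32")
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="2">', v, tr,
                "</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

.gifti_read_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  lapply(xml2::xml_find_all(doc, ".//DataArray"), function(da) {
    dims <- as.integer(vapply(seq_len(
      as.integer(xml2::xml_attr(da, "Dimensionality"))) - 1L,
      function(d) xml2::xml_attr(da, paste0("Dim", d)), character(1)))
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                 quiet = TRUE)
    list(intent = xml2::xml_attr(da, "Intent"), dims = dims, values = vals)
  })
}

#' Read a GIFTI surface written by [write_gifti_surface()]
#' @param path `.surf.gii` file
#' @return a `surface_mesh`
#' @export
read_gifti_surface <- function(path) {
  arrs <- .gifti_read_arrays(path)
  pts <- NULL; tri <- NULL
  for (a in arrs) {
    if (a$intent == "NIFTI_INTENT_POINTSET")
      pts <- matrix(a$values, ncol = 3L, byrow = TRUE)
    if (a$intent == "NIFTI_INTENT_TRIANGLE")
      tri <- matrix(as.integer(a$values), ncol = 3L, byrow = TRUE) + 1L
  }
  if (is.null(pts) || is.null(tri)) stop("no POINTSET/TRIANGLE arrays in ", path)
  surface_mesh(pts, tri, validate = FALSE)
}

#' Write a per-vertex metric (func) GIFTI file
#' @param values numeric vector
#' @param path output `.func.gii` path
#' @return `path`, invisibly
#' @export
write_gifti_metric <- function(values, path) {
  a <- .gifti_data_array(format(values, digits = 9, trim = TRUE),
                         "NIFTI_INTENT_NONE", length(values),
                         "NIFTI_TYPE_FLOAT32")
  writeLines(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                    '<GIFTI Version="1.0" NumberOfDataArrays="1">', a,
                    "</GIFTI>\n"), path)
  invisible(path)
}

#' Read a metric GIFTI file
#' @param path `.func.gii` file
#' @return numeric vector
#' @export
read_gifti_metric <- function(path) {
  .gifti_read_arrays(path)[[1L]]$values
}

#' Write a per-vertex label GIFTI file
#' @param labels character (or factor) vector
#' @param path output `.label.gii` path
#' @return `path`, invisibly
#' @export
write_gifti_label <- function(labels, path) {
  labels <- as.character(labels)
  levs <- sort(unique(labels))
  codes <- match(labels, levs)
  lt <- paste0("<LabelTable>",
               paste(sprintf('<Label Key="%d">%s</Label>', seq_along(levs),
                             levs), collapse = ""),
               "</LabelTable>")
  a <- .gifti_data_array(codes, "NIFTI_INTENT_LABEL", length(codes),
                         "NIFTI_TYPE_INT32")
  writeLines(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                    '<GIFTI Version="1.0" NumberOfDataArrays="1">', lt, a,
                    "</GIFTI>\n"), path)
  invisible(path)
}

#' Read a label GIFTI file
#' @param path `.label.gii` file
#' @return character vector of labels
#' @export
read_gifti_label <- function(path) {
  doc <- xml2::read_xml(path)
  keys <- as.integer(xml2::xml_attr(
    xml2::xml_find_all(doc, ".//LabelTable/Label"), "Key"))
  names <- xml2::xml_text(xml2::xml_find_all(doc, ".//LabelTable/Label"))
  codes <- as.integer(.gifti_read_arrays(path)[[1L]]$values)
  names[match(codes, keys)]
}

#' Write a mesh as ASCII PLY
#' @param mesh a `surface_mesh`
#' @param path output `.ply` path
#' @return `path`, invisibly
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path `.ply` file
#' @return a `surface_mesh`
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1L]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1L]))
  verts <- do.call(rbind, lapply(lines[(endh + 1):(endh + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]][1:3])))
  faces <- do.call(rbind, lapply(lines[(endh + nv + 1):(endh + nv + nf)],
                                 function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1L]])
    x[2:4] + 1L
  }))
  surface_mesh(verts, faces, validate = FALSE)
}

#' Write a data frame as TSV with header row
#' @param df data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSV with header row
#' @param path input path
#' @return data frame
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a plain-text key=value manifest
#' @param entries named list/vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest <- function(entries, path) {
  writeLines(paste0(names(entries), "=",
                    vapply(entries, function(x) paste(format(x), collapse = ","),
                           character(1))), path)
  invisible(path)
}

#' Read a key=value manifest
#' @param path input path
#' @return named character vector
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                         character(1)),
                  vapply(kv, `[[`, character(1), 1L))
}

#' Serialise a confluence model as a directory
#'
#' Writes `inner.surf.gii`, `outer.surf.gii`, `axis.func.gii`,
#' `ap.func.gii`, `subregion.label.gii`, `bridgeheads.tsv` and
#' `manifest.txt`.
#'
#' @param model a `confluence_model`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_confluence_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gifti_surface(model$inner, file.path(dir, "inner.surf.gii"))
  write_gifti_surface(model$outer, file.path(dir, "outer.surf.gii"))
  if (!is.null(model$axis_mm))
    write_gifti_metric(model$axis_mm, file.path(dir, "axis.func.gii"))
  write_gifti_metric(model$ap_mm, file.path(dir, "ap.func.gii"))
  write_gifti_label(model$subregion, file.path(dir, "subregion.label.gii"))
  write_tsv(data.frame(bridgehead = model$bridgeheads),
            file.path(dir, "bridgeheads.tsv"))
  write_gifti_label(model$origin, file.path(dir, "origin.label.gii"))
  write_manifest(list(n_vertices = n_vertices(model$inner),
                      n_bridgeheads = length(model$bridgeheads)),
                 file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a confluence model directory written by [write_confluence_model()]
#' @param dir model directory
#' @return a `confluence_model`
#' @export
read_confluence_model <- function(dir) {
  inner <- read_gifti_surface(file.path(dir, "inner.surf.gii"))
  outer <- read_gifti_surface(file.path(dir, "outer.surf.gii"))
  ap <- read_gifti_metric(file.path(dir, "ap.func.gii"))
  subregion <- read_gifti_label(file.path(dir, "subregion.label.gii"))
  origin <- read_gifti_label(file.path(dir, "origin.label.gii"))
  axis_path <- file.path(dir, "axis.func.gii")
  axis <- if (file.exists(axis_path)) read_gifti_metric(axis_path) else NULL
  bh <- read_tsv(file.path(dir, "bridgeheads.tsv"))$bridgehead
  inner$scalars <- list(origin = origin, ap = ap, subregion = subregion,
                        axis_mm = axis)
  outer$scalars <- inner$scalars
  structure(list(inner = inner, outer = outer, bridgeheads = bh,
                 origin = origin, ap_mm = ap, subregion = subregion,
                 allo_index = NULL, iso_index = NULL, axis_mm = axis),
            class = "confluence_model")
}

#' Write a profile matrix (with metadata and moments) as TSV
#' @param profiles a [profile_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_profile_tsv <- function(profiles, path) {
  mom <- suppressWarnings(central_moments(profiles))
  df <- cbind(data.frame(vertex = seq_len(nrow(profiles$intensities))),
              profiles$meta, as.data.frame(profiles$intensities), mom)
  write_tsv(df, path)
}
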