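## Image file I/O: NIfTI-1 (.nii/.nii.gz) through RNifti, MetaImage
## (.mha/.mhd) through a minimal reader/writer for the text-header dialect.

vx_format_of_path <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii\\.gz$", lp) || grepl("\\.nii$", lp)) return("nifti")
  if (grepl("\\.mha$", lp)) return("mha")
  if (grepl("\\.mhd$", lp)) return("mhd")
  vx_stop("vx_format_error",
          sprintf("unsupported image extension in '%s' (expected .nii, .nii.gz, .mha or .mhd)", path))
}

#' Read and write images with physical geometry
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`
#' single-file, `.mhd` header + `.raw`). Geometry (origin, spacing, direction)
#' round-trips through both formats; MetaImage raw storage round-trips pixel
#' data bit-exactly when written as `double`.
#'
#' NIfTI orientation is taken from the sform when present (qform otherwise);
#' on write the sform is set. NIfTI's world frame flips the sign of the first
#' two axes (LPS vs RAS) relative to the MetaImage/ITK convention used
#' internally; the flip is applied symmetrically on read and write so that a
#' `.nii` and an `.mha` written from one in-memory image agree.
#'
#' @param path File path; the extension selects the format.
#' @param image A `vximage`.
#' @param labels Logical: read as a [vx_label_image()]?
#' @param dtype Storage type for writing: `"double"`, `"float"`, or for label
#'   images `"int"`.
#' @return `vx_read_image()` returns a `vximage`; `vx_write_image()` returns
#'   `path` invisibly.
#' @export
vx_read_image <- function(path, labels = FALSE) {
  fmt <- vx_format_of_path(path)   # unrecognized extension first: format error
  if (!file.exists(path))
    vx_stop("vx_io_error", sprintf("file not found: '%s'", path))
  img <- if (fmt == "nifti") vx_read_nifti(path) else vx_read_metaimage(path)
  if (labels)
    vx_label_image(img$data, img$origin, img$spacing, img$direction)
  else img
}

#' @rdname vx_read_image
#' @export
vx_write_image <- function(image, path, dtype = "double") {
  stopifnot(inherits(image, "vximage"))
  fmt <- vx_format_of_path(path)
  if (fmt == "nifti") vx_write_nifti(image, path, dtype)
  else vx_write_metaimage(image, path, dtype, single_file = (fmt == "mha"))
  invisible(path)
}

## NIfTI ---------------------------------------------------------------------

# RAS (NIfTI) <-> LPS (internal/ITK) axis flip for the world frame.
vx_nii_flip <- function(d) diag(c(-1, -1, 1)[seq_len(d)], d)

vx_read_nifti <- function(path) {
  nii <- RNifti::readNifti(path, internal = FALSE)
  data <- as.array(nii)
  d <- length(dim(data))
  if (!d %in% c(2L, 3L))
    vx_stop("vx_format_error", "only 2-d and 3-d NIfTI images are supported")
  xf <- RNifti::xform(nii, useQuaternionFirst = FALSE)   # sform preferred
  A <- xf[seq_len(d), seq_len(d), drop = FALSE]
  origin_ras <- xf[seq_len(d), 4]
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0))
    vx_stop("vx_corrupt_error", sprintf("non-positive spacing in '%s'", path))
  direction <- sweep(A, 2, spacing, "/")
  F <- vx_nii_flip(d)
  vx_image(data, origin = as.double(F %*% origin_ras), spacing = spacing,
           direction = F %*% direction)
}

vx_write_nifti <- function(image, path, dtype = "double") {
  d <- vx_dim(image)
  data <- image$data
  if (dtype == "float") data <- vx_to_float32(data)
  F <- vx_nii_flip(d)
  A3 <- diag(3); A3[seq_len(d), seq_len(d)] <-
    (F %*% image$direction) %*% diag(image$spacing, d)
  org3 <- rep(0, 3); org3[seq_len(d)] <- as.double(F %*% image$origin)
  xf <- rbind(cbind(A3, org3), c(0, 0, 0, 1))
  dimnames(xf) <- NULL
  datatype <- switch(dtype, double = "double", float = "float",
                     int = "int32",
                     vx_stop("vx_format_error", "unsupported dtype"))
  nii <- RNifti::asNifti(data, datatype = datatype)
  nii <- RNifti::`sform<-`(nii, structure(xf, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(xf, code = 1L))
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}

## MetaImage -----------------------------------------------------------------

vx_met_type <- function(dtype) {
  switch(dtype, double = "MET_DOUBLE", float = "MET_FLOAT",
         int = "MET_INT", short = "MET_SHORT", uchar = "MET_UCHAR",
         vx_stop("vx_format_error", sprintf("unsupported dtype '%s'", dtype)))
}

vx_write_metaimage <- function(image, path, dtype = "double",
                               single_file = TRUE, ncomponents = 1L,
                               data_override = NULL) {
  d <- vx_dim(image)
  data <- if (is.null(data_override)) image$data else data_override
  hdr <- c(
    "ObjectType = Image",
    sprintf("NDims = %d", d),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(format(as.vector(t(image$direction)), digits = 17), collapse = " ")),
    sprintf("Offset = %s", paste(format(image$origin, digits = 17), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(image$spacing, digits = 17), collapse = " ")),
    sprintf("DimSize = %s", paste(vx_shape(image), collapse = " ")))
  if (ncomponents > 1L)
    hdr <- c(hdr, sprintf("ElementNumberOfChannels = %d", ncomponents))
  hdr <- c(hdr, sprintf("ElementType = %s", vx_met_type(dtype)))
  vec <- as.vector(data)
  size <- switch(dtype, double = 8L, float = 4L, int = 4L, short = 2L, uchar = 1L)
  if (dtype %in% c("int", "short", "uchar")) vec <- as.integer(round(vec))
  if (single_file) {
    hdr <- c(hdr, "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(vec, con, size = size, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c(hdr, sprintf("ElementDataFile = %s", rawname))
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(vec, con, size = size, endian = "little")
  }
  invisible(path)
}

vx_read_metaimage_header <- function(path) {
  # Header lines are "Key = value"; data may follow ElementDataFile = LOCAL
  # in the same file. Read line-wise in binary mode to find the data offset.
  con <- file(path, "rb")
  on.exit(close(con))
  keys <- list(); offset <- 0L
  repeat {
    line <- character(0); bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0) break
      offset <- offset + 1L
      if (b == as.raw(0x0a)) break
      bytes <- c(bytes, b)
    }
    if (length(bytes) == 0 && length(b) == 0) break
    line <- rawToChar(bytes[bytes != as.raw(0x0d)])
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(m) == 3) keys[[m[2]]] <- m[3]
    if (identical(keys[["ElementDataFile"]], "LOCAL")) break
    if (!is.null(keys[["ElementDataFile"]])) break
  }
  list(keys = keys, data_offset = offset)
}

vx_read_metaimage <- function(path) {
  h <- vx_read_metaimage_header(path)
  k <- h$keys
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(k)))
    vx_stop("vx_corrupt_error", sprintf("MetaImage header of '%s' is incomplete", path))
  d <- as.integer(k$NDims)
  shape <- as.integer(strsplit(k$DimSize, "\\s+")[[1]])
  if (length(shape) != d)
    vx_stop("vx_corrupt_error", "DimSize does not match NDims")
  ncomp <- if (!is.null(k$ElementNumberOfChannels))
    as.integer(k$ElementNumberOfChannels) else 1L
  spacing <- if (!is.null(k$ElementSpacing))
    as.double(strsplit(k$ElementSpacing, "\\s+")[[1]]) else rep(1, d)
  origin <- if (!is.null(k$Offset))
    as.double(strsplit(k$Offset, "\\s+")[[1]]) else rep(0, d)
  direction <- if (!is.null(k$TransformMatrix))
    matrix(as.double(strsplit(k$TransformMatrix, "\\s+")[[1]]), d, d, byrow = TRUE)
  else diag(d)
  type <- k$ElementType
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_INT = 4L,
                 MET_UINT = 4L, MET_SHORT = 2L, MET_USHORT = 2L,
                 MET_UCHAR = 1L, MET_CHAR = 1L,
                 vx_stop("vx_format_error", sprintf("unsupported ElementType %s", type)))
  what <- if (type %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  n <- prod(shape) * ncomp
  if (identical(k$ElementDataFile, "LOCAL")) {
    con <- file(path, "rb"); on.exit(close(con))
    seek(con, h$data_offset)
    vec <- readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  } else {
    rawpath <- file.path(dirname(path), k$ElementDataFile)
    if (!file.exists(rawpath))
      vx_stop("vx_io_error", sprintf("MetaImage data file not found: '%s'", rawpath))
    con <- file(rawpath, "rb"); on.exit(close(con))
    vec <- readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  }
  if (length(vec) != n)
    vx_stop("vx_corrupt_error",
            sprintf("'%s': expected %d elements, read %d", path, n, length(vec)))
  if (ncomp == 1L) {
    vx_image(array(as.double(vec), shape), origin, spacing, direction)
  } else {
    # vector-valued (e.g. displacement field): fastest-varying is the channel
    arr <- array(as.double(vec), c(ncomp, shape))
    perm <- c(seq_len(d) + 1L, 1L)
    structure(list(data = aperm(arr, perm), origin = origin, spacing = spacing,
                   direction = direction, domain_id = NULL,
                   ncomponents = ncomp),
              class = "vxvectorimage")
  }
}

## Displacement-field (vector MetaImage) serialization ------------------------

#' Read or write a dense displacement field as a vector-valued MetaImage
#'
#' The field is stored channel-fastest (`d` components per voxel, in mm).
#'
#' @param field Array of shape `c(shape, d)` holding per-voxel displacement.
#' @param geometry The `vxgeometry` the field is sampled on.
#' @param path Output `.mha` path.
#' @return `vx_read_field()` returns a list with `field` and `geometry`.
#' @export
vx_write_field <- function(field, geometry, path) {
  d <- length(geometry$shape)
  stopifnot(length(dim(field)) == d + 1L, dim(field)[d + 1L] == d)
  carrier <- vx_image(array(0, geometry$shape), geometry$origin,
                      geometry$spacing, geometry$direction)
  perm <- c(d + 1L, seq_len(d))
  vx_write_metaimage(carrier, path, dtype = "double", single_file = TRUE,
                     ncomponents = d, data_override = aperm(field, perm))
  invisible(path)
}

#' @rdname vx_write_field
#' @export
vx_read_field <- function(path) {
  v <- vx_read_metaimage(path)
  if (!inherits(v, "vxvectorimage"))
    vx_stop("vx_format_error", "not a vector-valued MetaImage")
  d <- length(v$spacing)
  list(field = v$data,
       geometry = vx_geometry(dim(v$data)[seq_len(d)], v$origin, v$spacing,
                              v$direction))
}
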