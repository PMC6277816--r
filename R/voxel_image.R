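#' Voxel image container
#'
#' A 3-D scalar intensity grid with physical voxel spacing and origin, the
#' input of the segmentation stage (Hounsfield-unit-like intensities from a
#' contrast-enhanced cardiac CT, or synthetic phantom intensities).
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing numeric length-3, physical voxel size per axis (mm), all
#'   strictly positive.
#' @param origin numeric length-3, physical coordinate of the center of voxel
#'   (1,1,1) (mm).
#' @return an object of class `voxel_image` with fields `data`, `spacing`,
#'   `origin`.
#' @export
voxel_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stopf("voxel_image: data must have 3 axes")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("voxel_image: spacing must be 3 strictly positive values")
  if (length(origin) != 3L) stopf("voxel_image: origin must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("voxel_image %s, spacing (%g, %g, %g) mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical coordinates of voxel centers
#'
#' @param img a [voxel_image()]
#' @param idx integer matrix (n x 3) of 1-based voxel indices
#' @return n x 3 matrix of physical coordinates (mm)
#' @export
voxel_to_physical <- function(img, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, img$spacing, `*`), 2, img$origin, `+`)
}

#' Voxel indices nearest to physical coordinates
#' @inheritParams voxel_to_physical
#' @param xyz n x 3 matrix of physical coordinates (mm)
#' @return integer n x 3 matrix of 1-based indices (not clipped)
#' @export
physical_to_voxel <- function(img, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  idx <- sweep(sweep(xyz, 2, img$origin, `-`), 2, img$spacing, `/`) + 1
  matrix(as.integer(round(idx)), ncol = 3)
}

# ---------------------------------------------------------------------------
# MetaImage (.mha / .mhd + .raw) I/O, uncompressed.  The header is plain text
# "Key = Value" lines; the voxel block is raw little-endian binary.  Only the
# keys this package writes are honored on read; others are ignored.

.mha_types <- c(MET_FLOAT = "float", MET_DOUBLE = "double",
                MET_SHORT = "short", MET_UCHAR = "uchar", MET_INT = "int")

#' Read a MetaImage volume
#'
#' Supports uncompressed `.mha` (header + inline raw data) and `.mhd`
#' (header referencing an external `.raw` file), `MET_FLOAT`, `MET_DOUBLE`,
#' `MET_SHORT`, `MET_INT` and `MET_UCHAR` element types, little-endian.
#'
#' @param path file path
#' @return a [voxel_image()]
#' @export
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); local_data <- FALSE
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stopf("read_metaimage: truncated header in %s", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stopf("read_metaimage: malformed header line '%s'", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") { local_data <- identical(val, "LOCAL"); break }
  }
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (length(dims) != 3L) stopf("read_metaimage: only 3-D volumes supported")
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  etype <- hdr[["ElementType"]] %||% "MET_FLOAT"
  n <- prod(dims)
  read_block <- function(src) {
    switch(etype,
      MET_FLOAT  = readBin(src, "numeric", n, size = 4, endian = "little"),
      MET_DOUBLE = readBin(src, "numeric", n, size = 8, endian = "little"),
      MET_SHORT  = readBin(src, "integer", n, size = 2, signed = TRUE, endian = "little"),
      MET_INT    = readBin(src, "integer", n, size = 4, endian = "little"),
      MET_UCHAR  = as.integer(readBin(src, "raw", n)),
      stopf("read_metaimage: unsupported ElementType %s", etype))
  }
  if (local_data) {
    vals <- read_block(con)
  } else {
    raw_path <- file.path(dirname(path), hdr[["ElementDataFile"]])
    con2 <- file(raw_path, "rb"); on.exit(close(con2), add = TRUE)
    vals <- read_block(con2)
  }
  if (length(vals) != n) stopf("read_metaimage: expected %d voxels, got %d", n, length(vals))
  voxel_image(array(as.numeric(vals), dim = dims), spacing, origin)
}

#' Write a MetaImage volume
#'
#' @param img a [voxel_image()]
#' @param path output `.mha` path (header + inline raw block) or `.mhd`
#'   (paired `.raw` written alongside)
#' @param element_type one of `"MET_FLOAT"`, `"MET_DOUBLE"`, `"MET_SHORT"`
#' @return `path`, invisibly
#' @export
write_metaimage <- function(img, path, element_type = "MET_FLOAT") {
  stopifnot(inherits(img, "voxel_image"))
  dims <- dim(img$data)
  mhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  data_file <- if (mhd) sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE) else "LOCAL"
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
           sprintf("ElementSpacing = %g %g %g", img$spacing[1], img$spacing[2], img$spacing[3]),
           sprintf("Offset = %g %g %g", img$origin[1], img$origin[2], img$origin[3]),
           sprintf("ElementType = %s", element_type),
           sprintf("ElementDataFile = %s", data_file))
  write_block <- function(con) {
    v <- as.vector(img$data)
    switch(element_type,
      MET_FLOAT  = writeBin(as.numeric(v), con, size = 4, endian = "little"),
      MET_DOUBLE = writeBin(as.numeric(v), con, size = 8, endian = "little"),
      MET_SHORT  = writeBin(as.integer(round(v)), con, size = 2, endian = "little"),
      stopf("write_metaimage: unsupported ElementType %s", element_type))
  }
  con <- file(path, "wb"); on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  if (mhd) {
    con2 <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(con2), add = TRUE)
    write_block(con2)
  } else {
    write_block(con)
  }
  invisible(path)
}
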