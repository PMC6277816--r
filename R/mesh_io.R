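# Mesh readers/writers: CARP (.pts/.elem/.lon) and VTK legacy ASCII.
#
# CARP dialect fixed by this package: .pts holds a count line then three
# whitespace-separated coordinates per line in mm (units = "um" converts on
# read); .elem holds a count line then "Tr n1 n2 n3 tag" / "Tt n1 n2 n3 n4 tag"
# records with 0-based node indices; .lon holds one unit axis per element per
# line (an optional leading "1" axes-per-element count line is tolerated).

#' Read a mesh from CARP or VTK files
#'
#' @param path for `format = "carp"` the base path (with or without `.pts`
#'   extension): `<base>.pts` and `<base>.elem` are required, `<base>.lon`
#'   optional.  For `format = "vtk"` a legacy-ASCII `.vtk` file.
#' @param format `"carp"` or `"vtk"`
#' @param units coordinate units in the file, `"mm"` (native) or `"um"`
#'   (converted to mm on read)
#' @return a [surface_mesh()] or [tet_mesh()] depending on element records
#' @export
read_mesh <- function(path, format = c("carp", "vtk"), units = c("mm", "um")) {
  format <- match.arg(format)
  units <- match.arg(units)
  scale <- if (units == "um") 1e-3 else 1
  if (format == "carp") read_carp(path, scale) else read_vtk(path, scale)
}

read_carp <- function(path, scale = 1) {
  base <- sub("\\.pts$", "", path)
  pts_path <- paste0(base, ".pts"); elem_path <- paste0(base, ".elem")
  lon_path <- paste0(base, ".lon")
  for (p in c(pts_path, elem_path))
    if (!file.exists(p)) stopf("read_mesh: required file %s not found", p)

  pts_lines <- readLines(pts_path)
  n_pts <- suppressWarnings(as.integer(trimws(pts_lines[1])))
  if (is.na(n_pts)) stopf("read_mesh: %s line 1: expected point count", pts_path)
  if (length(pts_lines) < n_pts + 1L)
    stopf("read_mesh: %s: %d points declared, %d lines present", pts_path, n_pts,
          length(pts_lines) - 1L)
  coords <- scan(text = pts_lines[2:(n_pts + 1L)], quiet = TRUE)
  if (length(coords) != 3L * n_pts)
    stopf("read_mesh: %s: malformed coordinate block", pts_path)
  vertices <- matrix(coords, ncol = 3, byrow = TRUE) * scale

  elem_lines <- readLines(elem_path)
  n_elem <- suppressWarnings(as.integer(trimws(elem_lines[1])))
  if (is.na(n_elem)) stopf("read_mesh: %s line 1: expected element count", elem_path)
  toks <- strsplit(trimws(elem_lines[2:(n_elem + 1L)]), "\\s+")
  kinds <- vapply(toks, `[[`, "", 1L)
  kind <- unique(kinds)
  if (length(kind) != 1L || !kind %in% c("Tr", "Tt"))
    stopf("read_mesh: %s: unsupported or mixed element types (%s); only Tr or Tt",
          elem_path, paste(kind, collapse = ","))
  nn <- if (kind == "Tt") 4L else 3L
  lens <- lengths(toks)
  if (any(lens < nn + 1L))
    stopf("read_mesh: %s line %d: too few fields", elem_path, which(lens < nn + 1L)[1] + 1L)
  num <- matrix(as.integer(unlist(lapply(toks, function(tk) tk[2:(nn + 1L)]))),
                ncol = nn, byrow = TRUE) + 1L   # CARP is 0-based
  tags <- ifelse(lens >= nn + 2L,
                 as.integer(vapply(toks, function(tk) if (length(tk) >= nn + 2L) tk[nn + 2L] else "0", "")),
                 0L)

  fibers <- NULL
  if (file.exists(lon_path)) {
    lon_lines <- readLines(lon_path)
    lon_lines <- lon_lines[nzchar(trimws(lon_lines))]
    # tolerate a leading axes-per-element count line ("1")
    first <- strsplit(trimws(lon_lines[1]), "\\s+")[[1]]
    if (length(first) == 1L) lon_lines <- lon_lines[-1]
    vals <- scan(text = lon_lines, quiet = TRUE)
    if (length(vals) != 3L * n_elem)
      stopf("read_mesh: %s: expected %d axes, found %g", lon_path, n_elem, length(vals) / 3)
    fibers <- matrix(vals, ncol = 3, byrow = TRUE)
  }

  if (kind == "Tt") tet_mesh(vertices, num, tags, fibers)
  else surface_mesh(vertices, num, tags, fibers)
}

#' Write a mesh to CARP or VTK files
#'
#' CARP: emits `<base>.pts` and `<base>.elem`, plus `<base>.lon` iff the mesh
#' carries fibers.  VTK: single legacy-ASCII unstructured grid with element
#' tags as cell scalars and fibers as a cell vector array.
#'
#' @param mesh a [surface_mesh()] or [tet_mesh()]
#' @param path base path (CARP) or `.vtk` file path (VTK)
#' @param format `"carp"` or `"vtk"`
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path, format = c("carp", "vtk")) {
  format <- match.arg(format)
  validate_mesh(mesh)
  if (format == "carp") write_carp(mesh, path) else write_vtk(mesh, path)
}

write_carp <- function(mesh, path) {
  base <- sub("\\.pts$", "", path)
  v <- mesh$vertices
  writeLines(c(format(nrow(v)),
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])),
             paste0(base, ".pts"))
  ele <- mesh_elements(mesh)
  kind <- if (inherits(mesh, "tet_mesh")) "Tt" else "Tr"
  tags <- mesh$element_tags %||% rep(0L, nrow(ele))
  idx0 <- ele - 1L
  body <- if (kind == "Tt")
    sprintf("Tt %d %d %d %d %d", idx0[, 1], idx0[, 2], idx0[, 3], idx0[, 4], tags)
  else
    sprintf("Tr %d %d %d %d", idx0[, 1], idx0[, 2], idx0[, 3], tags)
  writeLines(c(format(nrow(ele)), body), paste0(base, ".elem"))
  if (!is.null(mesh$fibers)) {
    f <- mesh$fibers
    writeLines(sprintf("%.9g %.9g %.9g", f[, 1], f[, 2], f[, 3]), paste0(base, ".lon"))
  }
  invisible(path)
}

write_vtk <- function(mesh, path) {
  v <- mesh$vertices; ele <- mesh_elements(mesh)
  nn <- ncol(ele); ctype <- if (nn == 4L) 10L else 5L
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "atriofiber mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(ele), nrow(ele) * (nn + 1L)), con)
  idx0 <- ele - 1L
  if (nn == 4L)
    writeLines(sprintf("4 %d %d %d %d", idx0[, 1], idx0[, 2], idx0[, 3], idx0[, 4]), con)
  else
    writeLines(sprintf("3 %d %d %d", idx0[, 1], idx0[, 2], idx0[, 3]), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(ele)), con)
  writeLines(format(rep(ctype, nrow(ele))), con)
  writeLines(sprintf("CELL_DATA %d", nrow(ele)), con)
  tags <- mesh$element_tags %||% rep(0L, nrow(ele))
  writeLines(c("SCALARS tags int 1", "LOOKUP_TABLE default", format(tags)), con)
  if (!is.null(mesh$fibers)) {
    f <- mesh$fibers
    writeLines("VECTORS fibers double", con)
    writeLines(sprintf("%.9g %.9g %.9g", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

read_vtk <- function(path, scale = 1) {
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "\\s+")
  find_kw <- function(kw) {
    hit <- which(vapply(toks, function(t) length(t) > 0 && identical(t[[1]], kw), TRUE))
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }
  ip <- find_kw("POINTS")
  if (is.na(ip)) stopf("read_mesh: %s: no POINTS block", path)
  np <- as.integer(toks[[ip]][2])
  pvals <- scan(text = lines[(ip + 1L):length(lines)], n = 3L * np, quiet = TRUE)
  vertices <- matrix(pvals, ncol = 3, byrow = TRUE) * scale
  ic <- find_kw("CELLS")
  nc <- as.integer(toks[[ic]][2]); ntot <- as.integer(toks[[ic]][3])
  cvals <- as.integer(scan(text = lines[(ic + 1L):length(lines)], n = ntot, quiet = TRUE))
  it <- find_kw("CELL_TYPES")
  ctypes <- as.integer(scan(text = lines[(it + 1L):length(lines)],
                            n = as.integer(toks[[it]][2]), quiet = TRUE))
  ct <- unique(ctypes)
  if (length(ct) != 1L || !ct %in% c(5L, 10L))
    stopf("read_mesh: %s: unsupported/mixed VTK cell types (%s)", path,
          paste(ct, collapse = ","))
  nn <- if (ct == 10L) 4L else 3L
  cm <- matrix(cvals, ncol = nn + 1L, byrow = TRUE)
  if (any(cm[, 1] != nn)) stopf("read_mesh: %s: inconsistent cell sizes", path)
  ele <- cm[, -1, drop = FALSE] + 1L
  tags <- NULL; fibers <- NULL
  is_ <- find_kw("SCALARS")
  if (!is.na(is_)) {
    svals <- scan(text = lines[(is_ + 2L):length(lines)], n = nc, quiet = TRUE)
    tags <- as.integer(svals)
  }
  iv <- find_kw("VECTORS")
  if (!is.na(iv)) {
    fvals <- scan(text = lines[(iv + 1L):length(lines)], n = 3L * nc, quiet = TRUE)
    fibers <- matrix(fvals, ncol = 3, byrow = TRUE)
  }
  if (nn == 4L) tet_mesh(vertices, ele, tags, fibers)
  else surface_mesh(vertices, ele, tags, fibers)
}
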