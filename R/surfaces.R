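#' Cortical surface mesh
#'
#' A triangle mesh in millimetre (RAS) coordinates tagged with the hemisphere
#' it represents. This is the substrate onto which streamline termination
#' points are projected.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, three 1-based vertex
#'   indices per row.
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `cortical_surface` with elements `vertices`,
#'   `triangles` and `hemisphere`.
#' @export
cortical_surface <- function(vertices, triangles, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L)
    stop("vertices must have 3 columns (x, y, z in mm)")
  if (nrow(vertices) < 3L)
    stop("a surface needs at least 3 vertices")
  if (ncol(triangles) != 3L)
    stop("triangles must have 3 columns of vertex indices")
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must be finite")
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle indices reference non-existent vertices")
    degen <- triangles[, 1L] == triangles[, 2L] |
      triangles[, 1L] == triangles[, 3L] |
      triangles[, 2L] == triangles[, 3L]
    if (any(degen))
      stop(sprintf("degenerate triangle(s) with repeated vertex index: first at row %d",
                   which(degen)[1L]))
  }
  structure(list(vertices = vertices, triangles = triangles, hemisphere = hemisphere),
            class = "cortical_surface")
}

#' @export
print.cortical_surface <- function(x, ...) {
  cat(sprintf("<cortical_surface: %s hemisphere, %d vertices, %d triangles>\n",
              x$hemisphere, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Per-triangle areas of a surface, in mm^2
#' @param surface a [cortical_surface()].
#' @return numeric vector of triangle areas.
#' @export
triangle_areas <- function(surface) {
  v <- surface$vertices
  t1 <- v[surface$triangles[, 1L], , drop = FALSE]
  e1 <- v[surface$triangles[, 2L], , drop = FALSE] - t1
  e2 <- v[surface$triangles[, 3L], , drop = FALSE] - t1
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Read a cortical surface mesh
#'
#' Accepts GIFTI surface files (`.gii`, ASCII / Base64Binary /
#' GZipBase64Binary encodings, little-endian), OFF, or ASCII PLY. The format
#' is detected from the file, not the extension.
#'
#' @param path path to a mesh file.
#' @param hemisphere hemisphere tag to store, `"left"` or `"right"`.
#' @return A [cortical_surface()].
#' @export
read_surface <- function(path, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (!file.exists(path)) stop(sprintf("surface file not found: %s", path))
  head_raw <- readBin(path, "raw", n = 512L)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0L)])
  if (grepl("<\\?xml|<GIFTI", head_txt)) {
    g <- read_gifti_surface(path)
    return(cortical_surface(g$vertices, g$triangles, hemisphere))
  }
  first <- toupper(trimws(strsplit(head_txt, "\n", fixed = TRUE)[[1L]][1L]))
  if (identical(first, "OFF")) {
    m <- read_off(path)
  } else if (identical(first, "PLY")) {
    m <- read_ply_ascii(path)
  } else {
    stop(sprintf("unrecognised surface format in %s (expected GIFTI, OFF or PLY; first line %s)",
                 path, dQuote(first)))
  }
  cortical_surface(m$vertices, m$triangles, hemisphere)
}

#' Write a cortical surface mesh
#'
#' OFF (default) or GIFTI ASCII, chosen by extension (`.gii` for GIFTI).
#' Coordinates are written at full double precision so a read-back is
#' bit-identical.
#'
#' @param surface a [cortical_surface()].
#' @param path destination path.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "cortical_surface"))
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    write_gifti_surface(surface, path)
  } else {
    write_off(surface, path)
  }
  invisible(path)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1L]) != "OFF")
    stop(sprintf("malformed OFF file %s: missing OFF header line", path))
  counts <- scan(text = lines[2L], what = integer(), quiet = TRUE)
  if (length(counts) < 2L)
    stop(sprintf("malformed OFF file %s: bad count line %s", path, dQuote(lines[2L])))
  nv <- counts[1L]; nf <- counts[2L]
  if (length(lines) < 2L + nv + nf)
    stop(sprintf("malformed OFF file %s: expected %d vertex and %d face lines", path, nv, nf))
  vtx <- matrix(scan(text = lines[3:(2L + nv)], what = double(), quiet = TRUE),
                ncol = 3L, byrow = TRUE)
  if (nf > 0L) {
    fl <- scan(text = lines[(3L + nv):(2L + nv + nf)], what = integer(), quiet = TRUE)
    fl <- matrix(fl, nrow = nf, byrow = TRUE)
    if (any(fl[, 1L] != 3L))
      stop(sprintf("malformed OFF file %s: non-triangular face at row %d",
                   path, which(fl[, 1L] != 3L)[1L]))
    tri <- fl[, 2:4, drop = FALSE] + 1L   # OFF is 0-based
  } else {
    tri <- matrix(integer(), 0L, 3L)
  }
  list(vertices = vtx, triangles = tri)
}

write_off <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surface$vertices), nrow(surface$triangles)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     surface$vertices[, 1L], surface$vertices[, 2L], surface$vertices[, 3L]), con)
  if (nrow(surface$triangles) > 0L)
    writeLines(sprintf("3 %d %d %d",
                       surface$triangles[, 1L] - 1L,
                       surface$triangles[, 2L] - 1L,
                       surface$triangles[, 3L] - 1L), con)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (toupper(trimws(lines[1L])) != "PLY")
    stop(sprintf("malformed PLY file %s: missing ply magic", path))
  end_hdr <- which(trimws(lines) == "end_header")[1L]
  if (is.na(end_hdr)) stop(sprintf("malformed PLY file %s: no end_header", path))
  hdr <- lines[seq_len(end_hdr)]
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop(sprintf("PLY file %s is not ASCII format", path))
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element\\s+vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "", grep("^element\\s+face", hdr, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf))
    stop(sprintf("malformed PLY file %s: missing vertex/face element counts", path))
  body <- lines[(end_hdr + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vraw <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vtx <- t(vapply(vraw, function(f) as.numeric(f[1:3]), numeric(3L)))
  fraw <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  tri <- t(vapply(fraw, function(f) {
    if (as.integer(f[1L]) != 3L) stop(sprintf("non-triangular face in PLY file %s", path))
    as.integer(f[2:4])
  }, integer(3L))) + 1L
  list(vertices = vtx, triangles = tri)
}
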