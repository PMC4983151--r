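# Minimal GIFTI (.gii) support: surface geometry (POINTSET + TRIANGLE data
# arrays) and per-element scalar/label arrays. Little-endian only; encodings
# ASCII, Base64Binary and GZipBase64Binary.

gifti_decode_data <- function(node, n_values) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  if (!is.na(endian) && identical(endian, "BigEndian"))
    stop("GIFTI BigEndian data is not supported")
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  rtype <- switch(dtype,
    "NIFTI_TYPE_FLOAT32" = list(what = "double", size = 4L),
    "NIFTI_TYPE_FLOAT64" = list(what = "double", size = 8L),
    "NIFTI_TYPE_INT32"   = list(what = "integer", size = 4L),
    "NIFTI_TYPE_UINT8"   = list(what = "integer", size = 1L),
    stop(sprintf("unsupported GIFTI DataType %s", dtype)))
  if (identical(enc, "ASCII")) {
    vals <- scan(text = txt, what = double(), quiet = TRUE)
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, type = "gzip")
    vals <- readBin(raw, rtype$what, n = n_values, size = rtype$size,
                    endian = "little", signed = TRUE)
  } else {
    stop(sprintf("unsupported GIFTI Encoding %s", enc))
  }
  if (length(vals) < n_values)
    stop(sprintf("GIFTI DataArray holds %d values, expected %d", length(vals), n_values))
  vals[seq_len(n_values)]
}

gifti_array_matrix <- function(node) {
  ndim <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  dims <- vapply(seq_len(ndim), function(d)
    as.integer(xml2::xml_attr(node, paste0("Dim", d - 1L))), integer(1L))
  n <- prod(dims)
  vals <- gifti_decode_data(node, n)
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  if (length(dims) == 1L) return(matrix(vals, ncol = 1L))
  if (is.na(order) || identical(order, "RowMajorOrder")) {
    matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
  } else {
    matrix(vals, nrow = dims[1L], ncol = dims[2L])
  }
}

read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0L)
    stop(sprintf("malformed GIFTI file %s: no DataArray elements", path))
  intents <- vapply(arrays, function(a) xml2::xml_attr(a, "Intent"), character(1L))
  ip <- which(intents == "NIFTI_INTENT_POINTSET")[1L]
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")[1L]
  if (is.na(ip) || is.na(it))
    stop(sprintf("GIFTI file %s lacks POINTSET and/or TRIANGLE arrays", path))
  vtx <- gifti_array_matrix(arrays[[ip]])
  tri <- gifti_array_matrix(arrays[[it]])
  storage.mode(tri) <- "integer"
  list(vertices = vtx, triangles = tri + 1L)   # GIFTI indices are 0-based
}

write_gifti_surface <- function(surface, path) {
  fmt_row <- function(m, fmt) paste(apply(m, 1L, function(r) paste(sprintf(fmt, r), collapse = " ")),
                                    collapse = "\n")
  vtx_txt <- fmt_row(surface$vertices, "%.9g")
  tri_txt <- fmt_row(surface$triangles - 1L, "%d")
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<GIFTI Version=\"1.0\" NumberOfDataArrays=\"2\">\n",
    sprintf(paste0("<DataArray Intent=\"NIFTI_INTENT_POINTSET\" DataType=\"NIFTI_TYPE_FLOAT32\"",
                   " ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"2\"",
                   " Dim0=\"%d\" Dim1=\"3\" Encoding=\"ASCII\" Endian=\"LittleEndian\">\n",
                   "<Data>%s</Data>\n</DataArray>\n"), nrow(surface$vertices), vtx_txt),
    sprintf(paste0("<DataArray Intent=\"NIFTI_INTENT_TRIANGLE\" DataType=\"NIFTI_TYPE_INT32\"",
                   " ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"2\"",
                   " Dim0=\"%d\" Dim1=\"3\" Encoding=\"ASCII\" Endian=\"LittleEndian\">\n",
                   "<Data>%s</Data>\n</DataArray>\n"), nrow(surface$triangles), tri_txt),
    "</GIFTI>\n")
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Export a per-triangle field as a GIFTI shape file
#'
#' Writes one scalar per surface element (`NIFTI_INTENT_SHAPE`), ASCII
#' encoded, suitable for surface viewers.
#'
#' @param values numeric vector, one value per triangle (or vertex).
#' @param path destination `.gii` path.
#' @export
write_gifti_shape <- function(values, path) {
  txt <- paste(sprintf("%.9g", values), collapse = "\n")
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<GIFTI Version=\"1.0\" NumberOfDataArrays=\"1\">\n",
    sprintf(paste0("<DataArray Intent=\"NIFTI_INTENT_SHAPE\" DataType=\"NIFTI_TYPE_FLOAT32\"",
                   " ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"1\" Dim0=\"%d\"",
                   " Encoding=\"ASCII\" Endian=\"LittleEndian\">\n<Data>%s</Data>\n</DataArray>\n"),
            length(values), txt),
    "</GIFTI>\n")
  writeLines(xml, path, sep = "")
  invisible(path)
}
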