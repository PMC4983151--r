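#' Tractogram container
#'
#' A set of streamlines, each an ordered polyline of 3-D points in scanner
#' millimetre (RAS) space.
#'
#' @param streamlines list of numeric matrices, each with >= 2 rows and 3
#'   columns (x, y, z in mm).
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines) {
  if (!is.list(streamlines)) stop("streamlines must be a list of point matrices")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L) stop("each streamline needs 3 coordinate columns")
    if (nrow(s) < 2L) stop("each streamline needs at least 2 points")
    if (!all(is.finite(s))) stop("streamline coordinates must be finite")
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines), class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1L))
  cat(sprintf("<tractogram: %d streamlines, %d points total>\n",
              length(x$streamlines), sum(np)))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Streamline lengths in mm
#' @param tract a [tractogram()].
#' @return numeric vector of polyline arc lengths.
#' @export
streamline_lengths <- function(tract) {
  vapply(tract$streamlines, function(s) {
    d <- diff(s)
    sum(sqrt(rowSums(d * d)))
  }, numeric(1L))
}

#' Termination points of every streamline
#' @param tract a [tractogram()].
#' @return list with `points` (2N x 3 matrix), `streamline` (index) and
#'   `end` (`"first"`/`"last"`) for each endpoint.
#' @export
streamline_endpoints <- function(tract) {
  n <- length(tract$streamlines)
  pts <- matrix(0, 2L * n, 3L)
  for (i in seq_len(n)) {
    s <- tract$streamlines[[i]]
    pts[2L * i - 1L, ] <- s[1L, ]
    pts[2L * i, ] <- s[nrow(s), ]
  }
  list(points = pts,
       streamline = rep(seq_len(n), each = 2L),
       end = rep(c("first", "last"), times = n))
}

# --- TCK (MRtrix) format ----------------------------------------------------
# Text header terminated by "END\n", then little-endian float32 triplets;
# (NaN,NaN,NaN) separates streamlines, (Inf,Inf,Inf) terminates the file.

#' Read a tractogram from a TCK file
#'
#' @param path path to an MRtrix `.tck` file (datatype Float32LE).
#' @return A [tractogram()]; coordinates carry float32 precision.
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) stop(sprintf("tractogram file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 14L || rawToChar(raw[1:13]) != "mrtrix tracks")
    stop(sprintf("%s is not a TCK file (missing 'mrtrix tracks' magic)", path))
  end_pos <- grepRaw("\nEND\n", raw, fixed = TRUE)
  if (length(end_pos) == 0L)
    stop(sprintf("malformed TCK header in %s: no END line", path))
  hdr_lines <- strsplit(rawToChar(raw[seq_len(end_pos[1L] - 1L)]), "\n", fixed = TRUE)[[1L]]
  kv <- hdr_lines[-1L]
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  dt <- vals[keys == "datatype"][1L]
  if (!is.na(dt) && !dt %in% c("Float32LE"))
    stop(sprintf("unsupported TCK datatype %s (only Float32LE)", dt))
  file_field <- vals[keys == "file"][1L]
  if (is.na(file_field)) stop(sprintf("malformed TCK header in %s: no file field", path))
  offset <- as.integer(sub("^\\.\\s+", "", file_field))
  if (is.na(offset)) stop(sprintf("malformed TCK file field %s", dQuote(file_field)))
  payload <- raw[(offset + 1L):length(raw)]
  vals32 <- readBin(payload, "double", n = length(payload) %/% 4L, size = 4L,
                    endian = "little")
  if (length(vals32) %% 3L != 0L)
    stop(sprintf("truncated TCK stream in %s (partial coordinate triplet)", path))
  m <- matrix(vals32, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.na(m)) == 3L
  is_inf <- rowSums(is.infinite(m)) == 3L
  term <- which(is_inf)[1L]
  seps <- which(is_nan | is_inf)
  if (is.na(term)) {
    n_complete <- sum(is_nan)
    stop(sprintf("truncated TCK file %s: no terminator after streamline %d", path, n_complete))
  }
  breaks <- c(0L, seps[seps <= term])
  streamlines <- list()
  count <- 0L
  for (b in seq_len(length(breaks) - 1L)) {
    lo <- breaks[b] + 1L; hi <- breaks[b + 1L] - 1L
    if (hi < lo) next
    count <- count + 1L
    streamlines[[count]] <- m[lo:hi, , drop = FALSE]
  }
  tractogram(streamlines)
}

#' Write a tractogram to a TCK file
#'
#' Coordinates are stored as little-endian float32, the TCK on-disk type.
#'
#' @param tract a [tractogram()].
#' @param path destination `.tck` path.
#' @export
write_tractogram <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  n <- length(tract$streamlines)
  # header length depends on the printed offset; iterate to a fixed point
  offset <- 100L
  repeat {
    hdr <- sprintf("mrtrix tracks\ndatatype: Float32LE\ncount: %d\nfile: . %d\nEND\n",
                   n, offset)
    if (nchar(hdr, type = "bytes") <= offset) break
    offset <- nchar(hdr, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  pad <- offset - nchar(hdr, type = "bytes")
  if (pad > 0L) writeBin(rep(as.raw(0L), pad), con)
  for (s in tract$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}
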