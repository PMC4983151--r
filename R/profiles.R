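#' Vulnerability profile container
#'
#' A networks x resection-extents matrix of involvement fractions in 0..1:
#' entry (n, e) is the fraction of network n's cortical triangles receiving
#' at least one endpoint from streamlines cut by an anterior resection of
#' extent e of the corpus callosum.
#'
#' @param values numeric matrix, networks in rows, extents in columns.
#' @param networks network labels (row names).
#' @param extents numeric extents in (0, 1], one per column.
#' @return An object of class `vulnerability_profile` (a matrix with an
#'   `extents` attribute).
#' @export
vulnerability_profile <- function(values, networks, extents) {
  values <- as.matrix(values)
  if (length(networks) != nrow(values)) stop("one network label per row required")
  if (length(extents) != ncol(values)) stop("one extent per column required")
  if (any(extents <= 0 | extents > 1)) stop("extents must lie in (0, 1]")
  ok <- is.na(values) | (values >= 0 & values <= 1)
  if (!all(ok)) stop("involvement values must lie in [0, 1]")
  rownames(values) <- as.character(networks)
  colnames(values) <- sprintf("extent_%g", extents)
  structure(values, extents = as.numeric(extents), class = c("vulnerability_profile", "matrix"))
}

#' @export
print.vulnerability_profile <- function(x, ...) {
  cat(sprintf("<vulnerability_profile: %d networks x %d extents>\n", nrow(x), ncol(x)))
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Write a vulnerability profile as CSV
#'
#' One row per network, one column per resection extent, values printed with
#' 6 decimal places (below any scientifically meaningful difference, above
#' float32 noise) so a read-back reproduces the file exactly.
#'
#' @param profile a [vulnerability_profile()].
#' @param path destination CSV path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "vulnerability_profile"))
  extents <- attr(profile, "extents")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("network", sprintf("%g", extents)), collapse = ","), con)
  for (i in seq_len(nrow(profile))) {
    vals <- ifelse(is.na(profile[i, ]), "NA", sprintf("%.6f", profile[i, ]))
    writeLines(paste(c(rownames(profile)[i], vals), collapse = ","), con)
  }
  invisible(path)
}

#' Read a vulnerability profile written by [write_profile()]
#' @param path CSV path.
#' @return A [vulnerability_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("profile file not found: %s", path))
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1L] != "network") stop(sprintf("malformed profile CSV %s", path))
  extents <- as.numeric(names(d)[-1L])
  if (anyNA(extents)) stop(sprintf("malformed extent header in %s", path))
  vals <- as.matrix(d[, -1L, drop = FALSE])
  vulnerability_profile(vals, d$network, extents)
}

#' Heat-map rendering of a vulnerability profile
#'
#' Base-graphics analogue of the usual network-by-extent heat map: anterior
#' resections on the left, networks stacked on the vertical axis.
#'
#' @param profile a [vulnerability_profile()].
#' @param main plot title.
#' @export
plot_vulnerability_profile <- function(profile, main = "Predicted network disruption") {
  extents <- attr(profile, "extents")
  z <- t(unclass(profile))[, rev(seq_len(nrow(profile))), drop = FALSE]
  graphics::image(x = seq_along(extents), y = seq_len(nrow(profile)), z = z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  zlim = c(0, 1), axes = FALSE, xlab = "anterior resection extent",
                  ylab = "", main = main)
  graphics::axis(1, at = seq_along(extents), labels = sprintf("%d%%", round(extents * 100)))
  graphics::axis(2, at = seq_len(nrow(profile)), labels = rev(rownames(profile)), las = 2)
  graphics::box()
  invisible(profile)
}
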