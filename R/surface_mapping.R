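#' Assign streamline endpoints to their nearest cortical vertex
#'
#' Every streamline contributes its two termination points; each is assigned
#' to the globally nearest vertex (shortest Euclidean distance) across both
#' hemispheres. Ties resolve to the lowest vertex id, left hemisphere before
#' right. With no distance cap the assignment is total: exactly
#' `2 * n_streamlines` endpoints are assigned.
#'
#' @param tract a [tractogram()].
#' @param surfaces list with `left` and `right` [cortical_surface()]s.
#' @param max_distance_mm optional cap; endpoints farther from every vertex
#'   are recorded as unassigned (default `NULL`, no cap).
#' @return An `endpoint_assignment`: data.frame `endpoints` (streamline, end,
#'   vertex global id, hemisphere, distance, assigned), integer vector
#'   `vertex_counts` over the concatenated left+right vertices, and
#'   `n_left_vertices` giving the split point.
#' @export
assign_endpoints <- function(tract, surfaces, max_distance_mm = NULL) {
  stopifnot(inherits(tract, "tractogram"))
  if (!all(c("left", "right") %in% names(surfaces)))
    stop("surfaces must be a list with elements left and right")
  sl <- surfaces$left; sr <- surfaces$right
  stopifnot(inherits(sl, "cortical_surface"), inherits(sr, "cortical_surface"))
  if (nrow(sl$vertices) == 0L || nrow(sr$vertices) == 0L)
    stop("empty surface")
  nv_l <- nrow(sl$vertices)
  verts <- rbind(sl$vertices, sr$vertices)
  n_total <- nv_l + nrow(sr$vertices)
  if (length(tract$streamlines) == 0L) {
    ep <- data.frame(streamline = integer(), end = character(),
                     vertex = integer(), hemisphere = character(),
                     distance = numeric(), assigned = logical())
    return(structure(list(endpoints = ep,
                          vertex_counts = integer(n_total),
                          n_left_vertices = nv_l),
                     class = "endpoint_assignment"))
  }
  eps <- streamline_endpoints(tract)
  nn <- nearest_vertex_cpp(eps$points, verts)
  assigned <- if (is.null(max_distance_mm)) rep(TRUE, nrow(eps$points))
              else nn$distance <= max_distance_mm
  ep <- data.frame(streamline = eps$streamline,
                   end = eps$end,
                   vertex = nn$index,
                   hemisphere = ifelse(nn$index <= nv_l, "left", "right"),
                   distance = nn$distance,
                   assigned = assigned,
                   stringsAsFactors = FALSE)
  counts <- tabulate(ep$vertex[ep$assigned], nbins = n_total)
  structure(list(endpoints = ep, vertex_counts = counts, n_left_vertices = nv_l),
            class = "endpoint_assignment")
}

#' @export
print.endpoint_assignment <- function(x, ...) {
  cat(sprintf("<endpoint_assignment: %d endpoints (%d assigned), %d vertices>\n",
              nrow(x$endpoints), sum(x$endpoints$assigned), length(x$vertex_counts)))
  invisible(x)
}

hemi_counts <- function(assignment, hemisphere) {
  nv_l <- assignment$n_left_vertices
  if (hemisphere == "left") assignment$vertex_counts[seq_len(nv_l)]
  else assignment$vertex_counts[(nv_l + 1L):length(assignment$vertex_counts)]
}

#' Per-triangle endpoint count field
#'
#' For each triangle, `n` is the median of the endpoint counts at its three
#' vertices; the display value is `log(1 + n)` (natural log). An
#' `any_involved` flag records the weaker any-vertex condition for the
#' alternative involvement rule.
#'
#' @param assignment an `endpoint_assignment` built against `surface`.
#' @param surface a [cortical_surface()]; its hemisphere tag selects the
#'   matching block of vertex counts.
#' @return A `triangle_count_field`: list with `n`, `display`,
#'   `any_involved`, `vertex_counts`, `hemisphere`.
#' @export
triangle_counts <- function(assignment, surface) {
  stopifnot(inherits(assignment, "endpoint_assignment"),
            inherits(surface, "cortical_surface"))
  vc <- hemi_counts(assignment, surface$hemisphere)
  if (length(vc) != nrow(surface$vertices))
    stop("assignment was built against a different surface (vertex count mismatch)")
  cm <- matrix(vc[surface$triangles], ncol = 3L)
  n <- pmax(pmin(cm[, 1L], cm[, 2L]),
            pmin(cm[, 1L], cm[, 3L]),
            pmin(cm[, 2L], cm[, 3L]))            # median of three
  structure(list(n = n, display = log1p(n),
                 any_involved = cm[, 1L] >= 1L | cm[, 2L] >= 1L | cm[, 3L] >= 1L,
                 vertex_counts = vc, hemisphere = surface$hemisphere),
            class = "triangle_count_field")
}

triangle_involved <- function(field, rule = c("median", "any")) {
  rule <- match.arg(rule)
  if (rule == "median") field$n >= 1L else field$any_involved
}

#' Fraction of a hemisphere's surface involved in callosal connectivity
#'
#' A triangle is involved when its median endpoint count `n >= 1` (default;
#' the same per-triangle statistic the count field displays). The `any`
#' rule, counting a triangle as involved when any of its three vertices
#' received an endpoint, is available as an alternative; area weighting
#' replaces the triangle fraction by an area fraction.
#'
#' @param field a [triangle_counts()] field.
#' @param surface the matching [cortical_surface()].
#' @param area_weighted use triangle areas instead of counts.
#' @param rule involvement rule, `"median"` (default) or `"any"`.
#' @return Fraction in 0..1.
#' @export
hemisphere_coverage <- function(field, surface, area_weighted = FALSE,
                                rule = c("median", "any")) {
  stopifnot(inherits(field, "triangle_count_field"),
            inherits(surface, "cortical_surface"))
  if (nrow(surface$triangles) == 0L) stop("surface has no triangles")
  if (length(field$n) != nrow(surface$triangles))
    stop("field was built for a different surface")
  inv <- triangle_involved(field, rule)
  if (!area_weighted) return(mean(inv))
  areas <- triangle_areas(surface)
  sum(areas[inv]) / sum(areas)
}

#' Export a triangle count field as CSV (triangle id, n, log1p)
#' @param field a [triangle_counts()] field.
#' @param path destination CSV path.
#' @export
write_triangle_field <- function(field, path) {
  utils::write.csv(data.frame(triangle = seq_along(field$n),
                              n = field$n,
                              log1p_n = sprintf("%.6f", field$display)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
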