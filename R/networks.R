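#' Per-network callosal involvement
#'
#' For each network, the fraction of its labelled triangles — both
#' hemispheres pooled, the Yeo models being bilateral — whose median
#' endpoint count is at least 1. Label-0 (unassigned/medial wall) triangles
#' are excluded. A network with no triangles yields `NA`, not 0.
#'
#' @param fields list with `left` and `right` [triangle_counts()] fields.
#' @param labels a [label_table()] over the same triangles.
#' @param rule involvement rule, `"median"` (default) or `"any"`.
#' @param per_hemisphere if `TRUE` return a networks x 2 matrix instead of
#'   the pooled vector.
#' @return Named numeric vector of involvement fractions (or a matrix).
#' @export
network_involvement <- function(fields, labels, rule = c("median", "any"),
                                per_hemisphere = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(labels, "label_table"))
  fl <- fields$left; fr <- fields$right
  stopifnot(inherits(fl, "triangle_count_field"),
            inherits(fr, "triangle_count_field"))
  if (length(fl$n) != length(labels$left) || length(fr$n) != length(labels$right))
    stop("labels do not cover the same triangles as the count fields")
  inv_l <- triangle_involved(fl, rule)
  inv_r <- triangle_involved(fr, rule)
  nn <- max(c(labels$left, labels$right, 1L))
  one <- function(inv, lab) vapply(seq_len(nn), function(g) {
    sel <- inv[lab == g]
    if (length(sel) == 0L) NA_real_ else mean(sel)
  }, numeric(1L))
  if (per_hemisphere) {
    out <- cbind(left = one(inv_l, labels$left), right = one(inv_r, labels$right))
    rownames(out) <- paste0("network_", seq_len(nn))
    return(out)
  }
  pooled <- vapply(seq_len(nn), function(g) {
    sel <- c(inv_l[labels$left == g], inv_r[labels$right == g])
    if (length(sel) == 0L) NA_real_ else mean(sel)
  }, numeric(1L))
  stats::setNames(pooled, paste0("network_", seq_len(nn)))
}

# rebuild an assignment-like count structure restricted to a streamline subset
restrict_assignment <- function(assignment, keep_streamlines) {
  ep <- assignment$endpoints
  sel <- ep$assigned & ep$streamline %in% keep_streamlines
  counts <- tabulate(ep$vertex[sel], nbins = length(assignment$vertex_counts))
  structure(list(endpoints = ep[sel, , drop = FALSE],
                 vertex_counts = counts,
                 n_left_vertices = assignment$n_left_vertices),
            class = "endpoint_assignment")
}

#' Vulnerability profile under progressive anterior callosotomy
#'
#' For each resection extent `j/k`, the tractogram is restricted to the
#' streamlines cut by an anterior-`j` resection (anterior-most traversed
#' segment `<= j`), the per-triangle count field is rebuilt from their
#' endpoints alone, and per-network involvement is recomputed. The extent-1
#' column therefore equals the full (callosal) involvement exactly — total
#' resection cuts every callosal streamline.
#'
#' @param assignment an [assign_endpoints()] result for the full tractogram.
#' @param segments a [streamline_segments()] result for the same tractogram.
#' @param labels a [label_table()].
#' @param surfaces list with `left` and `right` [cortical_surface()]s.
#' @param extents resection extents, each of the form `j/k`; default all of
#'   `1/k .. k/k` (20% increments for `k = 5`).
#' @param rule involvement rule passed to [network_involvement()].
#' @return A [vulnerability_profile()] (networks x extents).
#' @export
callosotomy_profile <- function(assignment, segments, labels, surfaces,
                                extents = NULL, rule = c("median", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(assignment, "endpoint_assignment"),
            inherits(segments, "streamline_segments"))
  k <- segments$k
  if (is.null(extents)) extents <- seq_len(k) / k
  js <- extents * k
  if (any(abs(js - round(js)) > 1e-9))
    stop(sprintf("extents must be multiples of 1/%d (segment granularity)", k))
  js <- as.integer(round(js))
  if (any(js < 1L | js > k)) stop("extents must lie in (0, 1]")
  cols <- lapply(js, function(j) {
    keep <- which(cut_by_resection(segments, j))
    sub <- restrict_assignment(assignment, keep)
    fields <- list(left = triangle_counts(sub, surfaces$left),
                   right = triangle_counts(sub, surfaces$right))
    network_involvement(fields, labels, rule = rule)
  })
  vals <- do.call(cbind, cols)
  vulnerability_profile(vals, rownames(vals), extents)
}

#' Fibre-count variant of the vulnerability profile
#'
#' Alternative metric: for each network and extent, the fraction of the
#' network's callosal streamlines cut by the resection (a streamline belongs
#' to every network owning a triangle adjacent to an assigned endpoint's
#' vertex is deliberately NOT attempted; membership here is by endpoint
#' vertex label, both endpoints counted). Kept separate from the primary
#' triangle-involvement metric, which is what reproduces the full-resection
#' identity.
#'
#' @param assignment an [assign_endpoints()] result.
#' @param segments a [streamline_segments()] result.
#' @param labels a [label_table()].
#' @param surfaces list of the two [cortical_surface()]s.
#' @param extents as in [callosotomy_profile()].
#' @return A [vulnerability_profile()] of cut-fibre fractions.
#' @export
fibre_fraction_profile <- function(assignment, segments, labels, surfaces,
                                   extents = NULL) {
  k <- segments$k
  if (is.null(extents)) extents <- seq_len(k) / k
  js <- as.integer(round(extents * k))
  # vertex -> network lookup: label of any incident triangle (first wins)
  vert_net <- function(surface, lab) {
    vn <- integer(nrow(surface$vertices))
    for (c in 3:1) vn[surface$triangles[, c]] <- lab
    vn
  }
  vn <- c(vert_net(surfaces$left, labels$left),
          vert_net(surfaces$right, labels$right) )
  ep <- assignment$endpoints
  ep <- ep[ep$assigned, , drop = FALSE]
  ep_net <- vn[ep$vertex]
  callosal <- segments$callosal[ep$streamline]
  nn <- max(c(labels$left, labels$right, 1L))
  vals <- matrix(NA_real_, nn, length(js))
  for (ci in seq_along(js)) {
    cut <- cut_by_resection(segments, js[ci])[ep$streamline]
    for (g in seq_len(nn)) {
      sel <- ep_net == g & callosal
      denom <- length(unique(ep$streamline[sel]))
      if (denom == 0L) next
      vals[g, ci] <- length(unique(ep$streamline[sel & cut])) / denom
    }
  }
  vulnerability_profile(vals, paste0("network_", seq_len(nn)), extents)
}

#' Downsample a 17-network profile to the 7-network model
#'
#' Each 7-network value at each extent is the weight-normalised average of
#' its contributing 17-network values: `sum(w v) / sum(w)`.
#'
#' @param profile a [vulnerability_profile()] over 17 networks (rows named
#'   `network_1..network_17` or plain `1..17`).
#' @param mapping data.frame from [read_network_mapping()].
#' @return A [vulnerability_profile()] over 7 networks, rows named by the
#'   standard Yeo 7 labels.
#' @export
downsample_17_to_7 <- function(profile, mapping = read_network_mapping()) {
  stopifnot(inherits(profile, "vulnerability_profile"))
  ids <- as.integer(gsub("[^0-9]", "", rownames(profile)))
  if (anyNA(ids)) stop("profile row names must identify networks 1..17")
  names7 <- c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
              "Limbic", "Frontoparietal", "Default")
  targets <- sort(unique(mapping$network7))
  vals <- matrix(NA_real_, length(targets), ncol(profile))
  for (ti in seq_along(targets)) {
    rows <- mapping[mapping$network7 == targets[ti], ]
    w <- rows$weight
    if (sum(w) <= 0) stop(sprintf("all mapping weights for 7-network %d are zero", targets[ti]))
    src <- match(rows$network17, ids)
    if (anyNA(src)) stop("mapping references networks missing from the profile")
    v <- unclass(profile)[src, , drop = FALSE]
    vals[ti, ] <- as.vector(crossprod(w, ifelse(is.na(v), 0, v))) /
      as.vector(crossprod(w, 1 - is.na(v) + 0))
  }
  lab <- if (max(targets) <= 7L) names7[targets] else paste0("network7_", targets)
  vulnerability_profile(vals, lab, attr(profile, "extents"))
}

#' Spearman rank correlation for scan-rescan reproducibility
#'
#' Computed from first principles: average ranks for ties, then the Pearson
#' correlation of the rank vectors; two-sided p-value via the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. Zero-count triangles are included — reproducibility
#' is assessed over every surface element.
#'
#' @param counts_a,counts_b equal-length numeric vectors (per-triangle
#'   counts of two sessions or pipeline runs).
#' @return A `reproducibility_result`: list with `rho`, `p_value`, `n` (and
#'   `note` when rho is undefined).
#' @export
spearman_reproducibility <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors must have equal length")
  n <- length(counts_a)
  if (n < 3L) stop("need at least 3 paired elements")
  if (length(unique(counts_a)) < 2L || length(unique(counts_b)) < 2L) {
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          note = "rho undefined: constant input vector"),
                     class = "reproducibility_result"))
  }
  ra <- rank(counts_a, ties.method = "average")
  rb <- rank(counts_b, ties.method = "average")
  da <- ra - mean(ra); db <- rb - mean(rb)
  rho <- sum(da * db) / sqrt(sum(da * da) * sum(db * db))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "reproducibility_result")
}

#' @export
print.reproducibility_result <- function(x, ...) {
  if (is.na(x$rho)) cat(sprintf("<reproducibility: rho undefined (%s), n = %d>\n", x$note, x$n))
  else cat(sprintf("<reproducibility: Spearman rho = %.4f, p = %.3g, n = %d>\n",
                   x$rho, x$p_value, x$n))
  invisible(x)
}
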