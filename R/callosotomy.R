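#' Subdivide the corpus callosum along its principal axis
#'
#' The principal eigendirection is the leading eigenvector of the covariance
#' of the in-mask voxel-centre mm coordinates, sign-flipped so its anterior
#' (+Y in RAS) component is non-negative. Voxel projections onto this axis
#' are binned into `k` equal-width intervals over `[min, max]`; segment 1 is
#' the anterior-most fifth (for the default `k = 5`). A projection exactly
#' on an interior bin edge goes to the more anterior bin.
#'
#' @param mask a [volume_mask()] of the CC.
#' @param k number of segments (default 5).
#' @return A `cc_segmentation`: `eigendirection` (unit 3-vector),
#'   `projections` (per voxel, mm), `bin_edges` (k+1, descending along the
#'   anterior direction when read as labels 1..k), `segment` (per-voxel
#'   label 1..k, 1 = anterior-most) and `k`.
#' @export
segment_cc <- function(mask, k = 5L) {
  stopifnot(inherits(mask, "volume_mask"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (nrow(mask$ijk) < k) stop(sprintf("mask has %d voxels, fewer than k = %d", nrow(mask$ijk), k))
  ctr <- mask_voxel_centres(mask)
  cv <- stats::cov(ctr)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1L] <= .Machine$double.eps * 100)
    stop("degenerate mask with no spatial spread")
  v <- eg$vectors[, 1L]
  rel_gap <- (eg$values[1L] - eg$values[2L]) / eg$values[1L]
  if (rel_gap < 1e-6) {
    warning("leading eigenvalues are tied; applying deterministic tie-break")
    tied <- which((eg$values[1L] - eg$values) / eg$values[1L] < 1e-6)
    cand <- eg$vectors[, tied, drop = FALSE]
    score <- abs(cand[2L, ]) * 2 + abs(cand[1L, ])   # largest |Y|, then |X|
    v <- cand[, which.max(score)]
  }
  # orient anterior-positive; fall back to +X then +Z when Y is exactly 0
  if (v[2L] < 0) v <- -v
  else if (v[2L] == 0 && (v[1L] < 0 || (v[1L] == 0 && v[3L] < 0))) v <- -v
  proj <- as.vector(ctr %*% v)
  lo <- min(proj); hi <- max(proj)
  if (hi - lo <= 0) stop("mask projections are degenerate (all voxels project equally)")
  edges <- seq(lo, hi, length.out = k + 1L)
  a <- (hi - proj) / (hi - lo)                  # 0 = anterior end of the axis
  seg <- pmax(1L, as.integer(ceiling(a * k)))
  structure(list(eigendirection = v, projections = proj, bin_edges = edges,
                 segment = seg, k = k),
            class = "cc_segmentation")
}

#' @export
print.cc_segmentation <- function(x, ...) {
  cat(sprintf("<cc_segmentation: k = %d, eigendirection (%.3f, %.3f, %.3f)>\n",
              x$k, x$eigendirection[1L], x$eigendirection[2L], x$eigendirection[3L]))
  print(table(segment = x$segment))
  invisible(x)
}

#' Which CC segments does each streamline traverse?
#'
#' Maps every streamline point to a voxel through the mask's inverse affine
#' (voxel-centre convention, nearest voxel) and collects the segment labels
#' of in-mask hits. Streamlines with no in-mask point are flagged
#' non-callosal and excluded from callosal analyses.
#'
#' @param tract a [tractogram()] in the same mm frame as the mask.
#' @param segmentation a [segment_cc()] result for `mask`.
#' @param mask the [volume_mask()] the segmentation was built from.
#' @return A `streamline_segments`: list `sets` (integer vector of traversed
#'   segment labels per streamline), `anterior_most` (min label, NA when
#'   non-callosal), `callosal` (logical), `k`.
#' @export
streamline_segments <- function(tract, segmentation, mask) {
  stopifnot(inherits(tract, "tractogram"),
            inherits(segmentation, "cc_segmentation"),
            inherits(mask, "volume_mask"))
  if (length(segmentation$segment) != nrow(mask$ijk))
    stop("segmentation does not match the mask (voxel count differs)")
  inv <- solve(mask$affine)
  keys <- voxel_key(mask$ijk, mask$dim)
  seg_of <- segmentation$segment[order(keys)]
  keys_sorted <- sort(keys)
  n <- length(tract$streamlines)
  sets <- vector("list", n)
  ant <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- tract$streamlines[[i]]
    vox <- cbind(p, 1) %*% t(inv)
    ijk <- round(vox[, 1:3, drop = FALSE])
    inside <- ijk[, 1L] >= 0 & ijk[, 1L] < mask$dim[1L] &
              ijk[, 2L] >= 0 & ijk[, 2L] < mask$dim[2L] &
              ijk[, 3L] >= 0 & ijk[, 3L] < mask$dim[3L]
    if (!any(inside)) { sets[[i]] <- integer(0); next }
    kk <- voxel_key(ijk[inside, , drop = FALSE], mask$dim)
    pos <- findInterval(kk, keys_sorted)
    hit <- pos > 0 & keys_sorted[pmax(pos, 1L)] == kk
    if (!any(hit)) { sets[[i]] <- integer(0); next }
    labs <- sort(unique(seg_of[pos[hit]]))
    sets[[i]] <- labs
    ant[i] <- labs[1L]
  }
  structure(list(sets = sets, anterior_most = ant,
                 callosal = !is.na(ant), k = segmentation$k),
            class = "streamline_segments")
}

#' @export
print.streamline_segments <- function(x, ...) {
  cat(sprintf("<streamline_segments: %d streamlines, %d callosal, %d non-callosal>\n",
              length(x$sets), sum(x$callosal), sum(!x$callosal)))
  invisible(x)
}

#' Streamlines cut by an anterior resection of the first `j` segments
#'
#' A streamline is cut when ANY of its traversed segments has label `<= j`
#' (a transected axon is disrupted wherever it is cut).
#'
#' @param segments a [streamline_segments()] result.
#' @param j number of anterior segments resected (0 cuts nothing).
#' @return Logical vector over streamlines.
#' @export
cut_by_resection <- function(segments, j) {
  stopifnot(inherits(segments, "streamline_segments"))
  if (j < 0L || j > segments$k) stop("j must lie in 0..k")
  !is.na(segments$anterior_most) & segments$anterior_most <= j
}

#' Export a CC segmentation as a labelled NIfTI volume
#' @param segmentation a [segment_cc()] result.
#' @param mask the matching [volume_mask()].
#' @param path destination `.nii` path.
#' @export
write_segmentation <- function(segmentation, mask, path) {
  write_mask(mask, path, values = segmentation$segment)
}

#' Export per-streamline segment sets as CSV
#' @param segments a [streamline_segments()] result.
#' @param path destination CSV path.
#' @export
write_streamline_segments <- function(segments, path) {
  df <- data.frame(streamline = seq_along(segments$sets),
                   segments = vapply(segments$sets, paste, character(1L), collapse = ";"),
                   anterior_most = segments$anterior_most)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
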