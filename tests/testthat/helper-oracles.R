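# Independent oracles and tiny fixture builders. Each oracle deliberately
# takes a different route from the implementation it checks.

# exhaustive nearest-vertex search, vectorised per endpoint (no C++)
oracle_nearest_vertex <- function(points, vertices) {
  idx <- integer(nrow(points))
  dist <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (vertices[, 1L] - points[i, 1L])^2 +
          (vertices[, 2L] - points[i, 2L])^2 +
          (vertices[, 3L] - points[i, 3L])^2
    j <- which.min(d2)          # which.min keeps the first (lowest id) tie
    idx[i] <- j
    dist[i] <- sqrt(d2[j])
  }
  list(index = idx, distance = dist)
}

# brute-force Otsu: split the SAMPLE at every interior bin edge and compute
# the between-class variance from the actual values
oracle_otsu <- function(values, n_bins = 256L) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  best <- -Inf; best_edge <- NA_real_
  for (i in 2:n_bins) {
    t <- edges[i]
    lo <- values[values < t]; hi <- values[values >= t]
    if (length(lo) == 0L || length(hi) == 0L) next
    b <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (b > best) { best <- b; best_edge <- t }
  }
  best_edge
}

# first-principles Spearman: average ranks, then plain Pearson via cor()
oracle_spearman <- function(a, b) {
  stats::cor(rank(a, ties.method = "average"), rank(b, ties.method = "average"))
}

# point-in-voxel by explicit comparison against every mask voxel centre
oracle_streamline_anterior <- function(points, mask, segmentation, half = NULL) {
  ctr <- mask_voxel_centres(mask)
  vs <- abs(diag(mask$affine)[1:3])
  labs <- integer(0)
  for (p in seq_len(nrow(points))) {
    inside <- abs(ctr[, 1L] - points[p, 1L]) <= vs[1L] / 2 &
              abs(ctr[, 2L] - points[p, 2L]) <= vs[2L] / 2 &
              abs(ctr[, 3L] - points[p, 3L]) <= vs[3L] / 2
    labs <- c(labs, segmentation$segment[inside])
  }
  if (length(labs) == 0L) NA_integer_ else min(labs)
}

# binomial 3-standard-error tolerance with the a-priori continuity clamp
tol3se <- function(p, n) {
  p <- pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  3 * sqrt(p * (1 - p) / n)
}

# a tiny two-hemisphere world for unit tests: two 3-vertex plates
tiny_surfaces <- function() {
  vl <- rbind(c(-10, 0, 0), c(-10, 5, 0), c(-10, 0, 5))
  vr <- rbind(c(10, 0, 0), c(10, 5, 0), c(10, 0, 5))
  list(left = cortical_surface(vl, rbind(c(1, 2, 3)), "left"),
       right = cortical_surface(vr, rbind(c(1, 2, 3)), "right"))
}

# straight left-right streamline through x = 0 at a given (y, z)
straight_streamline <- function(y = 0, z = 0, x_from = -12, x_to = 12, n = 25) {
  cbind(seq(x_from, x_to, length.out = n), y, z)
}

small_bundle <- function(seed = 1, n_streamlines = 2000, ...) {
  generate_dataset(synthetic_config(seed = seed, n_streamlines = n_streamlines,
                                    mesh_triangles_per_hemisphere = 2000L, ...))
}
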