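#' Orientation field for the toy deterministic tracker
#'
#' A voxel grid carrying one principal fibre direction and one anisotropy
#' value per voxel. This is a stand-in for a reconstructed diffusion model:
#' it exists so the stated termination rules (anisotropy threshold, turning
#' angle, length window) can be exercised exactly, not to model diffusion.
#'
#' @param dim integer triple, grid shape.
#' @param affine 4x4 voxel-index-to-mm matrix (voxel centres, 0-based).
#' @param directions array `dim x 3` (4-D) of direction vectors; normalised
#'   internally wherever anisotropy is positive.
#' @param anisotropy array `dim` of non-negative scalars.
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(dim, affine, directions, anisotropy) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (!all(dim(directions) == c(dim, 3L))) stop("directions must be dim x 3")
  if (!all(dim(anisotropy) == dim)) stop("anisotropy must match dim")
  if (any(anisotropy < 0)) stop("anisotropy must be non-negative")
  nrm <- sqrt(directions[, , , 1L]^2 + directions[, , , 2L]^2 + directions[, , , 3L]^2)
  pos <- anisotropy > 0
  if (any(pos & nrm == 0)) stop("zero direction vector where anisotropy > 0")
  for (a in 1:3) {
    d <- directions[, , , a]
    d[pos] <- d[pos] / nrm[pos]
    directions[, , , a] <- d
  }
  structure(list(dim = dim, affine = affine, inv_affine = solve(affine),
                 directions = directions, anisotropy = anisotropy),
            class = "orientation_field")
}

field_lookup <- function(field, pt) {
  # nearest-voxel (no interpolation): round the inverse-affine coordinate
  v <- field$inv_affine %*% c(pt, 1)
  ijk <- round(v[1:3])
  if (any(ijk < 0) || any(ijk >= field$dim)) return(NULL)
  i <- ijk[1L] + 1L; j <- ijk[2L] + 1L; k <- ijk[3L] + 1L
  list(dir = c(field$directions[i, j, k, 1L],
               field$directions[i, j, k, 2L],
               field$directions[i, j, k, 3L]),
       fa = field$anisotropy[i, j, k])
}

track_one_direction <- function(field, seed_pt, first_dir, step_mm,
                                cos_limit, threshold, max_steps) {
  pts <- matrix(0, max_steps + 1L, 3L)
  pts[1L, ] <- seed_pt
  prev_dir <- first_dir
  n <- 1L
  pos <- seed_pt
  while (n <= max_steps) {
    vox <- field_lookup(field, pos)
    if (is.null(vox) || vox$fa < threshold) break
    d <- vox$dir
    if (sum(d * prev_dir) < 0) d <- -d          # sign-align with previous step
    if (sum(d * prev_dir) < cos_limit) break    # turning angle exceeded
    pos <- pos + step_mm * d
    n <- n + 1L
    pts[n, ] <- pos
    prev_dir <- d
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Deterministic fixed-step Euler streamline tracking
#'
#' Propagates bidirectionally from each seed along the nearest voxel's
#' direction with a fixed Euler step. A direction terminates when the local
#' anisotropy falls below `anisotropy_threshold`, when the turning angle
#' between consecutive steps exceeds `angular_limit_deg`, or when the point
#' leaves the grid. The two half-tracks are concatenated and streamlines
#' with total arc length outside `[min_len_mm, max_len_mm]` are discarded.
#'
#' Defaults follow standard practice for CC-seeded deterministic tracking:
#' 60 degree angular limit, 10-300 mm length window, threshold 0.6 x Otsu of
#' the positive anisotropy values when not given.
#'
#' @param field an [orientation_field()].
#' @param seeds numeric matrix of seed points in mm (one per row).
#' @param step_mm Euler step, typically half the voxel size.
#' @param angular_limit_deg maximum turning angle between consecutive steps.
#' @param min_len_mm,max_len_mm accepted total streamline length window.
#' @param anisotropy_threshold tracking cutoff; `NULL` uses
#'   `0.6 * otsu_threshold(positive anisotropy)`.
#' @param max_steps per-direction step cap (guards runaway loops).
#' @return A [tractogram()] of the retained streamlines.
#' @export
track_streamlines <- function(field, seeds, step_mm,
                              angular_limit_deg = 60,
                              min_len_mm = 10, max_len_mm = 300,
                              anisotropy_threshold = NULL,
                              max_steps = 2000L) {
  stopifnot(inherits(field, "orientation_field"))
  if (step_mm <= 0) stop("step_mm must be positive")
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 3L) stop("seeds must be an n x 3 matrix of mm points")
  if (is.null(anisotropy_threshold)) {
    fa <- field$anisotropy[field$anisotropy > 0]
    anisotropy_threshold <- 0.6 * otsu_threshold(fa)
  }
  cos_limit <- cos(angular_limit_deg * pi / 180)
  out <- vector("list", nrow(seeds))
  kept <- 0L
  for (s in seq_len(nrow(seeds))) {
    seed_pt <- seeds[s, ]
    vox <- field_lookup(field, seed_pt)
    if (is.null(vox) || vox$fa < anisotropy_threshold) next
    fwd <- track_one_direction(field, seed_pt, vox$dir, step_mm,
                               cos_limit, anisotropy_threshold, max_steps)
    bwd <- track_one_direction(field, seed_pt, -vox$dir, step_mm,
                               cos_limit, anisotropy_threshold, max_steps)
    if (nrow(fwd) + nrow(bwd) < 3L) next        # a lone seed point is not a track
    line <- rbind(bwd[rev(seq_len(nrow(bwd)))[-nrow(bwd)], , drop = FALSE], fwd)
    len <- (nrow(line) - 1L) * step_mm
    if (len < min_len_mm || len > max_len_mm) next
    kept <- kept + 1L
    out[[kept]] <- line
  }
  tractogram(out[seq_len(kept)])
}
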