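#' Configuration for the synthetic dataset generator
#'
#' The defaults describe the stated world the tests run in: two
#' deformed-sphere hemispheres (8,000 triangles each, 16,000 total) flanking
#' a midline corpus-callosum slab, parasagittally concentrated terminations
#' with a modest left-greater-than-right coverage asymmetry, and 17 networks
#' whose callosal crossings follow planted anterior-posterior positions.
#'
#' @param seed integer; one global seed drives every random draw.
#' @param n_streamlines number of synthetic callosal streamlines.
#' @param mesh_triangles_per_hemisphere triangle budget per hemisphere mesh
#'   (even; default 8,000 so both meshes total 16,000).
#' @param parasagittal_sigma mm spread of termination density away from the
#'   midsagittal plane.
#' @param asymmetry left/right ratio of parasagittal spread (> 1 disperses
#'   left-hemisphere terminations more widely, raising left coverage).
#' @param n_networks number of cortical networks planted (default 17).
#' @param network_ap_gradient per-network mean anterior-posterior CC passage
#'   position in 0..1 (0 = anterior); default encodes posterior visual
#'   networks (1, 2), anterior default-mode networks (16, 17) and
#'   intermediate positions for the rest.
#' @param ap_sd spread of each network's passage position (truncated normal;
#'   the default 0.025 keeps ~95% of a network's crossings within a quarter
#'   of one CC fifth of its mean, so a planted anterior network really does
#'   pass anteriorly).
#' @param cc_extent mm triple: CC slab size along x (left-right),
#'   y (anterior-posterior) and z.
#' @param voxel_size mm isotropic voxel size of the CC mask grid.
#' @param hemisphere_offset mm from midline to each hemisphere sphere centre.
#' @param sphere_radius mm nominal hemisphere sphere radius.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_streamlines = 20000L,
                             mesh_triangles_per_hemisphere = 8000L,
                             parasagittal_sigma = 10,
                             asymmetry = 1.2,
                             n_networks = 17L,
                             network_ap_gradient = NULL,
                             ap_sd = 0.025,
                             cc_extent = c(4, 60, 10),
                             voxel_size = 1,
                             hemisphere_offset = 30,
                             sphere_radius = 22) {
  if (is.null(network_ap_gradient)) {
    defaults17 <- c(0.90, 0.85, 0.50, 0.55, 0.70, 0.65, 0.45, 0.40, 0.30,
                    0.15, 0.35, 0.45, 0.20, 0.60, 0.25, 0.15, 0.10)
    network_ap_gradient <- if (n_networks == 17L) defaults17 else
      seq(0.9, 0.1, length.out = n_networks)
  }
  cfg <- list(seed = as.integer(seed),
              n_streamlines = as.integer(n_streamlines),
              mesh_triangles_per_hemisphere = as.integer(mesh_triangles_per_hemisphere),
              parasagittal_sigma = parasagittal_sigma,
              asymmetry = asymmetry,
              n_networks = as.integer(n_networks),
              network_ap_gradient = network_ap_gradient,
              ap_sd = ap_sd,
              cc_extent = cc_extent,
              voxel_size = voxel_size,
              hemisphere_offset = hemisphere_offset,
              sphere_radius = sphere_radius)
  with(cfg, {
    stopifnot(n_streamlines > 0L, mesh_triangles_per_hemisphere > 0L,
              parasagittal_sigma > 0, asymmetry > 0, n_networks > 0L,
              ap_sd > 0, all(cc_extent > 0), voxel_size > 0,
              hemisphere_offset > 0, sphere_radius > 0)
    if (length(network_ap_gradient) != n_networks)
      stop("network_ap_gradient needs one entry per network")
    if (any(network_ap_gradient < 0 | network_ap_gradient > 1))
      stop("network_ap_gradient entries must lie in [0, 1]")
    if (mesh_triangles_per_hemisphere %% 2L != 0L)
      stop("mesh_triangles_per_hemisphere must be even")
  })
  if (cfg$hemisphere_offset - cfg$sphere_radius <= cfg$cc_extent[1] / 2)
    stop("infeasible geometry: CC slab overlaps the hemisphere meshes")
  class(cfg) <- "synthetic_config"
  cfg
}

# UV-sphere triangulation hitting the requested triangle count exactly when
# n_tri/2 admits a divisor; n_lon is the divisor of n_tri/2 closest to
# sqrt(n_tri) (keeps the aspect ratio sane).
uv_sphere_mesh <- function(n_tri, centre, radius, medial_sign) {
  half <- n_tri %/% 2L
  divs <- which(half %% seq_len(half) == 0L)
  n_lon <- divs[which.min(abs(divs - sqrt(n_tri)))]
  n_bands <- half %/% n_lon + 1L
  if (n_lon < 3L || n_bands < 3L)
    stop(sprintf("cannot triangulate a sphere with %d triangles", n_tri))
  # poles on the x axis; the medial pole faces the midline
  theta <- seq(0, pi, length.out = n_bands + 1L)[2:n_bands]   # ring polar angles
  phi <- seq(0, 2 * pi, length.out = n_lon + 1L)[seq_len(n_lon)]
  g <- expand.grid(phi = phi, theta = theta)
  # smooth deterministic deformation so the mesh is not a perfect sphere
  rfun <- function(th, ph) radius * (1 + 0.06 * sin(3 * th) * cos(2 * ph) +
                                       0.04 * cos(5 * ph) * sin(th))
  r <- rfun(g$theta, g$phi)
  # x along the pole axis (medial pole at theta = 0), y/z in the ring plane
  vx <- centre[1L] + r * medial_sign * cos(g$theta)
  vy <- centre[2L] + r * sin(g$theta) * cos(g$phi)
  vz <- centre[3L] + r * sin(g$theta) * sin(g$phi)
  pole_n <- centre + c(medial_sign * radius, 0, 0)            # theta = 0 pole
  pole_s <- centre + c(-medial_sign * radius, 0, 0)
  vertices <- rbind(pole_n, cbind(vx, vy, vz), pole_s)
  dimnames(vertices) <- NULL
  ring <- function(b) 1L + (b - 1L) * n_lon + seq_len(n_lon)  # vertex ids of ring b
  tris <- vector("list", n_bands)
  r1 <- ring(1L)
  tris[[1L]] <- cbind(1L, r1, r1[c(2:n_lon, 1L)])
  for (b in seq_len(n_bands - 2L)) {
    a <- ring(b); d <- ring(b + 1L)
    a2 <- a[c(2:n_lon, 1L)]; d2 <- d[c(2:n_lon, 1L)]
    tris[[b + 1L]] <- rbind(cbind(a, d, d2), cbind(a, d2, a2))
  }
  last <- ring(n_bands - 1L)
  pole_s_id <- nrow(vertices)
  tris[[n_bands]] <- cbind(pole_s_id, last[c(2:n_lon, 1L)], last)
  triangles <- do.call(rbind, tris)
  list(vertices = vertices, triangles = triangles,
       vertex_theta = c(0, g$theta, pi), vertex_phi = c(0, g$phi, 0),
       n_lon = n_lon, n_bands = n_bands)
}

# truncated-normal draw on [0,1] via inverse-CDF (vectorised, no rejection)
rtruncnorm01 <- function(n, mean, sd) {
  plo <- stats::pnorm(0, mean, sd)
  phi <- stats::pnorm(1, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), 0), 1)
}

# anterior-position -> segment label: label 1 is the anterior fifth; points
# exactly on an interior bin edge go to the more anterior bin.
ap_to_segment <- function(a, k) pmax(1L, as.integer(ceiling(a * k)))

# Compact independent tally used only to PLANT ground-truth summaries; the
# pipeline recovers the same quantities through its own code path.
plant_involvement <- function(vertex_counts, triangles) {
  cm <- matrix(vertex_counts[triangles], ncol = 3L)
  med <- pmax(pmin(cm[, 1L], cm[, 2L]), pmin(cm[, 1L], cm[, 3L]), pmin(cm[, 2L], cm[, 3L]))
  med >= 1L
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Builds two hemisphere meshes flanking a midline CC slab, a contiguous
#' longitude-band network parcellation, and `n_streamlines` callosal
#' streamlines. Each streamline joins a left-surface point to a
#' right-surface point through one CC passage position drawn from its
#' network's anterior-posterior distribution; termination vertices are drawn
#' with density proportional to exp(-x^2 / (2 sigma_h^2)) where `x` is the
#' distance from the midsagittal plane and `sigma_left = asymmetry * sigma`.
#' Every planted quantity downstream analyses should recover is recorded in
#' `$ground_truth`. A given seed reproduces the bundle bit-identically.
#'
#' @param config a [synthetic_config()].
#' @return list with `surfaces` (left/right [cortical_surface()]), `mask`
#'   ([volume_mask()]), `labels` ([label_table()]), `tractogram`
#'   ([tractogram()]) and `ground_truth`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- 5L
  nn <- config$n_networks

  ## hemisphere meshes ------------------------------------------------------
  mk_hemi <- function(sign, hemisphere) {
    m <- uv_sphere_mesh(config$mesh_triangles_per_hemisphere,
                        centre = c(sign * config$hemisphere_offset, 0, 0),
                        radius = config$sphere_radius,
                        medial_sign = -sign)
    surf <- cortical_surface(m$vertices, m$triangles, hemisphere)
    list(surf = surf, theta = m$vertex_theta, phi = m$vertex_phi)
  }
  left <- mk_hemi(-1, "left")
  right <- mk_hemi(+1, "right")

  ## parcellation: longitude bands around the medial-lateral axis.
  ## Vertices take the band of their own phi (0 on the medial-wall cap and at
  ## the poles); a triangle takes a network label only when all three of its
  ## vertices share it, so straddling triangles stay unassigned and every
  ## network's involvement is exactly attributable to its own streamlines.
  band_of <- function(phi) pmin(nn, 1L + as.integer(floor(phi / (2 * pi) * nn)))
  vert_label <- function(h) {
    lab <- band_of(h$phi %% (2 * pi))
    lab[h$theta < (15 * pi / 180)] <- 0L          # medial wall cap unassigned
    lab[c(1L, length(lab))] <- 0L                 # poles
    lab
  }
  vl_left <- vert_label(left)
  vl_right <- vert_label(right)
  tri_label <- function(h, vlab) {
    lm <- matrix(vlab[h$surf$triangles], ncol = 3L)
    out <- lm[, 1L]
    out[lm[, 1L] != lm[, 2L] | lm[, 1L] != lm[, 3L]] <- 0L
    out
  }
  labels <- label_table(tri_label(left, vl_left), tri_label(right, vl_right))

  ## CC slab mask -----------------------------------------------------------
  vs <- config$voxel_size
  dims <- as.integer(round(config$cc_extent / vs))
  if (any(dims < 1L)) stop("cc_extent smaller than one voxel")
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4L] <- -config$cc_extent / 2 + vs / 2
  ijk <- as.matrix(expand.grid(i = 0:(dims[1L] - 1L),
                               j = 0:(dims[2L] - 1L),
                               k = 0:(dims[3L] - 1L)))
  dimnames(ijk) <- NULL
  mask <- volume_mask(dims, affine, ijk)
  y_centres <- affine[2L, 4L] + (0:(dims[2L] - 1L)) * vs
  y_min <- min(y_centres); y_max <- max(y_centres)

  ## streamlines ------------------------------------------------------------
  n <- config$n_streamlines
  net <- sample.int(nn, n, replace = TRUE)
  t_pos <- rtruncnorm01(n, config$network_ap_gradient[net], config$ap_sd)
  # snap passage to a voxel-centre y; anterior (a = 0) is max y
  y_pass <- y_max - t_pos * (y_max - y_min)
  jy <- round((y_pass - affine[2L, 4L]) / vs)
  y_pass <- affine[2L, 4L] + jy * vs
  a_pos <- (y_max - y_pass) / (y_max - y_min)
  seg <- ap_to_segment(a_pos, k)
  # passage z: a central voxel-centre z
  kz_mid <- (dims[3L] - 1L) %/% 2L
  kz <- pmax(0L, pmin(dims[3L] - 1L, kz_mid + sample(-1:1, n, replace = TRUE)))
  z_pass <- affine[3L, 4L] + kz * vs

  draw_vertex <- function(h, vlab, sigma) {
    v <- h$surf$vertices
    w_all <- exp(-v[, 1L]^2 / (2 * sigma^2))
    idx_net <- split(seq_len(nrow(v)), vlab)
    picks <- integer(n)
    for (g in as.character(seq_len(nn))) {
      rows <- which(net == as.integer(g))
      cand <- idx_net[[g]]
      if (length(rows) == 0L) next
      if (is.null(cand) || length(cand) == 0L)
        stop("network with no candidate vertices; increase mesh resolution")
      picks[rows] <- cand[sample.int(length(cand), length(rows), replace = TRUE,
                                     prob = w_all[cand])]
    }
    picks
  }
  sig_l <- config$asymmetry * config$parasagittal_sigma
  sig_r <- config$parasagittal_sigma
  v_left <- draw_vertex(left, vl_left, sig_l)
  v_right <- draw_vertex(right, vl_right, sig_r)

  # endpoint = intended vertex displaced 0.3 mm radially outward, so the
  # nearest-vertex assignment is unambiguous but distances are non-zero
  outward <- function(h, vid) {
    ctr <- colMeans(h$surf$vertices)
    p <- h$surf$vertices[vid, , drop = FALSE]
    d <- p - rep(ctr, each = length(vid))
    p + 0.3 * d / sqrt(rowSums(d * d))
  }
  ep_l <- outward(left, v_left)
  ep_r <- outward(right, v_right)

  half_x <- config$cc_extent[1L] / 2
  streamlines <- vector("list", n)
  x_cross <- affine[1L, 4L] + (0:(dims[1L] - 1L)) * vs   # slab voxel-centre x
  for (i in seq_len(n)) {
    entry <- c(-(half_x + 1), y_pass[i], z_pass[i])
    exit <- c(half_x + 1, y_pass[i], z_pass[i])
    mids <- cbind(x_cross, y_pass[i], z_pass[i])
    streamlines[[i]] <- rbind(ep_l[i, ],
                              (ep_l[i, ] + entry) / 2,
                              entry, mids, exit,
                              (ep_r[i, ] + exit) / 2,
                              ep_r[i, ])
  }
  tract <- tractogram(streamlines)

  ## planted ground truth ---------------------------------------------------
  nv_l <- nrow(left$surf$vertices); nv_r <- nrow(right$surf$vertices)
  cnt_l <- tabulate(v_left, nbins = nv_l)
  cnt_r <- tabulate(v_right, nbins = nv_r)
  inv_l <- plant_involvement(cnt_l, left$surf$triangles)
  inv_r <- plant_involvement(cnt_r, right$surf$triangles)
  coverage <- c(left = mean(inv_l), right = mean(inv_r))

  involvement_from <- function(keep) {
    cl <- tabulate(v_left[keep], nbins = nv_l)
    cr <- tabulate(v_right[keep], nbins = nv_r)
    il <- plant_involvement(cl, left$surf$triangles)
    ir <- plant_involvement(cr, right$surf$triangles)
    vapply(seq_len(nn), function(g) {
      sel <- c(il[labels$left == g], ir[labels$right == g])
      if (length(sel) == 0L) NA_real_ else mean(sel)
    }, numeric(1L))
  }
  involvement <- involvement_from(rep(TRUE, n))
  extents <- seq_len(k) / k
  disruption <- vapply(seq_len(k), function(j) involvement_from(seg <= j),
                       numeric(nn))
  dimnames(disruption) <- list(paste0("network_", seq_len(nn)),
                               sprintf("extent_%g", extents))

  ground_truth <- list(
    per_streamline = data.frame(network = net,
                                left_vertex = v_left, right_vertex = v_right,
                                passage_pos = a_pos, segment = seg),
    coverage = coverage,
    involvement = stats::setNames(involvement, paste0("network_", seq_len(nn))),
    disruption = disruption,
    extents = extents,
    n_voxels = nrow(ijk),
    config = unclass(config))

  list(surfaces = list(left = left$surf, right = right$surf),
       mask = mask, labels = labels, tractogram = tract,
       ground_truth = ground_truth)
}

#' Write a generated bundle to disk in the pipeline's external formats
#'
#' Surfaces as OFF, tractogram as TCK, CC mask as NIfTI, labels as plain
#' text, ground truth as JSON, plus the default 17-to-7 mapping CSV.
#'
#' @param bundle result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_surface(bundle$surfaces$left, file.path(dir, "surface_left.off"))
  write_surface(bundle$surfaces$right, file.path(dir, "surface_right.off"))
  write_tractogram(bundle$tractogram, file.path(dir, "tractogram.tck"))
  write_mask(bundle$mask, file.path(dir, "cc_mask.nii"))
  write_labels(bundle$labels, file.path(dir, "labels_left.txt"),
               file.path(dir, "labels_right.txt"))
  file.copy(system.file("extdata", "yeo17_to_yeo7_default.csv",
                        package = "transcallosal", mustWork = TRUE),
            file.path(dir, "mapping_17_to_7.csv"), overwrite = TRUE)
  gt <- bundle$ground_truth
  gt$disruption <- as.data.frame(gt$disruption)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
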