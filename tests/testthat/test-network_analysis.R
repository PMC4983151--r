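make_fields <- function(bundle, streamline_ids = NULL) {
  a <- assign_endpoints(bundle$tractogram, bundle$surfaces)
  if (!is.null(streamline_ids))
    a <- transcallosal:::restrict_assignment(a, streamline_ids)
  list(assignment = a,
       fields = list(left = triangle_counts(a, bundle$surfaces$left),
                     right = triangle_counts(a, bundle$surfaces$right)))
}

test_that("network involvement: trivial extremes and missing networks", {
  b <- small_bundle(seed = 51, n_streamlines = 800)
  mf <- make_fields(b, integer(0))               # no endpoints at all
  inv0 <- network_involvement(mf$fields, b$labels)
  expect_true(all(inv0 == 0))
  # all vertices loaded: every labelled triangle involved
  full <- mf$assignment
  full$vertex_counts <- rep(1L, length(full$vertex_counts))
  ff <- list(left = triangle_counts(full, b$surfaces$left),
             right = triangle_counts(full, b$surfaces$right))
  expect_true(all(network_involvement(ff, b$labels) == 1))
  # a label absent from both hemispheres reports NA, not 0
  lab2 <- b$labels
  lab2$left[lab2$left == 9L] <- 0L
  lab2$right[lab2$right == 9L] <- 0L
  inv <- network_involvement(ff, lab2)
  expect_true(is.na(inv["network_9"]))
})

test_that("recovered involvement matches planted ground truth within 3 SE", {
  b <- small_bundle(seed = 52, n_streamlines = 5000)
  mf <- make_fields(b)
  inv <- network_involvement(mf$fields, b$labels)
  gt <- b$ground_truth$involvement
  ntri <- vapply(1:17, function(g) sum(b$labels$left == g) + sum(b$labels$right == g),
                 integer(1L))
  for (g in 1:17)
    expect_lt(abs(inv[g] - gt[g]), tol3se(gt[g], ntri[g]) + 1e-12)
})

test_that("profile identity: extent 1.0 equals full involvement; extent checks", {
  b <- small_bundle(seed = 53, n_streamlines = 1500)
  seg <- segment_cc(b$mask, 5L)
  ss <- streamline_segments(b$tractogram, seg, b$mask)
  mf <- make_fields(b)
  prof <- callosotomy_profile(mf$assignment, ss, b$labels, b$surfaces)
  inv <- network_involvement(mf$fields, b$labels)
  expect_identical(unname(unclass(prof)[, 5L]), unname(inv))
  expect_error(callosotomy_profile(mf$assignment, ss, b$labels, b$surfaces,
                                   extents = c(0.3)), "granularity")
  # monotone along extents, and within planted tolerance everywhere
  expect_true(all(apply(unclass(prof), 1L, function(r) all(diff(r) >= -1e-12))))
  gt <- b$ground_truth$disruption
  expect_equal(dim(unclass(prof)), dim(gt))
  expect_lt(max(abs(unclass(prof) - gt), na.rm = TRUE), 0.05)
})

test_that("aggregation: pooled involvement is the triangle-weighted mean over networks", {
  b <- small_bundle(seed = 54, n_streamlines = 1000)
  mf <- make_fields(b)
  inv <- network_involvement(mf$fields, b$labels)
  ntri <- vapply(1:17, function(g) sum(b$labels$left == g) + sum(b$labels$right == g),
                 numeric(1L))
  lab_all <- c(b$labels$left, b$labels$right)
  inv_all <- c(transcallosal:::triangle_involved(mf$fields$left),
               transcallosal:::triangle_involved(mf$fields$right))
  pooled <- mean(inv_all[lab_all > 0L])
  expect_equal(sum(inv * ntri) / sum(ntri), pooled)
})

test_that("17-to-7 downsampling is a weight-normalised average", {
  # identity mapping: values pass through
  v <- matrix(runif(17 * 5), 17, 5)
  prof <- vulnerability_profile(v, paste0("network_", 1:17), (1:5) / 5)
  ident <- data.frame(network17 = 1:17, network7 = c(1:7, rep(7, 10)), weight = 1)
  # restrict to a true one-to-one case for the pass-through check
  one <- data.frame(network17 = 1:17, network7 = 1:17, weight = 1)
  p7 <- downsample_17_to_7(prof, one)
  expect_equal(unname(unclass(p7)), unname(unclass(prof)))

  # Visual fed by networks 1 and 2 equally: 0.2 and 0.4 average to 0.3
  v2 <- v; v2[1L, ] <- 0.2; v2[2L, ] <- 0.4
  prof2 <- vulnerability_profile(v2, paste0("network_", 1:17), (1:5) / 5)
  p7b <- downsample_17_to_7(prof2, read_network_mapping())
  expect_equal(unname(unclass(p7b)["Visual", ]), rep(0.3, 5))

  # random weights equal the explicit sum(w v) / sum(w)
  set.seed(99)
  map <- data.frame(network17 = 1:17,
                    network7 = sample(1:7, 17, replace = TRUE),
                    weight = runif(17, 0.2, 2))
  map$weight <- map$weight / ave(map$weight, map$network17, FUN = sum)
  p7c <- downsample_17_to_7(prof, map)
  for (t in sort(unique(map$network7))) {
    rows <- map$network7 == t
    expected <- colSums(map$weight[rows] * v[map$network17[rows], , drop = FALSE]) /
      sum(map$weight[rows])
    got <- unclass(p7c)[match(t, sort(unique(map$network7))), ]
    expect_equal(unname(got), unname(expected))
    # bounds: each 7-network value inside [min, max] of its contributors
    expect_true(all(got >= apply(v[map$network17[rows], , drop = FALSE], 2L, min) - 1e-12))
    expect_true(all(got <= apply(v[map$network17[rows], , drop = FALSE], 2L, max) + 1e-12))
  }
})

test_that("spearman: trivial cases, tie handling vs oracle, constant input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_reproducibility(x, x)$rho, 1)
  expect_equal(spearman_reproducibility(x, rev(x))$rho, -1)
  expect_equal(spearman_reproducibility(x, x)$p_value, 0)
  set.seed(7)
  for (i in 1:20) {
    a <- rpois(50, 2); b <- rpois(50, 2)        # heavy ties, like triangle counts
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) next
    r <- spearman_reproducibility(a, b)
    expect_equal(r$rho, oracle_spearman(a, b), tolerance = 1e-12)
    expect_equal(r$rho, suppressWarnings(stats::cor(a, b, method = "spearman")),
                 tolerance = 1e-12)
    # p-value follows the documented t-approximation
    tt <- r$rho * sqrt((r$n - 2) / (1 - r$rho^2))
    expect_equal(r$p_value, 2 * stats::pt(-abs(tt), r$n - 2))
  }
  const <- spearman_reproducibility(rep(2, 10), rnorm(10))
  expect_true(is.na(const$rho))
  expect_match(const$note, "constant")
  expect_error(spearman_reproducibility(1:4, 1:5), "equal length")
})

test_that("fibre-fraction variant is monotone and complete at full resection", {
  b <- small_bundle(seed = 55, n_streamlines = 800)
  seg <- segment_cc(b$mask, 5L)
  ss <- streamline_segments(b$tractogram, seg, b$mask)
  a <- assign_endpoints(b$tractogram, b$surfaces)
  fp <- fibre_fraction_profile(a, ss, b$labels, b$surfaces)
  expect_true(all(apply(unclass(fp), 1L, function(r) all(diff(r) >= -1e-12)), na.rm = TRUE))
  expect_true(all(unclass(fp)[, 5L] == 1, na.rm = TRUE))
})
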