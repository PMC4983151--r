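test_that("identical seeds give bit-identical bundles, different seeds differ", {
  a <- small_bundle(seed = 9, n_streamlines = 300)
  b <- small_bundle(seed = 9, n_streamlines = 300)
  expect_identical(a$tractogram, b$tractogram)
  expect_identical(a$ground_truth$per_streamline, b$ground_truth$per_streamline)
  expect_identical(a$labels, b$labels)
  c <- small_bundle(seed = 10, n_streamlines = 300)
  expect_false(identical(a$tractogram, c$tractogram))
})

test_that("config validation rejects infeasible worlds", {
  expect_error(synthetic_config(n_streamlines = 0), "n_streamlines")
  expect_error(synthetic_config(network_ap_gradient = rep(0.5, 3)),
               "one entry per network")
  expect_error(synthetic_config(network_ap_gradient = c(rep(0.5, 16), 1.2)),
               "0, 1")
  expect_error(synthetic_config(hemisphere_offset = 5, sphere_radius = 22),
               "infeasible geometry")
  expect_error(synthetic_config(mesh_triangles_per_hemisphere = 8001L), "even")
})

test_that("symmetry limit: asymmetry 1 and huge sigma equalise hemisphere coverage", {
  b <- generate_dataset(synthetic_config(seed = 21, n_streamlines = 20000,
                                         asymmetry = 1, parasagittal_sigma = 1e6))
  gt <- b$ground_truth
  expect_lt(abs(gt$coverage["left"] - gt$coverage["right"]), 0.02)
})

test_that("default world plants left > right coverage and parasagittal concentration", {
  b <- generate_dataset(synthetic_config(seed = 22, n_streamlines = 20000))
  expect_gt(b$ground_truth$coverage["left"], b$ground_truth$coverage["right"])
  ep <- streamline_endpoints(b$tractogram)
  # termination density concentrates toward the midline: the median |x| of
  # endpoints is well inside the medial half of each hemisphere sphere
  expect_lt(stats::median(abs(ep$points[, 1])), 30)
})

test_that("ground truth is internally consistent and anterior networks disrupt early", {
  b <- small_bundle(seed = 23, n_streamlines = 5000)
  gt <- b$ground_truth
  # disruption curves non-decreasing, final column equals involvement
  expect_true(all(apply(gt$disruption, 1, function(r) all(diff(r) >= -1e-12))))
  expect_equal(gt$disruption[, ncol(gt$disruption)], gt$involvement,
               ignore_attr = TRUE)
  # recompute disruption at 20% from per-streamline records (independent route)
  ps <- gt$per_streamline
  grad <- b$ground_truth$config$network_ap_gradient
  ant <- which.min(grad)                        # most anterior network
  cut20 <- ps$segment <= 1L
  frac_cut <- mean(cut20[ps$network == ant])
  expect_gt(frac_cut, 0.9)
  expect_gt(gt$disruption[ant, 1L], 0.9 * gt$involvement[ant])
})

test_that("every generated streamline crosses the CC mask in its planted segment", {
  b <- small_bundle(seed = 24, n_streamlines = 500)
  seg <- segment_cc(b$mask, 5L)
  ss <- streamline_segments(b$tractogram, seg, b$mask)
  expect_true(all(ss$callosal))
  expect_identical(ss$anterior_most, b$ground_truth$per_streamline$segment)
  # single-segment passages only, by construction
  expect_true(all(lengths(ss$sets) == 1L))
})

test_that("otsu threshold separates classes and matches the brute-force oracle", {
  v <- c(0, 0, 0, 10, 10, 10)
  t0 <- otsu_threshold(v, 256L)
  expect_gt(t0, 0); expect_lt(t0, 10)
  expect_equal(stats::var(v[v < t0]), 0)
  expect_equal(stats::var(v[v >= t0]), 0)

  set.seed(42)
  for (i in 1:5) {
    mix <- c(rnorm(300, 2, 0.5), rnorm(200, 9, 0.8))
    mix <- mix[mix > 0]
    expect_equal(otsu_threshold(mix, 128L), oracle_otsu(mix, 128L))
  }
  expect_error(otsu_threshold(rep(3, 10)), "distinct")
})

test_that("tracker: uniform field gives exact fixed-step collinear polylines", {
  dim <- c(30L, 5L, 5L)
  dirs <- array(0, c(dim, 3L)); dirs[, , , 1L] <- 1
  fa <- array(1, dim)
  f <- orientation_field(dim, diag(4), dirs, fa)
  tr <- track_streamlines(f, rbind(c(15, 2, 2)), step_mm = 1,
                          min_len_mm = 10, max_len_mm = 300,
                          anisotropy_threshold = 0.5)
  expect_length(tr, 1L)
  s <- tr$streamlines[[1L]]
  steps <- sqrt(rowSums(diff(s)^2))
  expect_equal(steps, rep(1, nrow(s) - 1L))
  expect_true(all(abs(s[, 2L] - 2) < 1e-12) && all(abs(s[, 3L] - 2) < 1e-12))
  # bidirectional: spans the grid on both sides of the seed
  expect_lt(min(s[, 1L]), 1); expect_gt(max(s[, 1L]), 29)
})

test_that("tracker terminates at a 90-degree field discontinuity under the 60-degree rule", {
  dim <- c(40L, 40L, 3L)
  dirs <- array(0, c(dim, 3L))
  dirs[1:20, , , 1L] <- 1                      # +x on the left half
  dirs[21:40, , , 2L] <- 1                     # +y on the right half
  fa <- array(1, dim)
  f <- orientation_field(dim, diag(4), dirs, fa)
  tr <- track_streamlines(f, rbind(c(5, 20, 1)), step_mm = 1,
                          angular_limit_deg = 60,
                          min_len_mm = 10, max_len_mm = 300,
                          anisotropy_threshold = 0.5)
  s <- tr$streamlines[[1L]]
  expect_lt(max(s[, 1L]), 21)                  # never proceeds into the +y region
  expect_true(all(abs(s[, 2L] - 20) < 1e-12))  # and never turned
  # with a permissive angular limit the track does turn the corner
  tr2 <- track_streamlines(f, rbind(c(5, 20, 1)), step_mm = 1,
                           angular_limit_deg = 120,
                           min_len_mm = 10, max_len_mm = 300,
                           anisotropy_threshold = 0.5)
  expect_gt(max(tr2$streamlines[[1L]][, 2L]), 21)
})

test_that("tracker length window and anisotropy threshold drop streamlines", {
  dim <- c(8L, 3L, 3L)
  dirs <- array(0, c(dim, 3L)); dirs[, , , 1L] <- 1
  fa <- array(1, dim)
  f <- orientation_field(dim, diag(4), dirs, fa)
  # grid only allows ~7 mm of track: below the 10 mm minimum
  tr <- track_streamlines(f, rbind(c(4, 1, 1)), step_mm = 1,
                          min_len_mm = 10, max_len_mm = 300,
                          anisotropy_threshold = 0.5)
  expect_length(tr, 0L)
  # max length cap
  dim2 <- c(400L, 3L, 3L)
  dirs2 <- array(0, c(dim2, 3L)); dirs2[, , , 1L] <- 1
  f2 <- orientation_field(dim2, diag(4), dirs2, array(1, dim2))
  tr2 <- track_streamlines(f2, rbind(c(200, 1, 1)), step_mm = 1,
                           min_len_mm = 10, max_len_mm = 300,
                           anisotropy_threshold = 0.5)
  expect_length(tr2, 0L)
  # anisotropy gate stops tracking where fa drops
  fa3 <- array(1, dim2); fa3[216:400, , ] <- 0.1
  f3 <- orientation_field(dim2, diag(4), dirs2, fa3)
  tr3 <- track_streamlines(f3, rbind(c(200, 1, 1)), step_mm = 1,
                           min_len_mm = 10, max_len_mm = 300,
                           anisotropy_threshold = 0.5)
  expect_length(tr3, 1L)
  expect_lt(max(tr3$streamlines[[1L]][, 1L]), 216)
})

test_that("tracked streamlines seeded in a left-right field cross the CC mask", {
  b <- small_bundle(seed = 25, n_streamlines = 10)
  mask <- b$mask
  dim <- c(80L, 60L, 10L)
  aff <- diag(4); aff[1:3, 4L] <- c(-40, -30, -5) + 0.5
  dirs <- array(0, c(dim, 3L)); dirs[, , , 1L] <- 1
  f <- orientation_field(dim, aff, dirs, array(1, dim))
  set.seed(1)
  seeds <- cbind(runif(20, -1, 1), runif(20, -25, 25), runif(20, -4, 4))
  tr <- track_streamlines(f, seeds, step_mm = 0.5, min_len_mm = 10,
                          max_len_mm = 300, anisotropy_threshold = 0.5)
  expect_gt(length(tr), 0L)
  seg <- segment_cc(mask, 5L)
  ss <- streamline_segments(tr, seg, mask)
  expect_true(all(ss$callosal))
  # fixed-step contract across every tracked streamline
  for (s in tr$streamlines)
    expect_equal(sqrt(rowSums(diff(s)^2)), rep(0.5, nrow(s) - 1L))
})
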