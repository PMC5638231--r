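test_that("Gaussian blur preserves constants, mass, and the impulse response", {
  const <- matrix(500, 20, 20)
  expect_equal(gaussian_blur(const, 1), const, tolerance = 1e-12)

  # interior-supported blob: total intensity preserved (kernel normalization)
  blob <- matrix(0, 40, 40)
  blob[18:22, 18:22] <- 1000
  expect_equal(sum(gaussian_blur(blob, 1.5)), sum(blob),
               tolerance = 1e-6 * sum(blob))

  # unit impulse, sigma = 1: centre value of the truncated discrete kernel
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  k1 <- naive_gauss_kernel_1d(1)
  centre <- k1[ceiling(length(k1) / 2)]^2
  out <- gaussian_blur(imp, 1)
  expect_equal(out[21, 21], centre, tolerance = 1e-12)
  expect_equal(out[21, 21], 1 / (2 * pi), tolerance = 1e-3)

  expect_error(gaussian_blur(const, 0), "positive")
})

test_that("Gaussian blur agrees with a naive full-kernel convolution", {
  set.seed(7)
  m <- matrix(runif(15 * 18, 0, 1000), 15, 18)
  for (sigma in c(0.8, 1, 2))
    expect_equal(gaussian_blur(m, sigma), naive_gaussian_blur(m, sigma),
                 tolerance = 1e-9)
})

test_that("Sobel magnitude matches the hand-derived step and ramp responses", {
  expect_true(all(sobel_magnitude(matrix(77, 10, 10)) == 0))

  # vertical step of height 100 between columns 5 and 6
  step <- matrix(0, 9, 10); step[, 6:10] <- 100
  g <- sobel_magnitude(step)
  expect_true(all(abs(g[, 5:6] - 400) < 1e-9))
  expect_true(all(abs(g[, c(1:4, 7:10)]) < 1e-9))

  # linear ramp plane(r, c) = c * k: interior magnitude uniformly 8k, Gy = 0
  k <- 3.5
  ramp <- matrix(rep((1:12) * k, each = 10), 10, 12)
  g2 <- sobel_magnitude(ramp)
  expect_true(all(abs(g2[, 2:11] - 8 * k) < 1e-9))

  expect_error(sobel_magnitude(matrix(1, 2, 5)), "3x3")
})

test_that("Sobel magnitude agrees with a naive double-loop convolution", {
  set.seed(8)
  m <- matrix(runif(14 * 13, 0, 255), 14, 13)
  expect_equal(sobel_magnitude(m), naive_sobel(m), tolerance = 1e-9)
})

test_that("segmentation thresholds, fills holes, and keeps the largest 8-connected component", {
  disk <- disk_plane(n = 31L, r = 10, value = 500L)
  seg <- segment_nucleus(disk, 200L)
  expect_equal(seg$area_px, sum(disk$pixels > 200L))
  expect_identical(matrix(seg$mask, 31, 31), disk$pixels > 200L)

  # bright ring with dark centre: the hole is filled by definition
  ring <- disk_plane(n = 31L, r = 10, value = 500L)
  inner <- disk_plane(n = 31L, r = 5, value = 1L)
  px <- ring$pixels; px[inner$pixels > 0L] <- 0L
  ring <- image_plane(px, bit_depth = 16L)
  seg_ring <- segment_nucleus(ring, 200L)
  expect_equal(seg_ring$area_px, seg$area_px)   # filled back to the full disk

  # two disks: only the larger one survives
  two <- matrix(0L, 41, 61)
  big <- disk_plane(n = 41L, r = 9, value = 400L, centre = c(21, 15))$pixels
  small <- disk_plane(n = 41L, r = 5, value = 400L, centre = c(21, 15))$pixels
  two[, 1:41] <- pmax(two[, 1:41], big)
  two[, 21:61] <- pmax(two[, 21:61], small)
  p2 <- image_plane(two, bit_depth = 16L)
  seg2 <- segment_nucleus(p2, 100L)
  expect_equal(seg2$area_px, sum(big > 100L))
  expect_identical(seg2$mask, naive_largest_component8(
    naive_fill_holes(two > 100L)))
})

test_that("diagonally touching blobs form one 8-connected component", {
  m <- matrix(0L, 12, 12)
  m[2:5, 2:5] <- 300L
  m[6:9, 6:9] <- 300L   # touches the first block only at the (5,5)/(6,6) corner
  p <- image_plane(m, bit_depth = 16L)
  seg <- segment_nucleus(p, 100L)
  expect_equal(seg$area_px, 32L)   # both blocks kept as one component
})

test_that("condensation index hits its analytic bounds on uniform and saturated nuclei", {
  disk <- disk_plane(n = 41L, r = 12, value = 30000L)
  # uniform nucleus: once the erosion covers the blur support (4 sigma + 1
  # for the Sobel neighbourhood), the interior gradient is exactly 0 and the
  # index is 0 at any positive edge threshold — the rim never counts
  rec <- condensation_index(disk, 200L, edge_threshold = 1e-6,
                            analysis_params(boundary_erosion_px = 5L))
  expect_equal(rec$edge_px, 0L)
  expect_equal(rec$condensation_index, 0)
  expect_false(rec$empty)

  # every interior pixel above threshold: index exactly 1
  rec1 <- condensation_index(disk, 200L, edge_threshold = -1)
  expect_equal(rec1$condensation_index, 1)

  # empty interior: flagged, no division
  dark <- image_plane(matrix(0L, 10, 10), bit_depth = 16L)
  rec2 <- condensation_index(dark, 200L, edge_threshold = 1)
  expect_true(rec2$empty)
  expect_true(is.na(rec2$condensation_index))
  expect_equal(rec2$nuclear_area_px, 0L)
})

test_that("condensation index agrees with the independent step-by-step oracle", {
  model <- nucleus_model(radius_px = 16, n_foci = 5L, seed = 42L)
  plane <- make_nucleus_plane(model, c(60, 60))
  params <- analysis_params()
  for (th in list(c(5000, 8000), c(9000, 15000))) {
    got <- condensation_index(plane, th[1], th[2], params)
    ref <- naive_condensation_index(plane, th[1], th[2], sigma = 1,
                                    erosion_px = 1L)
    expect_equal(got$nuclear_area_px, ref$area)
    expect_equal(got$edge_px, ref$edge_px)
    expect_equal(got$condensation_index, ref$index, tolerance = 1e-9)
  }
})

test_that("dataset analysis applies one threshold pair everywhere and is order invariant", {
  ds <- tiny_dataset(seed = 11L, n_planes = 3L)
  res <- analyze_dataset(ds)
  th <- attr(res, "thresholds")
  for (r in res) expect_identical(r$thresholds_used, th)

  perm <- chrom_dataset(rev(ds$stacks))
  res2 <- analyze_dataset(perm)
  expect_identical(attr(res2, "thresholds"), th)
  for (id in c("lo", "hi")) {
    a <- res[[which(vapply(res, function(r) r$stack_id, character(1)) == id)]]
    b <- res2[[which(vapply(res2, function(r) r$stack_id, character(1)) == id)]]
    expect_equal(a$records, b$records)
    expect_equal(a$aggregate_index, b$aggregate_index)
  }

  # per-stack aggregate is the ratio of sums over non-empty planes
  r1 <- res[[1]]$records
  expect_equal(res[[1]]$aggregate_index,
               sum(r1$edge_px[!r1$empty]) / sum(r1$nuclear_area_px[!r1$empty]))
})

test_that("an all-zero dataset aborts naming its root", {
  p <- image_plane(matrix(0L, 8, 8), bit_depth = 16L)
  ds <- chrom_dataset(list(image_stack(list(p), "s")), root = NULL)
  expect_error(analyze_dataset(ds), "empty histogram")
})

test_that("group summary computes mean and standard error and survives relabeling", {
  mk <- function(id, idx) stack_result(
    id, data.frame(plane_index = 0L, nuclear_area_px = 100L,
                   edge_px = as.integer(idx * 100), condensation_index = idx,
                   empty = FALSE), c(intensity = 1, edge = 1))
  res <- list(mk("a1", 0.2), mk("a2", 0.4), mk("b1", 0.5))
  s <- summarize_groups(res, c(a1 = "g1", a2 = "g1", b1 = "g2"))
  g1 <- s[s$group == "g1", ]
  expect_equal(g1$n, 2L)
  expect_equal(g1$mean_index, 0.3)
  expect_equal(g1$se, 0.1)

  s2 <- summarize_groups(res, c(a1 = "x", a2 = "x", b1 = "y"))
  expect_equal(s2$mean_index[order(s2$group)], s$mean_index[order(s$group)])
  expect_equal(s2$se[order(s2$group)], s$se[order(s$group)])
})
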