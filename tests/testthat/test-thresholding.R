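test_that("pooled histogram counts non-zero pixels across planes and is additive", {
  p1 <- image_plane(rbind(c(0L, 5L, 5L), c(10L, 0L, 0L), c(0L, 0L, 0L)),
                    bit_depth = 8L)
  p2 <- image_plane(rbind(c(10L, 10L, 0L), c(0L, 0L, 0L), c(0L, 0L, 0L)),
                    bit_depth = 8L)
  ds <- chrom_dataset(list(image_stack(list(p1), "a"),
                           image_stack(list(p2), "b")))
  h <- pooled_histogram(ds)
  expect_equal(h$counts[1], 0)          # zeros excluded
  expect_equal(h$counts[5 + 1], 2)
  expect_equal(h$counts[10 + 1], 3)
  expect_equal(sum(h$counts), 5)

  # additivity: pooled = element-wise sum of per-stack histograms
  ha <- pooled_histogram(chrom_dataset(list(ds$stacks[[1]])))
  hb <- pooled_histogram(chrom_dataset(list(ds$stacks[[2]])))
  expect_equal(h$counts, ha$counts + hb$counts)
})

test_that("an all-zero dataset yields the empty-histogram error", {
  p <- image_plane(matrix(0L, 4, 4), bit_depth = 8L)
  ds <- chrom_dataset(list(image_stack(list(p), "z")))
  expect_error(pooled_histogram(ds), "empty histogram")
})

test_that("between-class variance matches hand arithmetic and empty-class cases", {
  h <- hist_from_levels(c(10L, 200L), c(50, 50))
  expect_equal(between_class_variance(h, 100), 0.5 * 0.5 * 190^2)  # 9025
  expect_equal(between_class_variance(h, 5), 0)    # class 0 empty
  expect_equal(between_class_variance(h, 250), 0)  # class 1 empty
  single <- hist_from_levels(37L, 1000)
  for (t in c(0, 37, 200)) expect_equal(between_class_variance(single, t), 0)
})

test_that("Otsu picks the documented levels on the worked histograms", {
  expect_equal(otsu_threshold(hist_from_levels(c(10L, 200L),
                                               c(50, 50)))$level, 10)
  expect_equal(otsu_threshold(hist_from_levels(c(5L, 8L, 100L),
                                               c(70, 30, 100)))$level, 8)
  res <- NULL
  expect_warning(res <- otsu_threshold(hist_from_levels(37L, 1000)),
                 "degenerate")
  expect_true(res$success)
  expect_true(res$degenerate)
  expect_equal(res$level, 37)
  expect_equal(res$iterations, 0L)
})

test_that("Otsu scale consistency: 16-bit embedding of an 8-bit histogram scales the level by 257", {
  set.seed(41)
  for (i in 1:25) {
    occ <- sort(sample(1:255, sample(3:40, 1)))
    cts <- stats::rpois(length(occ), 40) + 1
    h8 <- hist_from_levels(occ, cts)
    h16 <- hist_from_levels(occ * 257L, cts, bit_depth = 16L)
    expect_equal(otsu_threshold(h16)$level, 257 * otsu_threshold(h8)$level)
  }
})

test_that("pooled threshold is invariant to how planes are grouped into stacks", {
  ds <- tiny_dataset(seed = 3L, n_planes = 3L)
  all_planes <- unlist(lapply(ds$stacks, function(s) s$planes),
                       recursive = FALSE)
  regroup1 <- chrom_dataset(list(image_stack(all_planes, "one")))
  regroup2 <- chrom_dataset(lapply(seq_along(all_planes), function(i)
    image_stack(all_planes[i], sprintf("s%02d", i))))
  reversed <- chrom_dataset(rev(ds$stacks))
  lv <- function(d) otsu_threshold(pooled_histogram(d))$level
  expect_equal(lv(regroup1), lv(ds))
  expect_equal(lv(regroup2), lv(ds))
  expect_equal(lv(reversed), lv(ds))
})

test_that("legacy thresholder finds the valley of a clean bimodal histogram without smoothing", {
  cts <- rep(2, 256)
  cts[21] <- 10; cts[121] <- 12   # strict peaks at levels 20 and 120
  cts[61] <- 1                    # unique valley at level 60
  h <- gray_histogram(cts, 8L, zeros_excluded = FALSE)
  res <- legacy_recursive_threshold(h)
  expect_true(res$success)
  expect_equal(res$level, 60)
  expect_equal(res$iterations, 0L)
  expect_equal(res$level, oracle_two_peak_valley(cts))
})

test_that("legacy thresholder ties break to the lowest valley level", {
  cts <- rep(5, 256)
  cts[31] <- 20; cts[91] <- 20    # peaks at 30 and 90
  cts[c(51, 71)] <- 2             # two equal minima: levels 50 and 70
  res <- legacy_recursive_threshold(gray_histogram(cts, 8L,
                                                   zeros_excluded = FALSE))
  expect_true(res$success)
  expect_equal(res$level, 50)
})

test_that("legacy thresholder fails within the cap on constant and unimodal histograms", {
  const <- gray_histogram(rep(7, 256), 8L, zeros_excluded = FALSE)
  res <- legacy_recursive_threshold(const)
  expect_false(res$success)
  expect_true(is.na(res$level))
  expect_equal(res$iterations, 10000L)

  gauss <- gray_histogram(stats::dnorm(0:255, 128, 25) * 1e4, 8L,
                          zeros_excluded = FALSE)
  res2 <- legacy_recursive_threshold(gauss)
  expect_false(res2$success)
  expect_lte(res2$iterations, 10000L)
})

test_that("smoothing rescues a noisy bimodal histogram after a positive number of rounds", {
  # two broad modes plus a one-bin spike: three strict peaks initially; the
  # moving average removes the spike and the two true modes remain
  base <- stats::dnorm(0:255, 60, 12) * 1000 + stats::dnorm(0:255, 190, 12) * 1000
  base[131] <- base[131] + 40
  h <- gray_histogram(base, 8L, zeros_excluded = FALSE)
  res <- legacy_recursive_threshold(h)
  expect_true(res$success)
  expect_gt(res$iterations, 0L)
  expect_true(res$level > 60 && res$level < 190)
})

test_that("2x2 binning takes block means with the odd-edge drop rule", {
  p <- image_plane(rbind(c(10L, 20L, 99L), c(30L, 40L, 99L), c(99L, 99L, 99L)),
                   bit_depth = 8L)
  out <- legacy_bin2(p)
  expect_equal(dim(out$pixels), c(1L, 1L))
  expect_equal(out$pixels[1, 1], 25L)   # mean of the top-left 2x2 block

  const <- image_plane(matrix(81L, 6, 8), bit_depth = 8L)
  outc <- legacy_bin2(const)
  expect_equal(dim(outc$pixels), c(3L, 4L))
  expect_true(all(outc$pixels == 81L))
})

test_that("robustness is the per-plane success fraction of the chosen thresholder", {
  set.seed(9)
  noisy <- lapply(1:4, function(i)
    make_nucleus_plane(nucleus_model(seed = 400 + i), c(48, 48)))
  expect_equal(robustness("otsu", noisy), 1.0)

  # constant-histogram planes force legacy failure
  flat <- lapply(1:3, function(i)
    image_plane(matrix(100L, 16, 16), bit_depth = 8L))
  expect_equal(robustness("legacy", flat), 0.0)
  expect_equal(robustness("otsu", flat), 1.0)   # degenerate but successful

  # mixed set: 3 clean-bimodal + 1 unimodal plane under legacy -> 0.75
  bimodal <- function(seed) {
    set.seed(seed)
    v <- c(sample(18:22, 120, TRUE), sample(118:122, 120, TRUE), 60L)
    image_plane(matrix(c(v, rep(20L, 256 - length(v))), 16, 16),
                bit_depth = 8L)
  }
  unimodal <- image_plane(matrix(rep(c(99L, 100L, 101L, 100L), 64), 16, 16),
                          bit_depth = 8L)
  planes <- c(lapply(1:3, bimodal), list(unimodal))
  expect_equal(robustness("legacy", planes, max_iter = 2000L), 0.75)
})
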