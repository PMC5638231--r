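# Global thresholding: the pooled non-zero-pixel histogram of a whole dataset,
# Otsu's discriminant threshold on it (one pass over cumulative moments), and
# the legacy recursive two-peak/valley thresholder it replaces.

#' Gray-level histogram
#'
#' Counts per gray level 0 .. 2^bit_depth - 1. The pipeline pools every
#' non-zero pixel of the entire dataset into one histogram so that a single
#' threshold applies to all images equally; `zeros_excluded` records whether
#' level 0 was dropped.
#'
#' @param counts Non-negative counts, length `2^bit_depth` (level g at index
#'   g + 1).
#' @param bit_depth 8 or 16.
#' @param zeros_excluded Was level 0 excluded?
#' @export
gray_histogram <- function(counts, bit_depth, zeros_excluded = TRUE) {
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (length(counts) != 2^bit_depth)
    stop(sprintf("counts must have length %d", 2^bit_depth))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (zeros_excluded && counts[1] != 0)
    stop("zeros_excluded histogram has a non-zero count at level 0")
  structure(list(counts = as.numeric(counts), bit_depth = as.integer(bit_depth),
                 zeros_excluded = isTRUE(zeros_excluded)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram> %d-bit, %s pixels%s\n", x$bit_depth,
              format(sum(x$counts), big.mark = ","),
              if (x$zeros_excluded) " (zeros excluded)" else ""))
  invisible(x)
}

plane_histogram_counts <- function(pixels, bit_depth) {
  # tabulate() drops zeros on its own (bin 0); add them back at level 0.
  n <- 2^bit_depth
  cts <- tabulate(as.integer(pixels) + 1L, nbins = n)
  as.numeric(cts)
}

#' Pooled dataset histogram
#'
#' Builds the unified histogram of every pixel (by default every non-zero
#' pixel) across all planes of all stacks of a dataset. This pooled histogram
#' is the input to the global threshold that is later applied to every image
#' equally.
#'
#' @param dataset A [chrom_dataset()] (an [image_stack()] is promoted to a
#'   one-stack dataset).
#' @param exclude_zero Drop gray level 0 (the black background) — the
#'   pipeline's convention.
#' @return A [gray_histogram()].
#' @export
pooled_histogram <- function(dataset, exclude_zero = TRUE) {
  if (inherits(dataset, "chrom_stack"))
    dataset <- chrom_dataset(list(dataset))
  stopifnot(inherits(dataset, "chrom_dataset"))
  b <- dataset_bit_depth(dataset)
  counts <- numeric(2^b)
  for (s in dataset$stacks)
    for (p in s$planes)
      counts <- counts + plane_histogram_counts(p$pixels, b)
  if (exclude_zero) counts[1] <- 0
  if (sum(counts) == 0) stop("empty histogram")
  gray_histogram(counts, bit_depth = b, zeros_excluded = exclude_zero)
}

#' Between-class variance at a threshold
#'
#' The Otsu criterion: `w0 * w1 * (mu0 - mu1)^2` where class 0 holds gray
#' levels `<= t`, class 1 the levels `> t`, `w` are class probability masses
#' and `mu` class mean gray levels. Zero when either class is empty.
#'
#' @param hist A [gray_histogram()] with positive total count.
#' @param t Threshold gray level (0-based).
#' @return The between-class variance (gray-level^2 units).
#' @export
between_class_variance <- function(hist, t) {
  stopifnot(inherits(hist, "gray_histogram"))
  counts <- hist$counts
  total <- sum(counts)
  if (total <= 0) stop("empty histogram")
  g <- seq_along(counts) - 1
  lo <- g <= t
  n0 <- sum(counts[lo]); n1 <- total - n0
  if (n0 == 0 || n1 == 0) return(0)
  mu0 <- sum(counts[lo] * g[lo]) / n0
  mu1 <- sum(counts[!lo] * g[!lo]) / n1
  (n0 / total) * (n1 / total) * (mu0 - mu1)^2
}

#' Otsu's global threshold
#'
#' Non-recursive discriminant thresholding: the returned level is the smallest
#' gray level maximizing the between-class variance over all levels, computed
#' in one pass over the histogram's cumulative moments. Never fails on a
#' non-empty histogram; a histogram with a single occupied level returns that
#' level with `degenerate = TRUE` (and a warning) so the pipeline can continue
#' on pathological crops.
#'
#' @param hist A [gray_histogram()].
#' @return A `threshold_result`: list with `level`, `method = "otsu"`,
#'   `success`, `iterations = 0`, `degenerate`.
#' @examples
#' cts <- numeric(256); cts[c(11, 201)] <- 50  # levels 10 and 200
#' otsu_threshold(gray_histogram(cts, 8, zeros_excluded = TRUE))$level
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  counts <- hist$counts
  total <- sum(counts)
  if (total <= 0) stop("empty histogram")
  occ <- which(counts > 0) - 1L
  if (length(occ) == 1L) {
    warning("degenerate histogram: single occupied gray level", call. = FALSE)
    return(threshold_result(level = occ, method = "otsu", success = TRUE,
                            iterations = 0L, degenerate = TRUE))
  }
  g <- seq_along(counts) - 1
  p <- counts / total
  w0 <- cumsum(p)                 # P(level <= t), indexed by t = g
  m0 <- cumsum(p * g)             # partial first moment
  mt <- m0[length(m0)]
  w1 <- 1 - w0
  num <- (mt * w0 - m0)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, 0)
  level <- g[which.max(bcv)]      # which.max takes the first (lowest) maximum
  threshold_result(level = level, method = "otsu", success = TRUE,
                   iterations = 0L, degenerate = FALSE)
}

threshold_result <- function(level, method, success, iterations = 0L,
                             degenerate = FALSE) {
  structure(list(level = if (success) as.numeric(level) else NA_real_,
                 method = method, success = isTRUE(success),
                 iterations = as.integer(iterations),
                 degenerate = isTRUE(degenerate)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> method %s: %s%s\n", x$method,
              if (x$success) sprintf("level %g", x$level)
              else sprintf("FAILED after %d iterations", x$iterations),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

count_strict_peaks <- function(h) {
  n <- length(h)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  which(h[i - 1] < h[i] & h[i] > h[i + 1]) + 1L
}

smooth_histogram <- function(h) {
  n <- length(h)
  if (n < 3L) return(h)
  s <- h
  s[1] <- (h[1] + h[2]) / 2
  s[n] <- (h[n - 1] + h[n]) / 2
  i <- 2:(n - 1)
  s[i] <- (h[i - 1] + h[i] + h[i + 1]) / 3
  s
}

#' Legacy recursive two-peak/valley threshold
#'
#' The antecedent method: find exactly two strict local maxima in the
#' histogram and threshold at the minimum count between them (lowest level on
#' ties). When the peak count differs from two, the working histogram is
#' smoothed (3-bin moving average, ends averaged over the available
#' neighbours) and the search repeats, up to `max_iter` rounds, after which
#' the method reports failure. A strict local maximum requires
#' `counts[g-1] < counts[g] > counts[g+1]`, so plateau peaks wider than one
#' bin are not detected — the behaviour that makes the method fragile on
#' noisy, heterogeneous histograms. A smoothing round that leaves the working
#' histogram bit-identical (a fixed point, e.g. a constant histogram)
#' short-circuits directly to failure since no further round can change it.
#'
#' @param hist A [gray_histogram()].
#' @param max_iter Iteration cap (default 10000).
#' @return A `threshold_result` with `method = "legacy"`; failure is a
#'   returned state (`success = FALSE`), not an error.
#' @export
legacy_recursive_threshold <- function(hist, max_iter = 10000L) {
  stopifnot(inherits(hist, "gray_histogram"))
  h <- hist$counts
  if (sum(h) <= 0) stop("empty histogram")
  for (k in 0:max_iter) {
    peaks <- count_strict_peaks(h)
    if (length(peaks) == 2L) {
      between <- (peaks[1] + 1L):(peaks[2] - 1L)
      valley <- between[which.min(h[between])]   # first minimum = lowest level
      return(threshold_result(level = valley - 1L, method = "legacy",
                              success = TRUE, iterations = k))
    }
    if (k == max_iter) break
    s <- smooth_histogram(h)
    if (identical(s, h)) break   # fixed point: no later round can differ
    h <- s
  }
  threshold_result(level = NA, method = "legacy", success = FALSE,
                   iterations = max_iter)
}

#' 2x2 pixel binning (legacy compression)
#'
#' Block-mean downsampling by a factor of two in each axis, as performed by
#' the legacy pipeline before thresholding (analyzing an image four times
#' smaller than the input). A trailing odd row/column is dropped; block means
#' are rounded to the nearest integer. Provided so the benchmark can compare
#' compressed and uncompressed inputs; the main pipeline never bins.
#'
#' @param plane An [image_plane()] with at least 2 rows and columns.
#' @return An [image_plane()] of half size.
#' @export
legacy_bin2 <- function(plane) {
  stopifnot(inherits(plane, "chrom_plane"))
  px <- plane$pixels
  nr <- (nrow(px) %/% 2L) * 2L
  nc <- (ncol(px) %/% 2L) * 2L
  if (nr < 2L || nc < 2L) stop("plane must be at least 2x2")
  px <- px[seq_len(nr), seq_len(nc), drop = FALSE]
  out <- (px[seq(1, nr, 2), seq(1, nc, 2)] + px[seq(2, nr, 2), seq(1, nc, 2)] +
          px[seq(1, nr, 2), seq(2, nc, 2)] + px[seq(2, nr, 2), seq(2, nc, 2)]) / 4
  # block means stay inside the original range, so no clipping needed.
  # The result may be smaller than the 3x3 Sobel minimum (a 2x2 input bins to
  # a single pixel); it is built directly since it only ever feeds histograms.
  out <- matrix(as.integer(round(out)), nrow = nr %/% 2L)
  structure(list(pixels = out, bit_depth = plane$bit_depth,
                 plane_index = plane$plane_index),
            class = "chrom_plane")
}

#' Per-plane thresholding success rate
#'
#' Applies the chosen thresholder to each plane's own non-zero histogram and
#' returns the fraction of planes for which it succeeds — the robustness
#' statistic of the method comparison (Otsu never fails on a plane with at
#' least one non-zero pixel; the legacy method often does).
#'
#' @param method `"otsu"` or `"legacy"`.
#' @param planes List of [image_plane()] objects.
#' @param max_iter Iteration cap for the legacy method.
#' @return Fraction in \[0, 1\].
#' @export
robustness <- function(method = c("otsu", "legacy"), planes,
                       max_iter = 10000L) {
  method <- match.arg(method)
  stopifnot(length(planes) >= 1L)
  ok <- vapply(planes, function(p) {
    counts <- plane_histogram_counts(p$pixels, p$bit_depth)
    counts[1] <- 0
    if (sum(counts) == 0) return(FALSE)
    h <- gray_histogram(counts, p$bit_depth, zeros_excluded = TRUE)
    res <- if (method == "otsu") suppressWarnings(otsu_threshold(h))
           else legacy_recursive_threshold(h, max_iter = max_iter)
    res$success
  }, logical(1))
  mean(ok)
}
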