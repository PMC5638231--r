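# Benchmark harness: the (image size x bit depth x method) grid of the
# thresholder comparison — per cell, n seeded synthetic nuclei, success flag
# and wall time per run. Wall times are reported, never asserted: they are
# hardware-dependent.

#' Benchmark specification
#'
#' @param sizes Plane side lengths (default 128, 256, 512, 1024, 2048).
#' @param bit_depths Subset of `c(8, 16)`.
#' @param n_images Images per (size, depth) cell (default 15).
#' @param methods Subset of `c("otsu", "legacy", "legacy_uncompressed")`;
#'   `"legacy"` runs on 2x2-binned planes (the legacy pipeline's compression),
#'   `"legacy_uncompressed"` on full planes.
#' @param seed Base seed for the synthetic images.
#' @param max_iter Legacy iteration cap.
#' @export
benchmark_spec <- function(sizes = c(128L, 256L, 512L, 1024L, 2048L),
                           bit_depths = c(8L, 16L), n_images = 15L,
                           methods = c("otsu", "legacy",
                                       "legacy_uncompressed"),
                           seed = 1L, max_iter = 10000L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(sizes >= 8), n_images >= 1L,
            all(bit_depths %in% c(8L, 16L)))
  structure(list(sizes = as.integer(sizes),
                 bit_depths = as.integer(bit_depths),
                 n_images = as.integer(n_images), methods = methods,
                 seed = as.integer(seed), max_iter = as.integer(max_iter)),
            class = "benchmark_spec")
}

benchmark_plane <- function(size, bit_depth, seed) {
  model <- nucleus_model(radius_px = size * 0.3,
                         focus_radius_px = max(2, size * 0.045),
                         n_foci = 5L, bit_depth = bit_depth, seed = seed)
  make_nucleus_plane(model, shape = c(size, size))
}

threshold_plane <- function(plane, method, max_iter) {
  counts <- plane_histogram_counts(plane$pixels, plane$bit_depth)
  counts[1] <- 0
  h <- gray_histogram(counts, plane$bit_depth, zeros_excluded = TRUE)
  if (method == "otsu") suppressWarnings(otsu_threshold(h))
  else legacy_recursive_threshold(h, max_iter = max_iter)
}

#' Run the thresholder benchmark grid
#'
#' For every (size, bit depth, method) cell, generates `n_images` seeded
#' synthetic nuclear planes, runs the thresholder on each plane's non-zero
#' histogram, and records mean wall time and the robustness percentage
#' (100 * successes / n). The `legacy` method is timed on 2x2-binned planes
#' (binning time included), `legacy_uncompressed` on the full planes.
#'
#' @param spec A [benchmark_spec()].
#' @param out Optional CSV path for the table.
#' @return `data.frame` with columns `method`, `size_px`, `bit_depth`,
#'   `file_size_bytes`, `n`, `mean_exec_time_s`, `robustness_pct`.
#' @export
run_benchmark <- function(spec = benchmark_spec(), out = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  rows <- list()
  for (depth in spec$bit_depths) {
    for (size in spec$sizes) {
      planes <- lapply(seq_len(spec$n_images), function(i)
        benchmark_plane(size, depth, spec$seed + i +
                          1000L * match(depth, c(8L, 16L)) +
                          31L * match(size, spec$sizes)))
      for (method in spec$methods) {
        inputs <- if (method == "legacy") lapply(planes, legacy_bin2)
                  else planes
        runner <- if (method == "otsu") "otsu" else "legacy"
        times <- numeric(length(inputs)); ok <- logical(length(inputs))
        for (i in seq_along(inputs)) {
          t0 <- proc.time()[["elapsed"]]
          res <- threshold_plane(inputs[[i]], runner, spec$max_iter)
          times[i] <- proc.time()[["elapsed"]] - t0
          ok[i] <- res$success
        }
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, size_px = size, bit_depth = depth,
          file_size_bytes = size^2 * (depth / 8),
          n = spec$n_images, mean_exec_time_s = mean(times),
          robustness_pct = 100 * mean(ok))
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}
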