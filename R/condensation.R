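# The per-image pipeline: Gaussian blur, Sobel gradient magnitude, nucleus
# segmentation (hole filling, largest component, extraction to black
# background), and the condensation index — edge pixels over interior nuclear
# area — under one dataset-wide threshold pair.

#' Analysis parameters
#'
#' @param gaussian_sigma Standard deviation, in pixels, of the Gaussian blur
#'   applied before Sobel edge detection (suppresses high-frequency camera
#'   noise while preserving edges). Default 1.
#' @param boundary_erosion_px Number of 3x3 erosions applied to the nuclear
#'   mask before counting edge pixels, so the artificial nucleus/background
#'   rim created by extraction to black is not counted as chromatin edge.
#'   Default 1; 0 disables the exclusion (sensitivity analysis).
#' @param keep_largest_component Keep only the largest 8-connected component
#'   of the thresholded mask (default `TRUE`): one nucleus per image.
#' @param edge_threshold_mode `"pooled_otsu_on_gradient"` (default): the edge
#'   threshold is Otsu's level on the pooled histogram of quantized Sobel
#'   magnitudes over all masked planes of the dataset; `"fixed"`: use
#'   `fixed_edge_threshold`.
#' @param fixed_edge_threshold Gradient-magnitude threshold used when
#'   `edge_threshold_mode = "fixed"`.
#' @export
analysis_params <- function(gaussian_sigma = 1,
                            boundary_erosion_px = 1L,
                            keep_largest_component = TRUE,
                            edge_threshold_mode = c("pooled_otsu_on_gradient",
                                                    "fixed"),
                            fixed_edge_threshold = NULL) {
  edge_threshold_mode <- match.arg(edge_threshold_mode)
  if (!is.numeric(gaussian_sigma) || gaussian_sigma <= 0)
    stop("gaussian_sigma must be positive")
  if (boundary_erosion_px < 0) stop("boundary_erosion_px must be >= 0")
  if (edge_threshold_mode == "fixed" &&
      (is.null(fixed_edge_threshold) || !is.finite(fixed_edge_threshold)))
    stop("fixed edge_threshold_mode requires a finite fixed_edge_threshold")
  structure(list(gaussian_sigma = gaussian_sigma,
                 boundary_erosion_px = as.integer(boundary_erosion_px),
                 keep_largest_component = isTRUE(keep_largest_component),
                 edge_threshold_mode = edge_threshold_mode,
                 fixed_edge_threshold = fixed_edge_threshold),
            class = "analysis_params")
}

#' Gaussian blur
#'
#' Separable 2-D Gaussian convolution with symmetric (reflective) border
#' handling, kernel truncated at 4 sigma. The output is kept in real
#' precision — no requantization before edge detection.
#'
#' @param plane An [image_plane()] or a numeric matrix.
#' @param sigma Positive standard deviation in pixels.
#' @return A numeric matrix of the same shape.
#' @export
gaussian_blur <- function(plane, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number")
  m <- if (inherits(plane, "chrom_plane")) plane$pixels else plane
  m <- matrix(as.numeric(m), nrow = nrow(m))
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  r <- min(r, nrow(m), ncol(m))        # reflection cannot exceed the extent
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_reflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  # vertical pass
  v <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k))
    v <- v + k[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  # horizontal pass
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * v[, (i - 1L) + seq_len(nc), drop = FALSE]
  out
}

#' Sobel gradient magnitude
#'
#' `sqrt(Gx^2 + Gy^2)` with the standard 3x3 Sobel kernels
#' (`[[-1,0,1],[-2,0,2],[-1,0,1]]` and its transpose), symmetric borders.
#'
#' @param plane Numeric matrix (or [image_plane()]) of at least 3x3.
#' @return A numeric matrix of gradient magnitudes.
#' @export
sobel_magnitude <- function(plane) {
  m <- if (inherits(plane, "chrom_plane")) plane$pixels else plane
  m <- matrix(as.numeric(m), nrow = nrow(m))
  if (nrow(m) < 3L || ncol(m) < 3L) stop("plane must be at least 3x3 for Sobel")
  p <- pad_reflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  ri <- 1L + seq_len(nr); ci <- 1L + seq_len(nc)
  sh <- function(dr, dc) p[ri + dr, ci + dc, drop = FALSE]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

# Hole filling by border flood: a FALSE region becomes TRUE unless it is
# 4-connected to the image border (EBImage::bwlabel is 4-connected, which is
# exactly the background-connectivity convention dual to 8-connected
# foreground).
fill_holes <- function(mask) {
  bg <- EBImage::bwlabel(1 - mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- bg > 0 & !(bg %in% border_labels)
  mask | matrix(hole, nrow = nrow(mask))
}

# 8-connected component labels: 4-connected EBImage labels merged across
# diagonal adjacencies via graph components.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab <= 1L) return(list(labels = lab, groups = seq_len(nlab)))
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal pairs
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(edges) == 0L) return(list(labels = lab, groups = seq_len(nlab)))
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(nlab)]
  list(labels = lab, groups = comp)
}

#' Segment the nucleus in one plane
#'
#' Thresholds the plane (`pixels > intensity_threshold`), fills internal holes
#' (FALSE regions not 4-connected to the border become TRUE), and optionally
#' keeps only the largest 8-connected component (ties broken toward the
#' component containing the lowest row-major pixel).
#'
#' @param plane An [image_plane()].
#' @param intensity_threshold Gray level within the plane's bit-depth range.
#' @param params An [analysis_params()].
#' @return A `nuclear_mask`: list with logical `mask` and integer `area_px`.
#'   An all-FALSE mask is allowed (flagged empty downstream).
#' @export
segment_nucleus <- function(plane, intensity_threshold,
                            params = analysis_params()) {
  stopifnot(inherits(plane, "chrom_plane"))
  if (intensity_threshold < 0 || intensity_threshold > max_gray(plane$bit_depth))
    stop("intensity_threshold outside bit-depth range")
  mask <- plane$pixels > intensity_threshold
  if (any(mask)) {
    mask <- fill_holes(mask)
    if (params$keep_largest_component) {
      l8 <- label8(mask)
      merged <- matrix(0L, nrow(mask), ncol(mask))
      nz <- l8$labels > 0
      merged[nz] <- as.integer(l8$groups[l8$labels[nz]])
      areas <- tabulate(merged[merged > 0])
      best <- which(areas == max(areas))
      if (length(best) > 1L) {
        # tie: component containing the lowest row-major pixel wins
        first_px <- vapply(best, function(gid)
          min(row_major_index(merged == gid)), numeric(1))
        best <- best[which.min(first_px)]
      }
      mask <- merged == best
    }
  }
  structure(list(mask = mask, area_px = sum(mask)), class = "nuclear_mask")
}

erode_mask <- function(mask, n) {
  if (n <= 0L || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(3L, shape = "box")
  m <- mask * 1L
  for (i in seq_len(n)) m <- EBImage::erode(m, brush)
  matrix(m > 0, nrow = nrow(mask))
}

# Shared per-plane machinery: segmentation, extraction to black background,
# blur, Sobel, interior mask. Returns everything condensation_index and the
# pooled gradient histogram need.
plane_gradient <- function(plane, intensity_threshold, params) {
  seg <- segment_nucleus(plane, intensity_threshold, params)
  interior <- erode_mask(seg$mask, params$boundary_erosion_px)
  area <- sum(interior)
  if (area == 0L)
    return(list(interior = interior, area = 0L, grad = NULL))
  working <- plane$pixels
  working[!seg$mask] <- 0L                       # extract to black background
  g <- sobel_magnitude(gaussian_blur(working, params$gaussian_sigma))
  list(interior = interior, area = area, grad = g)
}

record_from_gradient <- function(pg, plane_index, edge_threshold) {
  if (pg$area == 0L)
    return(data.frame(plane_index = plane_index, nuclear_area_px = 0L,
                      edge_px = 0L, condensation_index = NA_real_,
                      empty = TRUE))
  edge_px <- sum(pg$grad[pg$interior] > edge_threshold)
  data.frame(plane_index = plane_index, nuclear_area_px = pg$area,
             edge_px = as.integer(edge_px),
             condensation_index = edge_px / pg$area, empty = FALSE)
}

#' Condensation index of one plane
#'
#' Runs the full per-plane pipeline: segment the nucleus, extract it to a
#' black background, Gaussian-blur, take the Sobel gradient magnitude, erode
#' the mask by `boundary_erosion_px` to drop the artificial rim, and count
#' interior pixels whose gradient exceeds `edge_threshold`. The index is
#' `edge_px / interior area`; `nuclear_area_px` reports the interior area.
#'
#' @param plane An [image_plane()].
#' @param intensity_threshold Gray level for segmentation (normally the pooled
#'   dataset Otsu level).
#' @param edge_threshold Gradient-magnitude threshold (normally pooled; see
#'   [analyze_dataset()]).
#' @param params An [analysis_params()].
#' @return One-row `data.frame`: `plane_index`, `nuclear_area_px`, `edge_px`,
#'   `condensation_index`, `empty`. An empty interior yields `empty = TRUE`
#'   and an `NA` index (no division).
#' @export
condensation_index <- function(plane, intensity_threshold, edge_threshold,
                               params = analysis_params()) {
  stopifnot(is.finite(intensity_threshold), is.finite(edge_threshold))
  pg <- plane_gradient(plane, intensity_threshold, params)
  record_from_gradient(pg, plane$plane_index, edge_threshold)
}

# Pooled edge threshold: Otsu on the 65,536-bin histogram of interior
# gradient magnitudes over the whole dataset; returns the upper edge of the
# selected bin (0 when the dataset has no gradient at all).
pooled_edge_threshold <- function(grad_values) {
  gmax <- if (length(grad_values)) max(grad_values) else 0
  if (gmax <= 0) return(0)
  nbins <- 65536L
  w <- gmax / nbins
  bins <- pmin(floor(grad_values / w), nbins - 1L)
  counts <- tabulate(as.integer(bins) + 1L, nbins = nbins)
  h <- gray_histogram(as.numeric(counts), bit_depth = 16L,
                      zeros_excluded = FALSE)
  t <- suppressWarnings(otsu_threshold(h))$level
  (t + 1) * w
}

#' Analyze a whole dataset under one pooled threshold pair
#'
#' The pipeline's entry point. Computes (1) ONE intensity threshold for the
#' entire dataset — Otsu on the pooled non-zero-pixel histogram — applied to
#' every image equally; (2) one edge threshold — Otsu on the pooled histogram
#' of quantized Sobel magnitudes over all masked, blurred planes (or the
#' user's fixed value); (3) the per-plane condensation records; (4) the
#' per-stack aggregate index (total edge pixels / total interior area); and
#' optionally writes one CSV per stack source folder plus a run summary and a
#' JSON manifest.
#'
#' @param dataset A [chrom_dataset()] (or an [image_stack()], promoted).
#' @param params An [analysis_params()].
#' @param write_csv Write per-stack `<id>_chromcon.csv` files. Default: write
#'   when the dataset was read from disk (`dataset$root` set), skip for
#'   in-memory datasets.
#' @param out_dir Folder for the per-stack CSVs, the run summary CSV and the
#'   run manifest; defaults to each stack's source folder under
#'   `dataset$root` (summary and manifest at the root).
#' @return List of [stack_result()] objects, one per stack (same order as the
#'   dataset), with attributes `thresholds` (the pooled pair) and `params`.
#' @export
analyze_dataset <- function(dataset, params = analysis_params(),
                            write_csv = NULL, out_dir = NULL) {
  if (inherits(dataset, "chrom_stack"))
    dataset <- chrom_dataset(list(dataset))
  stopifnot(inherits(dataset, "chrom_dataset"))
  if (is.null(write_csv)) write_csv <- !is.null(dataset$root)

  hist <- tryCatch(pooled_histogram(dataset, exclude_zero = TRUE),
                   error = function(e)
                     stop(sprintf("%s (dataset root: %s)", conditionMessage(e),
                                  dataset$root %||% "<in memory>"),
                          call. = FALSE))
  intensity_th <- suppressWarnings(otsu_threshold(hist))$level

  # First pass: segmentation + gradients, pooling interior gradient values.
  per_stack <- lapply(dataset$stacks, function(s)
    lapply(s$planes, plane_gradient, intensity_threshold = intensity_th,
           params = params))
  edge_th <- if (params$edge_threshold_mode == "fixed")
    params$fixed_edge_threshold
  else
    pooled_edge_threshold(unlist(lapply(per_stack, function(ps)
      lapply(ps, function(pg) if (pg$area > 0L) pg$grad[pg$interior]))))

  thresholds <- c(intensity = intensity_th, edge = edge_th)
  results <- lapply(seq_along(dataset$stacks), function(i) {
    s <- dataset$stacks[[i]]
    recs <- do.call(rbind, lapply(seq_along(s$planes), function(j)
      record_from_gradient(per_stack[[i]][[j]], s$planes[[j]]$plane_index,
                           edge_th)))
    stack_result(s$stack_id, recs, thresholds)
  })

  if (write_csv) {
    for (i in seq_along(results)) {
      dest <- out_dir %||% file.path(dataset$root, results[[i]]$stack_id)
      if (!dir.exists(dest)) dir.create(dest, recursive = TRUE)
      write_results_csv(results[[i]], dest)
    }
    run_dir <- out_dir %||% dataset$root
    write_run_summary(results, run_dir)
    write_run_manifest(params, thresholds, dataset$root %||% "<in memory>",
                       run_dir)
  }
  attr(results, "thresholds") <- thresholds
  attr(results, "params") <- params
  results
}

write_run_summary <- function(results, dir) {
  df <- data.frame(
    stack_id = vapply(results, function(r) r$stack_id, character(1)),
    aggregate_index = vapply(results, function(r) r$aggregate_index,
                             numeric(1)),
    mean_index = vapply(results, function(r) r$mean_index, numeric(1)),
    intensity_threshold = vapply(results, function(r)
      r$thresholds_used[["intensity"]], numeric(1)),
    edge_threshold = vapply(results, function(r)
      r$thresholds_used[["edge"]], numeric(1)))
  utils::write.csv(df, file.path(dir, "chromcon_summary.csv"),
                   row.names = FALSE)
}

write_run_manifest <- function(params, thresholds, input_root, dir,
                               seed = NULL) {
  manifest <- list(
    software = "chromcon",
    version = as.character(utils::packageVersion("chromcon")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_root = input_root,
    parameters = unclass(params),
    thresholds = as.list(thresholds),
    seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "chromcon_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Group summary of aggregate indices
#'
#' Per-group mean and standard error of the per-stack aggregate condensation
#' index (the quantity plotted with standard-error bars in stage/tissue
#' comparisons). No hypothesis testing.
#'
#' @param results List of [stack_result()] objects.
#' @param group_of Either a function `stack_id -> group label` or a named
#'   vector mapping stack ids to labels.
#' @return `data.frame` with columns `group`, `n`, `mean_index`, `se`.
#' @export
summarize_groups <- function(results, group_of) {
  ids <- vapply(results, function(r) r$stack_id, character(1))
  groups <- if (is.function(group_of)) vapply(ids, function(i)
    as.character(group_of(i)), character(1)) else as.character(group_of[ids])
  if (anyNA(groups)) stop("every stack must be assigned a group")
  idx <- vapply(results, function(r) r$aggregate_index, numeric(1))
  keep <- !is.na(idx)
  if (!all(keep))
    warning("omitting stacks with empty results from group summary",
            call. = FALSE)
  groups <- groups[keep]; idx <- idx[keep]
  out <- do.call(rbind, lapply(split(idx, groups), function(v)
    data.frame(n = length(v), mean_index = mean(v),
               se = stats::sd(v) / sqrt(length(v)))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
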