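#' Image plane
#'
#' The atomic unit of analysis: one 2-D grid of unsigned integer intensities
#' with a declared bit depth and a 0-based z position. Pixel coordinates are
#' 0-based, row-major, origin top-left throughout the package; internally the
#' grid is stored as a base R integer matrix (rows x cols).
#'
#' @param pixels Integer matrix of intensities, at least 3 x 3 (the minimum
#'   neighbourhood for a 3x3 Sobel kernel).
#' @param bit_depth 8 or 16.
#' @param plane_index 0-based z position of the plane in its stack.
#' @return An object of class `chrom_plane` with fields `pixels`, `bit_depth`,
#'   `plane_index`.
#' @examples
#' p <- image_plane(matrix(0:24, 5, 5), bit_depth = 8)
#' dim(p$pixels)
#' @export
image_plane <- function(pixels, bit_depth = 16L, plane_index = 0L) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("plane must be at least 3x3")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > max_gray(bit_depth))
    stop(sprintf("pixel values must lie in [0, %d]", max_gray(bit_depth)))
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 plane_index = as.integer(plane_index)),
            class = "chrom_plane")
}

#' @export
print.chrom_plane <- function(x, ...) {
  cat(sprintf("<chrom_plane> %d x %d, %d-bit, z = %d\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$plane_index))
  invisible(x)
}

#' Image stack
#'
#' An ordered list of z-planes of one segmented nucleus. All planes must share
#' shape and bit depth; `plane_index` runs 0, 1, 2, ... in order.
#'
#' @param planes List of [image_plane()] objects.
#' @param stack_id Text label, conventionally the source folder name.
#' @param z_spacing_um Optional positive axial spacing in micrometres
#'   (confocal/apotome stacks are typically ~0.24 um).
#' @return An object of class `chrom_stack`.
#' @export
image_stack <- function(planes, stack_id = "stack", z_spacing_um = NULL) {
  if (length(planes) < 1L) stop("no planes")
  if (!all(vapply(planes, inherits, logical(1), "chrom_plane")))
    stop("planes must be chrom_plane objects")
  dims <- vapply(planes, function(p) dim(p$pixels), integer(2))
  depths <- vapply(planes, function(p) p$bit_depth, integer(1))
  if (length(unique(depths)) != 1L || nrow(unique(t(dims))) != 1L)
    stop("inconsistent stack: planes differ in shape or bit depth")
  for (i in seq_along(planes)) planes[[i]]$plane_index <- i - 1L
  if (!is.null(z_spacing_um) && z_spacing_um <= 0)
    stop("z_spacing_um must be positive")
  structure(list(planes = planes, stack_id = as.character(stack_id),
                 z_spacing_um = z_spacing_um),
            class = "chrom_stack")
}

#' @export
print.chrom_stack <- function(x, ...) {
  p <- x$planes[[1]]
  cat(sprintf("<chrom_stack> '%s': %d plane(s), %d x %d, %d-bit\n",
              x$stack_id, length(x$planes), nrow(p$pixels), ncol(p$pixels),
              p$bit_depth))
  invisible(x)
}

#' @export
length.chrom_stack <- function(x) length(x$planes)

#' Dataset of image stacks
#'
#' The set of stacks that share one pooled threshold pair. All stacks must
#' share bit depth and carry unique ids.
#'
#' @param stacks List of [image_stack()] objects.
#' @param root Optional path of the dataset folder the stacks were read from;
#'   `NULL` for purely in-memory datasets (e.g. simulations).
#' @return An object of class `chrom_dataset`.
#' @export
chrom_dataset <- function(stacks, root = NULL) {
  if (length(stacks) < 1L) stop("empty dataset")
  if (!all(vapply(stacks, inherits, logical(1), "chrom_stack")))
    stop("stacks must be chrom_stack objects")
  ids <- vapply(stacks, function(s) s$stack_id, character(1))
  if (anyDuplicated(ids)) stop("stack ids must be unique")
  depths <- vapply(stacks, function(s) s$planes[[1]]$bit_depth, integer(1))
  if (length(unique(depths)) != 1L)
    stop("all stacks of a dataset must share bit depth")
  structure(list(stacks = stacks, root = root), class = "chrom_dataset")
}

#' @export
print.chrom_dataset <- function(x, ...) {
  cat(sprintf("<chrom_dataset> %d stack(s)%s\n", length(x$stacks),
              if (is.null(x$root)) " (in memory)" else paste0(" at ", x$root)))
  invisible(x)
}

dataset_bit_depth <- function(dataset) dataset$stacks[[1]]$planes[[1]]$bit_depth

#' Per-stack condensation result
#'
#' Bundles the per-plane condensation records of one stack with the stack-level
#' aggregate index (ratio of sums: total edge pixels over total interior
#' nuclear area across non-empty planes) and the threshold pair applied.
#'
#' @param stack_id Stack label.
#' @param records `data.frame` with columns `plane_index`, `nuclear_area_px`,
#'   `edge_px`, `condensation_index`, `empty`.
#' @param thresholds_used Named numeric vector `c(intensity =, edge =)`.
#' @return An object of class `chrom_result`.
#' @export
stack_result <- function(stack_id, records, thresholds_used) {
  stopifnot(is.data.frame(records),
            all(c("plane_index", "nuclear_area_px", "edge_px",
                  "condensation_index", "empty") %in% names(records)))
  ok <- !records$empty
  area <- sum(records$nuclear_area_px[ok])
  aggregate_index <- if (area > 0) sum(records$edge_px[ok]) / area else NA_real_
  mean_index <- if (any(ok)) mean(records$condensation_index[ok]) else NA_real_
  structure(list(stack_id = stack_id, records = records,
                 aggregate_index = aggregate_index,
                 mean_index = mean_index,
                 thresholds_used = thresholds_used),
            class = "chrom_result")
}

#' @export
print.chrom_result <- function(x, ...) {
  cat(sprintf(
    "<chrom_result> '%s': %d plane(s), aggregate condensation index %s\n",
    x$stack_id, nrow(x$records),
    ifelse(is.na(x$aggregate_index), "NA (empty)",
           sprintf("%.4f", x$aggregate_index))))
  invisible(x)
}
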