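# Pre-analysis processing: lossless 3-D crop of a (multi-channel) hyperstack
# and splitting into per-channel folders of single-z-plane TIFFs — the layout
# read_stack()/read_dataset() consume. No operation here touches pixel values.

#' Crop box
#'
#' Axis-aligned 3-D crop region. `x0`/`y0` are 0-based inclusive column/row of
#' the top-left pixel, `z0` the 0-based first plane.
#'
#' @param x0,y0 0-based top-left pixel (column, row).
#' @param width,height Positive pixel extents.
#' @param z0 0-based first plane.
#' @param depth Positive number of planes.
#' @export
crop_box <- function(x0, y0, width, height, z0 = 0L, depth = 1L) {
  v <- c(x0 = x0, y0 = y0, width = width, height = height,
         z0 = z0, depth = depth)
  if (any(v[c("x0", "y0", "z0")] < 0) || any(v[c("width", "height", "depth")] < 1))
    stop("crop box must have non-negative origin and positive extent")
  structure(as.list(as.integer(v)) |> stats::setNames(names(v)),
            class = "crop_box")
}

#' Multi-channel stack
#'
#' One [image_stack()] per fluorescence channel, all sharing geometry.
#'
#' @param channels List of [image_stack()] objects.
#' @param channel_names Optional labels; default `ch1`, `ch2`, ...
#' @export
multi_channel_stack <- function(channels, channel_names = NULL) {
  stopifnot(length(channels) >= 1L,
            all(vapply(channels, inherits, logical(1), "chrom_stack")))
  geom <- vapply(channels, function(s)
    c(length(s$planes), dim(s$planes[[1]]$pixels),
      s$planes[[1]]$bit_depth), integer(4))
  if (nrow(unique(t(geom))) != 1L)
    stop("all channels must share plane count, shape and bit depth")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(channels))
  stopifnot(length(channel_names) == length(channels))
  structure(list(channels = channels,
                 channel_names = as.character(channel_names)),
            class = "multi_channel_stack")
}

crop_one_stack <- function(stack, box) {
  p1 <- stack$planes[[1]]$pixels
  nr <- nrow(p1); nc <- ncol(p1); nz <- length(stack$planes)
  if (box$x0 + box$width > nc)
    stop("crop exceeds image bounds on x axis")
  if (box$y0 + box$height > nr)
    stop("crop exceeds image bounds on y axis")
  if (box$z0 + box$depth > nz)
    stop("crop exceeds image bounds on z axis")
  rows <- (box$y0 + 1L):(box$y0 + box$height)
  cols <- (box$x0 + 1L):(box$x0 + box$width)
  zs <- (box$z0 + 1L):(box$z0 + box$depth)
  planes <- lapply(seq_along(zs), function(i) {
    src <- stack$planes[[zs[i]]]
    image_plane(src$pixels[rows, cols, drop = FALSE],
                bit_depth = src$bit_depth, plane_index = i - 1L)
  })
  image_stack(planes, stack_id = stack$stack_id,
              z_spacing_um = stack$z_spacing_um)
}

#' Lossless 3-D crop
#'
#' Extracts a rectangular sub-volume; output pixels are bit-identical copies
#' of the source region (no rescaling, no dtype change).
#'
#' @param stack An [image_stack()] or [multi_channel_stack()].
#' @param box A [crop_box()] inside the stack bounds.
#' @return Object of the same kind as the input.
#' @export
crop_3d <- function(stack, box) {
  stopifnot(inherits(box, "crop_box"))
  if (inherits(stack, "multi_channel_stack")) {
    multi_channel_stack(lapply(stack$channels, crop_one_stack, box = box),
                        channel_names = stack$channel_names)
  } else if (inherits(stack, "chrom_stack")) {
    crop_one_stack(stack, box)
  } else stop("stack must be a chrom_stack or multi_channel_stack")
}

#' Split channels into the dataset folder layout
#'
#' Writes, for every channel, a folder `out_root/<channel>/` holding one TIFF
#' per z plane (`z000.tif`, `z001.tif`, ... — zero-padded so name order is z
#' order) plus a combined multi-page stack `out_root/<channel>_stack.tif`.
#' All outputs are pixel-exact copies.
#'
#' @param stack A [multi_channel_stack()] (or a single [image_stack()],
#'   treated as one channel).
#' @param out_root Output folder; created if missing.
#' @param overwrite Overwrite existing non-empty channel folders.
#' @return Character vector of created channel folder paths.
#' @export
split_channels <- function(stack, out_root, overwrite = FALSE) {
  if (inherits(stack, "chrom_stack"))
    stack <- multi_channel_stack(list(stack), channel_names = stack$stack_id)
  stopifnot(inherits(stack, "multi_channel_stack"))
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (i in seq_along(stack$channels)) {
    ch <- stack$channels[[i]]
    name <- stack$channel_names[i]
    dir <- file.path(out_root, name)
    if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
      stop(sprintf("refusing to write into non-empty folder %s (set overwrite = TRUE)", dir))
    dir.create(dir, showWarnings = FALSE)
    for (p in ch$planes)
      write_plane_tiff(p, file.path(dir, sprintf("z%03d.tif", p$plane_index)))
    write_stack_tiff(ch, file.path(out_root, paste0(name, "_stack.tif")))
    out <- c(out, dir)
  }
  out
}
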