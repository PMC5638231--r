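# Reading the dataset layout (one folder of single-z-plane TIFFs per nucleus,
# folders grouped under a dataset root) and writing per-stack CSV results.

read_tiff_pages <- function(path) {
  meta <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (!is.null(names(meta))) meta <- list(meta)   # single page -> list of meta
  bits <- unique(unlist(lapply(meta, function(m)
    as.integer(m$bits.per.sample))))
  if (length(bits) != 1L || !bits %in% c(8L, 16L))
    stop(sprintf("unsupported bit depth in %s (expected 8 or 16)", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(px) {
    if (length(dim(px)) != 2L)
      stop(sprintf("expected single channel (grayscale) TIFF: %s", path))
    storage.mode(px) <- "integer"
    list(pixels = px, bit_depth = bits)
  })
}

write_plane_tiff <- function(plane, path) {
  m <- plane$pixels / max_gray(plane$bit_depth)
  tiff::writeTIFF(m, path, bits.per.sample = plane$bit_depth,
                  compression = "none")
  invisible(path)
}

write_stack_tiff <- function(stack, path) {
  b <- stack$planes[[1]]$bit_depth
  pages <- lapply(stack$planes, function(p) p$pixels / max_gray(b))
  tiff::writeTIFF(pages, path, bits.per.sample = b, compression = "none")
  invisible(path)
}

#' Read one image stack
#'
#' Reads a folder of single-z-plane grayscale TIFFs (ordered by numeric-aware
#' filename sort, so `z2.tif` precedes `z10.tif`), or a single multi-page TIFF
#' whose pages are the z planes. Bit depth is inferred from the files.
#'
#' @param folder Path to a stack folder, or directly to a `.tif`/`.tiff` file.
#' @param stack_id Label for the stack; defaults to the folder/file base name.
#' @return An [image_stack()].
#' @examples
#' \dontrun{stk <- read_stack("dataset/nucleus01")}
#' @export
read_stack <- function(folder, stack_id = NULL) {
  if (file.exists(folder) && !dir.exists(folder)) {
    files <- folder
    if (is.null(stack_id))
      stack_id <- tools::file_path_sans_ext(basename(folder))
  } else {
    if (!dir.exists(folder)) stop(sprintf("no such folder: %s", folder))
    files <- list.files(folder, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop(sprintf("no planes in %s", folder))
    files <- files[natural_order(basename(files))]
    if (is.null(stack_id)) stack_id <- basename(normalizePath(folder))
  }
  raw <- unlist(lapply(files, read_tiff_pages), recursive = FALSE)
  dims <- vapply(raw, function(p) dim(p$pixels), integer(2))
  depths <- vapply(raw, function(p) p$bit_depth, integer(1))
  if (length(unique(depths)) != 1L || nrow(unique(t(dims))) != 1L)
    stop(sprintf("inconsistent stack in %s: mixed shapes or bit depths",
                 folder))
  planes <- lapply(seq_along(raw), function(i)
    image_plane(raw[[i]]$pixels, bit_depth = depths[1], plane_index = i - 1L))
  image_stack(planes, stack_id = stack_id)
}

#' Read a dataset of stacks
#'
#' One stack per immediate subfolder of `root`, sorted by folder name.
#' Subfolders holding no TIFF images are skipped with a warning. The returned
#' dataset shares one pooled threshold in [analyze_dataset()].
#'
#' @param root Dataset folder whose subfolders are stacks.
#' @return A [chrom_dataset()].
#' @export
read_dataset <- function(root) {
  if (!dir.exists(root)) stop(sprintf("no such folder: %s", root))
  subs <- list.dirs(root, recursive = FALSE)
  subs <- subs[order(basename(subs))]
  stacks <- list()
  for (s in subs) {
    n_tiff <- length(list.files(s, pattern = "\\.tiff?$", ignore.case = TRUE))
    if (n_tiff == 0L) {
      warning(sprintf("skipping %s: no TIFF images", s), call. = FALSE)
      next
    }
    stacks[[length(stacks) + 1L]] <- read_stack(s)
  }
  if (length(stacks) == 0L) stop(sprintf("empty dataset: %s", root))
  chrom_dataset(stacks, root = normalizePath(root))
}

#' Write a per-stack results CSV
#'
#' Writes `<stack_id>_chromcon.csv`: one header row, one row per plane
#' (`plane_index`, `nuclear_area_px`, `edge_px`, `condensation_index`, `flag`)
#' and a final aggregate row whose `condensation_index` is the ratio-of-sums
#' stack index and whose `mean_condensation_index` column carries the
#' mean-of-planes alternative. Empty planes (no nuclear interior) get an empty
#' index field and flag `"empty"`. Numbers are serialized with 8 significant
#' digits.
#'
#' @param result A [stack_result()].
#' @param folder Destination folder (conventionally the stack's source folder).
#' @return The written path, invisibly.
#' @export
write_results_csv <- function(result, folder) {
  stopifnot(inherits(result, "chrom_result"))
  if (!dir.exists(folder)) stop(sprintf("no such folder: %s", folder))
  path <- file.path(folder, paste0(result$stack_id, "_chromcon.csv"))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.8g", x))
  rec <- result$records
  lines <- c(
    "plane_index,nuclear_area_px,edge_px,condensation_index,flag,mean_condensation_index",
    sprintf("%d,%d,%d,%s,%s,", rec$plane_index, rec$nuclear_area_px,
            rec$edge_px, fmt(rec$condensation_index),
            ifelse(rec$empty, "empty", "")),
    sprintf("aggregate,%d,%d,%s,aggregate,%s",
            sum(rec$nuclear_area_px[!rec$empty]), sum(rec$edge_px[!rec$empty]),
            fmt(result$aggregate_index), fmt(result$mean_index)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
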