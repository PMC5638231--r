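# Synthetic DAPI-like nuclei with controllable condensation ground truth:
# an elliptical nucleus at a uniform base intensity on a zero background,
# bright Gaussian-profile heterochromatin foci, and Poisson + Gaussian camera
# noise. Fully deterministic under a seed, so every pipeline stage is testable
# without real tissue.

#' Synthetic nucleus model
#'
#' @param radius_px Geometric-mean nucleus radius in pixels.
#' @param ellipticity Axis ratio >= 1 (semi-axes `radius * sqrt(e)` and
#'   `radius / sqrt(e)`; orientation drawn from the seed).
#' @param base_intensity Nucleus intensity as a fraction of dynamic range.
#' @param n_foci Number of condensed-chromatin foci.
#' @param focus_radius_px Focus radius; foci are Gaussian blobs with
#'   `sd = focus_radius_px / 2` (hard disks with `focus_profile = "disk"`).
#' @param focus_gain Intensity multiplier at the focus centre (> 1): the peak
#'   reaches `base_intensity * focus_gain`.
#' @param noise_sd_frac Gaussian read noise sd as a fraction of dynamic range.
#' @param poisson_noise Apply Poisson (shot) noise before the Gaussian noise?
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; the rendering is fully determined by it.
#' @param focus_profile `"gaussian"` (default, realistic gradients for Sobel)
#'   or `"disk"` (hard-edged, analytically checkable).
#' @param background_level Background intensity as a fraction of dynamic
#'   range, default 0 (exactly black outside the nucleus pre-noise — the
#'   regime the pipeline's non-zero-pixel pooling assumes). A small positive
#'   value emulates residual mounting-medium fluorescence and stress-tests
#'   that assumption.
#' @export
nucleus_model <- function(radius_px = 18, ellipticity = 1.2,
                          base_intensity = 0.35, n_foci = 5,
                          focus_radius_px = 3, focus_gain = 2.5,
                          noise_sd_frac = 0.02, poisson_noise = TRUE,
                          bit_depth = 16L, seed = 1L,
                          focus_profile = c("gaussian", "disk"),
                          background_level = 0) {
  focus_profile <- match.arg(focus_profile)
  stopifnot(radius_px > 0, ellipticity >= 1, base_intensity > 0,
            base_intensity <= 1, n_foci >= 0, focus_radius_px > 0,
            focus_gain > 1, noise_sd_frac >= 0, bit_depth %in% c(8L, 16L),
            background_level >= 0, background_level < 1)
  structure(list(radius_px = radius_px, ellipticity = ellipticity,
                 base_intensity = base_intensity, n_foci = as.integer(n_foci),
                 focus_radius_px = focus_radius_px, focus_gain = focus_gain,
                 noise_sd_frac = noise_sd_frac,
                 poisson_noise = isTRUE(poisson_noise),
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed),
                 focus_profile = focus_profile,
                 background_level = background_level),
            class = "nucleus_model")
}

# Deterministic draw of foci centres and nucleus geometry for a model; split
# out so tests can replay the sampler independently of the rendering.
sample_nucleus_geometry <- function(model, shape) {
  nr <- shape[1]; nc <- shape[2]
  a <- model$radius_px * sqrt(model$ellipticity)   # semi-major
  b <- model$radius_px / sqrt(model$ellipticity)   # semi-minor
  with_seed(model$seed, {
    theta <- stats::runif(1, 0, pi)
    cy <- nr / 2 + stats::runif(1, -1, 1)
    cx <- nc / 2 + stats::runif(1, -1, 1)
    k <- model$n_foci
    foci <- NULL
    if (k > 0) {
      # rejection-free: uniform in the concentric ellipse shrunk by the
      # focus-radius margin (u ~ sqrt keeps density uniform in area)
      margin <- model$focus_radius_px
      fa <- max(a - margin, 0.5); fb <- max(b - margin, 0.5)
      u <- sqrt(stats::runif(k)); phi <- stats::runif(k, 0, 2 * pi)
      ex <- u * cos(phi) * fa; ey <- u * sin(phi) * fb
      foci <- cbind(x = cx + ex * cos(theta) - ey * sin(theta),
                    y = cy + ex * sin(theta) + ey * cos(theta))
    }
    list(a = a, b = b, theta = theta, cx = cx, cy = cy, foci = foci)
  })
}

#' Render one synthetic nucleus plane
#'
#' An elliptical nucleus at `base_intensity` on an exactly-zero background,
#' `n_foci` bright foci strictly inside the nucleus (margin of one focus
#' radius), then Poisson noise, then Gaussian read noise, then quantization to
#' the model's bit depth. Bit-identical for identical `(model, shape)`.
#'
#' @param model A [nucleus_model()].
#' @param shape `c(rows, cols)`; the nucleus must fit with >= 3 px margin.
#' @param plane_index 0-based z position stamped on the plane.
#' @return An [image_plane()].
#' @export
make_nucleus_plane <- function(model, shape = c(64L, 64L), plane_index = 0L) {
  stopifnot(inherits(model, "nucleus_model"), length(shape) == 2L)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  a <- model$radius_px * sqrt(model$ellipticity)
  if (2 * a + 6 > min(nr, nc))
    stop("nucleus larger than frame (needs >= 3 px margin)")
  geo <- sample_nucleus_geometry(model, c(nr, nc))
  dyn <- max_gray(model$bit_depth)
  base <- model$base_intensity * dyn

  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)   # column coordinate
  y <- matrix(rep(seq_len(nr), nc), nr, nc)          # row coordinate
  dx <- x - geo$cx; dy <- y - geo$cy
  ex <- dx * cos(geo$theta) + dy * sin(geo$theta)
  ey <- -dx * sin(geo$theta) + dy * cos(geo$theta)
  inside <- (ex / geo$a)^2 + (ey / geo$b)^2 <= 1
  img <- ifelse(inside, base, model$background_level * dyn)

  if (!is.null(geo$foci)) {
    amp <- base * (model$focus_gain - 1)
    sd <- model$focus_radius_px / 2
    for (i in seq_len(nrow(geo$foci))) {
      fx <- geo$foci[i, "x"]; fy <- geo$foci[i, "y"]
      # local window only (4 sd / full radius) keeps large frames cheap
      r <- ceiling(if (model$focus_profile == "gaussian") 4 * sd
                   else model$focus_radius_px)
      rs <- max(1L, floor(fy - r)):min(nr, ceiling(fy + r))
      cs <- max(1L, floor(fx - r)):min(nc, ceiling(fx + r))
      d2 <- outer((rs - fy)^2, (cs - fx)^2, "+")
      add <- if (model$focus_profile == "gaussian")
        amp * exp(-d2 / (2 * sd^2))
      else
        amp * (d2 <= model$focus_radius_px^2)
      img[rs, cs] <- img[rs, cs] + add * inside[rs, cs]
    }
  }
  img <- pmin(img, dyn)

  img <- with_seed(derive_plane_seed(model$seed, plane_index) + 1L, {
    out <- img
    if (model$poisson_noise) {
      pos <- out > 0
      out[pos] <- stats::rpois(sum(pos), lambda = out[pos])
    }
    if (model$noise_sd_frac > 0)
      out <- out + stats::rnorm(length(out), sd = model$noise_sd_frac * dyn)
    out
  })
  img <- matrix(as.integer(pmin(pmax(round(img), 0), dyn)), nr, nc)
  image_plane(img, bit_depth = model$bit_depth, plane_index = plane_index)
}

#' Render a synthetic z-stack
#'
#' A spherical-cap z profile: at plane z the nucleus radius scales by
#' `sqrt(1 - ((z - zc) / zr)^2)` (zc the stack centre, zr half-depth plus one)
#' and the base intensity by `0.5 + 0.5 * scale`, so the nucleus appears,
#' peaks mid-stack and disappears. Per-plane randomness (foci, noise) derives
#' deterministically from `(model$seed, plane_index)`.
#'
#' @param model A [nucleus_model()] describing the mid-stack (largest) section.
#' @param n_planes Number of z planes (>= 1).
#' @param shape `c(rows, cols)` of every plane.
#' @param stack_id Label for the stack.
#' @return An [image_stack()].
#' @export
make_stack <- function(model, n_planes = 5L, shape = c(64L, 64L),
                       stack_id = "synthetic") {
  stopifnot(inherits(model, "nucleus_model"))
  n_planes <- as.integer(n_planes)
  if (n_planes < 1L) stop("n_planes must be >= 1")
  zc <- (n_planes - 1) / 2
  zr <- (n_planes - 1) / 2 + 1
  planes <- lapply(seq_len(n_planes) - 1L, function(z) {
    scale <- sqrt(max(0, 1 - ((z - zc) / zr)^2))
    m <- model
    m$radius_px <- model$radius_px * scale
    m$base_intensity <- model$base_intensity * (0.5 + 0.5 * scale)
    m$seed <- derive_plane_seed(model$seed, z)
    if (m$radius_px < 1) m$n_foci <- 0L   # vanishing cap section
    make_nucleus_plane(m, shape = shape, plane_index = z)
  })
  image_stack(planes, stack_id = stack_id)
}

#' Two-group synthetic dataset with ground truth
#'
#' Writes `2 * n_per_group` stack folders under `out_root` (ids `lo_NN` /
#' `hi_NN`, so the group is recoverable from the id prefix) in the layout
#' [read_dataset()] consumes, plus a sidecar `ground_truth.csv` recording the
#' generating parameters per stack. Stack seeds are `base seed + stack
#' number`, so the dataset regenerates bit-identically from the sidecar.
#'
#' @param model_lo,model_hi [nucleus_model()]s for the two groups; by design
#'   they should differ only in condensation-relevant parameters (`n_foci`,
#'   `focus_gain`) for clean ground truth.
#' @param n_per_group Stacks per group.
#' @param out_root Output folder.
#' @param n_planes,shape Stack geometry.
#' @param overwrite Overwrite an existing non-empty `out_root`.
#' @return The in-memory [chrom_dataset()] (root set to `out_root`).
#' @export
make_two_group_dataset <- function(model_lo, model_hi, n_per_group,
                                   out_root, n_planes = 5L,
                                   shape = c(64L, 64L), overwrite = FALSE) {
  if (dir.exists(out_root) && length(list.files(out_root)) > 0L && !overwrite)
    stop(sprintf("refusing to write into non-empty folder %s (set overwrite = TRUE)",
                 out_root))
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  stacks <- list(); truth <- list()
  for (g in c("lo", "hi")) {
    model <- if (g == "lo") model_lo else model_hi
    for (i in seq_len(n_per_group)) {
      m <- model
      m$seed <- model$seed + i
      id <- sprintf("%s_%02d", g, i)
      stk <- make_stack(m, n_planes = n_planes, shape = shape, stack_id = id)
      dir.create(file.path(out_root, id), showWarnings = FALSE)
      for (p in stk$planes)
        write_plane_tiff(p, file.path(out_root, id,
                                      sprintf("z%03d.tif", p$plane_index)))
      stacks[[length(stacks) + 1L]] <- stk
      truth[[length(truth) + 1L]] <- data.frame(
        stack_id = id, group = g, seed = m$seed, n_foci = m$n_foci,
        focus_gain = m$focus_gain, radius_px = m$radius_px,
        base_intensity = m$base_intensity, noise_sd_frac = m$noise_sd_frac,
        bit_depth = m$bit_depth, n_planes = n_planes,
        rows = shape[1], cols = shape[2])
    }
  }
  utils::write.csv(do.call(rbind, truth),
                   file.path(out_root, "ground_truth.csv"), row.names = FALSE)
  chrom_dataset(stacks, root = normalizePath(out_root))
}

#' Named synthetic presets
#'
#' Condensation presets emulating the biological gradients the method was
#' built to quantify: spermatogenesis stages with progressively more compact
#' chromatin (spermatogonia < spermatocyte < spermatid) and regenerating
#' blastema (open, euchromatic) versus mature dermis (compact). Foci count
#' and gain carry the condensation signal; geometry and noise are shared.
#'
#' @param name One of `"spermatogonia"`, `"spermatocyte"`, `"spermatid"`,
#'   `"blastema"`, `"dermal"`.
#' @param bit_depth 8 or 16.
#' @param seed Base seed.
#' @return A [nucleus_model()].
#' @export
chromcon_preset <- function(name = c("spermatogonia", "spermatocyte",
                                     "spermatid", "blastema", "dermal"),
                            bit_depth = 16L, seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    spermatogonia = list(n_foci = 2L,  focus_gain = 1.8),
    spermatocyte  = list(n_foci = 6L,  focus_gain = 2.2),
    spermatid     = list(n_foci = 12L, focus_gain = 2.8),
    blastema      = list(n_foci = 2L,  focus_gain = 1.6),
    dermal        = list(n_foci = 10L, focus_gain = 2.6))
  nucleus_model(n_foci = cfg$n_foci, focus_gain = cfg$focus_gain,
                bit_depth = bit_depth, seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Renders `n` stacks from a preset (seeds `seed + 1 .. seed + n`) into the
#' folder layout [read_dataset()] consumes, with a ground-truth sidecar CSV.
#'
#' @param preset Preset name (see [chromcon_preset()]).
#' @param n Number of stacks.
#' @param out_root Output folder.
#' @param size Plane side length in pixels.
#' @param bit_depth 8 or 16.
#' @param seed Base seed.
#' @param n_planes Planes per stack.
#' @param overwrite Overwrite an existing non-empty folder.
#' @return The [chrom_dataset()] written.
#' @export
simulate_dataset <- function(preset, n, out_root, size = 64L, bit_depth = 16L,
                             seed = 1L, n_planes = 5L, overwrite = FALSE) {
  model <- chromcon_preset(preset, bit_depth = bit_depth, seed = seed)
  model$radius_px <- size * 0.28
  model$focus_radius_px <- max(2, size * 0.045)
  if (dir.exists(out_root) && length(list.files(out_root)) > 0L && !overwrite)
    stop(sprintf("refusing to write into non-empty folder %s (set overwrite = TRUE)",
                 out_root))
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  stacks <- list(); truth <- list()
  for (i in seq_len(n)) {
    m <- model
    m$seed <- seed + i
    id <- sprintf("%s_%02d", preset, i)
    stk <- make_stack(m, n_planes = n_planes, shape = c(size, size),
                      stack_id = id)
    dir.create(file.path(out_root, id), showWarnings = FALSE)
    for (p in stk$planes)
      write_plane_tiff(p, file.path(out_root, id,
                                    sprintf("z%03d.tif", p$plane_index)))
    stacks[[length(stacks) + 1L]] <- stk
    truth[[length(truth) + 1L]] <- data.frame(
      stack_id = id, preset = preset, seed = m$seed, n_foci = m$n_foci,
      focus_gain = m$focus_gain, radius_px = m$radius_px,
      base_intensity = m$base_intensity, bit_depth = m$bit_depth,
      n_planes = n_planes, rows = size, cols = size)
  }
  utils::write.csv(do.call(rbind, truth),
                   file.path(out_root, "ground_truth.csv"), row.names = FALSE)
  chrom_dataset(stacks, root = normalizePath(out_root))
}
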