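# Shared tiny fixtures, built in code at test time.

# a histogram object from a sparse {level: count} spec
hist_from_levels <- function(levels, counts, bit_depth = 8L,
                             zeros_excluded = TRUE) {
  cts <- numeric(2^bit_depth)
  cts[levels + 1L] <- counts
  gray_histogram(cts, bit_depth, zeros_excluded = zeros_excluded)
}

# a solid disk plane: intensity `value` inside radius r, 0 outside
disk_plane <- function(n = 31L, r = 10, value = 500L, bit_depth = 16L,
                       centre = c((n + 1) / 2, (n + 1) / 2)) {
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), n), n, n)
  inside <- (x - centre[2])^2 + (y - centre[1])^2 <= r^2
  image_plane(matrix(as.integer(inside) * value, n, n), bit_depth = bit_depth)
}

# small two-stack in-memory dataset with distinct condensation levels
tiny_dataset <- function(seed = 1L, n_planes = 2L, shape = c(48L, 48L)) {
  lo <- nucleus_model(radius_px = 13, n_foci = 2L, focus_gain = 1.8,
                      seed = seed)
  hi <- nucleus_model(radius_px = 13, n_foci = 9L, focus_gain = 2.8,
                      seed = seed + 50L)
  chrom_dataset(list(make_stack(lo, n_planes, shape, "lo"),
                     make_stack(hi, n_planes, shape, "hi")))
}
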