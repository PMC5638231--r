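# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric-aware ("natural") ordering of file names: digit runs compare by
# value, so z2 sorts before z10. Non-digit runs compare lexicographically.
natural_order <- function(x) {
  # Pad every digit run to 20 characters so lexicographic order == numeric.
  key <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)[[1]]
    if (m[1] == -1L) return(s)
    runs <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
    padded <- vapply(runs, function(r) formatC(r, width = 20, flag = "0"),
                     character(1))
    regmatches(s, gregexpr("[0-9]+", s)) <- list(padded)
    s
  }, character(1), USE.NAMES = FALSE)
  order(key, x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-plane seed: seed XOR (Knuth multiplicative hash of the
# plane index), folded into [0, 2^31). Documented so an external replay
# oracle can reproduce it without this package.
derive_plane_seed <- function(seed, plane_index) {
  h <- (plane_index * 2654435761) %% 2147483647
  bitwXor(as.integer(seed %% 2147483647), as.integer(h))
}

# Pad a matrix by `k` pixels on every side with symmetric (edge-duplicating)
# reflection; k may exceed the matrix extent only if k <= dim - 1.
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(k >= 1, k <= nr, k <= nc)
  ri <- c(k:1, seq_len(nr), nr:(nr - k + 1))
  ci <- c(k:1, seq_len(nc), nc:(nc - k + 1))
  m[ri, ci, drop = FALSE]
}

# Row-major (origin top-left, 0-based elsewhere in the docs) linear index of
# every TRUE pixel of a logical matrix; used for deterministic tie-breaks.
row_major_index <- function(mask) {
  w <- which(mask)                       # column-major 1-based
  r <- ((w - 1L) %% nrow(mask)) + 1L
  c <- ((w - 1L) %/% nrow(mask)) + 1L
  (r - 1L) * ncol(mask) + (c - 1L)
}

max_gray <- function(bit_depth) as.integer(2^bit_depth - 1)
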