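# Independent, deliberately naive re-implementations used as oracles. They
# share only the stated conventions (symmetric borders, 4/8 connectivity,
# replicated-border erosion) with the package, never its code paths: blur and
# Sobel are literal double loops over explicit kernels, hole filling and
# components are queue-based flood fills.

refl_idx <- function(i, n) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))

naive_convolve <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- (nrow(kernel) - 1L) / 2L; kc <- (ncol(kernel) - 1L) / 2L
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (dr in -kr:kr) for (dc in -kc:kc) {
      rr <- refl_idx(r + dr, nr); cc <- refl_idx(c + dc, nc)
      acc <- acc + kernel[dr + kr + 1L, dc + kc + 1L] * m[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

naive_gauss_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

naive_gaussian_blur <- function(m, sigma) {
  k1 <- naive_gauss_kernel_1d(sigma)
  naive_convolve(m, outer(k1, k1))
}

naive_sobel <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  sqrt(naive_convolve(m, kx)^2 + naive_convolve(m, ky)^2)
}

neighbours <- function(r, c, nr, nc, eight = FALSE) {
  d <- if (eight) expand.grid(dr = -1:1, dc = -1:1) else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  d <- d[!(d$dr == 0 & d$dc == 0), ]
  rr <- r + d$dr; cc <- c + d$dc
  keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  cbind(rr[keep], cc[keep])
}

# flood fill from a set of seed pixels over `open` pixels
naive_flood <- function(open, seeds, eight = FALSE) {
  nr <- nrow(open); nc <- ncol(open)
  visited <- matrix(FALSE, nr, nc)
  queue <- seeds[open[seeds], , drop = FALSE]
  if (nrow(queue)) visited[queue] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    nb <- neighbours(cur[1], cur[2], nr, nc, eight)
    for (i in seq_len(nrow(nb))) {
      if (open[nb[i, 1], nb[i, 2]] && !visited[nb[i, 1], nb[i, 2]]) {
        visited[nb[i, 1], nb[i, 2]] <- TRUE
        queue <- rbind(queue, nb[i, , drop = FALSE])
      }
    }
  }
  visited
}

naive_fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(rbind(cbind(1, seq_len(nc)), cbind(nr, seq_len(nc)),
                         cbind(seq_len(nr), 1), cbind(seq_len(nr), nc)))
  reach <- naive_flood(!mask, border, eight = FALSE)
  mask | (!mask & !reach)
}

naive_largest_component8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc); lab <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && labels[r, c] == 0L) {
      lab <- lab + 1L
      comp <- naive_flood(mask, cbind(r, c), eight = TRUE)
      labels[comp] <- lab
    }
  }
  if (lab == 0L) return(mask)
  areas <- tabulate(labels[labels > 0L])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # lowest row-major pixel wins; row-major index = (r-1)*nc + (c-1)
    rm_first <- sapply(best, function(l) {
      w <- which(labels == l)
      r <- (w - 1L) %% nr + 1L; c <- (w - 1L) %/% nr + 1L
      min((r - 1L) * nc + (c - 1L))
    })
    best <- best[which.min(rm_first)]
  }
  labels == best
}

# erosion with 3x3 box, out-of-frame treated as foreground (replicated border)
naive_erode <- function(mask, n) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (k in seq_len(n)) {
    out <- matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      keep <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && !mask[rr, cc])
          keep <- FALSE
      }
      out[r, c] <- keep
    }
    mask <- out
  }
  mask
}

# the whole per-plane pipeline, step by step, from the naive primitives
naive_condensation_index <- function(plane, intensity_threshold,
                                     edge_threshold, sigma = 1,
                                     erosion_px = 1L) {
  mask <- plane$pixels > intensity_threshold
  if (any(mask)) {
    mask <- naive_fill_holes(mask)
    mask <- naive_largest_component8(mask)
  }
  interior <- naive_erode(mask, erosion_px)
  area <- sum(interior)
  if (area == 0) return(list(area = 0L, edge_px = 0L, index = NA_real_))
  working <- plane$pixels
  working[!mask] <- 0L
  g <- naive_sobel(naive_gaussian_blur(working, sigma))
  edge_px <- sum(g[interior] > edge_threshold)
  list(area = area, edge_px = edge_px, index = edge_px / area)
}

# exhaustive-scan Otsu oracle: direct class sums at every candidate level
oracle_bcv <- function(counts, t) {
  g <- seq_along(counts) - 1
  n0 <- sum(counts[g <= t]); n1 <- sum(counts[g > t]); n <- n0 + n1
  if (n0 == 0 || n1 == 0) return(0)
  mu0 <- sum((counts * g)[g <= t]) / n0
  mu1 <- sum((counts * g)[g > t]) / n1
  (n0 / n) * (n1 / n) * (mu0 - mu1)^2
}

# full scan over every level (feasible at 8 bit)
oracle_otsu_full <- function(counts) {
  v <- vapply(0:(length(counts) - 1L), function(t) oracle_bcv(counts, t),
              numeric(1))
  which.max(v) - 1L
}

# scan over occupied levels only: the variance is constant for thresholds in
# a run of unoccupied levels, so the smallest maximizing level over ALL
# levels is always an occupied level (below the lowest occupied level one
# class is empty and the variance is 0)
oracle_otsu_occupied <- function(counts) {
  occ <- which(counts > 0) - 1L
  gl <- occ; cl <- counts[occ + 1L]
  n <- sum(cl)
  v <- vapply(gl, function(t) {
    lo <- gl <= t
    n0 <- sum(cl[lo]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) return(0)
    mu0 <- sum(cl[lo] * gl[lo]) / n0
    mu1 <- sum(cl[!lo] * gl[!lo]) / n1
    (n0 / n) * (n1 / n) * (mu0 - mu1)^2
  }, numeric(1))
  gl[which.max(v)]
}

# direct peak/valley search for the legacy comparator (no smoothing loop)
oracle_two_peak_valley <- function(counts) {
  n <- length(counts)
  i <- 2:(n - 1)
  peaks <- i[counts[i - 1] < counts[i] & counts[i] > counts[i + 1]]
  if (length(peaks) != 2L) return(NULL)
  between <- (peaks[1] + 1L):(peaks[2] - 1L)
  between[which.min(counts[between])] - 1L
}
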