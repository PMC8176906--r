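# Independent brute-force oracles used to cross-check the fast implementations.

oracle_offsets <- data.frame(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
  dist = c(sqrt(2), 1, sqrt(2), 1, 1, sqrt(2), 1, sqrt(2))
)

# D8 specific catchment area by explicit path-following: every cell's area is
# walked down its steepest-descent chain until a cell with no lower neighbour,
# depositing the area at each visited cell.
d8_oracle_as <- function(z, cell_size) {
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)
  cell_area <- cell_size^2
  for (sr in seq_len(nr)) {
    for (sc in seq_len(nc)) {
      r <- sr; c <- sc
      repeat {
        acc[r, c] <- acc[r, c] + cell_area
        best_k <- 0L; best_s <- 0
        for (k in 1:8) {
          rr <- r + oracle_offsets$dr[k]; cc <- c + oracle_offsets$dc[k]
          if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
          s <- (z[r, c] - z[rr, cc]) / (oracle_offsets$dist[k] * cell_size)
          if (s > best_s) { best_s <- s; best_k <- k }
        }
        if (best_k == 0L) break
        r <- r + oracle_offsets$dr[best_k]
        c <- c + oracle_offsets$dc[best_k]
      }
    }
  }
  acc / cell_size
}

# Per-window population SD by direct extraction of each neighbourhood.
focal_sd_oracle <- function(v, window) {
  k <- (window - 1L) %/% 2L
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(v[r, c])) next
      vals <- as.vector(v[max(1L, r - k):min(nr, r + k),
                          max(1L, c - k):min(nc, c + k)])
      vals <- vals[!is.na(vals)]
      if (length(vals) >= 2L) {
        out[r, c] <- sqrt(sum((vals - mean(vals))^2) / length(vals))
      }
    }
  }
  out
}

# Strict 8-neighbour local maxima (greater than every in-grid neighbour).
strict_local_maxima <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      higher <- FALSE; any_nb <- FALSE
      for (k in 1:8) {
        rr <- r + oracle_offsets$dr[k]; cc <- c + oracle_offsets$dc[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        any_nb <- TRUE
        if (z[rr, cc] >= z[r, c]) higher <- TRUE
      }
      out[r, c] <- any_nb && !higher
    }
  }
  out
}

# Tiny deterministic grids used across tests.
tilted_plane <- function(n = 8, slope_per_m = 1, cell_size = 1) {
  z <- matrix(rep(seq_len(n) - 1, each = n) * slope_per_m * cell_size, n, n)
  lcv_grid(z, cell_size)
}
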