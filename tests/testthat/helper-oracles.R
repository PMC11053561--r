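# Independent brute-force oracles used across the suite. These stay
# deliberately naive (loops, exhaustive scans) and separate from the
# package's vectorized implementations.

# Count lattice points with x^2 + y^2 + z^2 <= r^2 by explicit scanning.
oracle_ball_voxel_count <- function(r) {
  n <- 0L
  rng <- -ceiling(r):ceiling(r)
  for (z in rng) for (y in rng) {
    rem <- r^2 - z^2 - y^2
    if (rem >= 0) n <- n + sum(rng^2 <= rem)
  }
  n
}

# Exhaustive 6-neighbour scan: count exposed faces of a logical mask by
# looping over every foreground voxel and testing each face neighbour.
oracle_exposed_faces <- function(mask) {
  d <- dim(mask)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  counts <- c(z = 0L, y = 0L, x = 0L)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    for (k in seq_len(6)) {
      nb <- fg[i, ] + offs[k, ]
      exposed <- any(nb < 1L) || any(nb > d) || !mask[nb[1], nb[2], nb[3]]
      if (exposed) {
        ax <- which(offs[k, ] != 0)
        counts[ax] <- counts[ax] + 1L
      }
    }
  }
  counts  # faces normal to z, y, x
}

# Jonckheere-Terpstra statistic by naive double loops.
oracle_jt_stat <- function(x, g, levels_sorted) {
  s <- 0
  for (i in seq_along(levels_sorted)[-length(levels_sorted)]) {
    for (j in (i + 1):length(levels_sorted)) {
      xi <- x[g == levels_sorted[i]]
      xj <- x[g == levels_sorted[j]]
      for (a in xi) for (b in xj) {
        s <- s + (a < b) + 0.5 * (a == b)
      }
    }
  }
  s
}

# All permutations of 1..n (recursive; for n <= 7).
oracle_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- oracle_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# A random blob-ish logical mask (union of random balls), for property
# tests over irregular geometries.
random_blob_mask <- function(dims, n_balls = 4, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dim = dims)
  zc <- seq_len(dims[1]); yc <- seq_len(dims[2]); xc <- seq_len(dims[3])
  for (b in seq_len(n_balls)) {
    ctr <- c(runif(1, 4, dims[1] - 3), runif(1, 4, dims[2] - 3),
             runif(1, 4, dims[3] - 3))
    r <- runif(1, 2, min(dims) / 3)
    m <- m | (outer(outer((zc - ctr[1])^2, (yc - ctr[2])^2, "+"),
                    (xc - ctr[3])^2, "+") <= r^2)
  }
  m
}
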