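# Independent brute-force oracles, deliberately written as plain R loops so
# they share no code with the package internals they check.

# Minimum-image distance between two points in a cubic box.
oracle_mi_dist <- function(a, b, L) {
  d <- a - b
  d <- d - L * round(d / L)
  sqrt(sum(d^2))
}

# Exhaustive O(N^2) overlap scan; returns the smallest gap over all pairs.
oracle_min_gap <- function(config) {
  pos <- config$positions
  r <- config$radii
  L <- config$box_edge
  n <- nrow(pos)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      g <- oracle_mi_dist(pos[i, ], pos[j, ], L) - (r[i] + r[j])
      if (g < best) best <- g
    }
  }
  best
}

# Double-loop time-and-particle averaged MSD at one lag for an unwrapped
# position array (frames x particles x 3).
oracle_msd_at_lag <- function(arr, lag) {
  nf <- dim(arr)[1]
  np <- dim(arr)[2]
  acc <- 0
  cnt <- 0
  for (i in seq_len(np)) {
    for (t in seq_len(nf - lag)) {
      d <- arr[t + lag, i, ] - arr[t, i, ]
      acc <- acc + sum(d^2)
      cnt <- cnt + 1
    }
  }
  acc / cnt
}

# Hand-built trajectory container for constructed motion (drift, stationary).
make_trajectory <- function(arr, dt) {
  nf <- dim(arr)[1]
  structure(list(times = (seq_len(nf) - 1) * dt,
                 box_edge = Inf,
                 labels = rep("p", dim(arr)[2]),
                 radii = rep(1, dim(arr)[2]),
                 d0 = rep(1, dim(arr)[2]),
                 timestep = dt, seed = 0L,
                 unwrapped = arr, final = NULL,
                 equilibrated = rep(TRUE, nf)),
            class = "bd_trajectory")
}

env298 <- physical_environment(298, 0.89)
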