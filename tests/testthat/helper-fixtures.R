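# Shared fixtures and independent oracles, all built in code.

# Tiny label volume from a vector (filled down a d1 x d2 x d3 grid).
lv <- function(values, dims = c(length(values), 1, 1), spacing = 1) {
  label_volume(array(values, dim = dims), spacing = spacing)
}

# Mask with a given foreground count, laid out from voxel `from` in a
# flattened 10x10x10 grid; used to hit exact |A|, |B|, |A n B| counts.
count_mask <- function(n_fg, from = 1L, total = 1000L, dims = c(10, 10, 10)) {
  v <- integer(total)
  if (n_fg > 0) v[from:(from + n_fg - 1L)] <- 1L
  lv(v, dims)
}

# Small config for fast experiment-level tests: coarser grid, narrower
# protraction range so the phantom still fits.
small_config <- function(...) {
  synthetic_config(grid_shape = 32L, spacing_mm = 2,
                   protraction_range_mm = c(15, 40), ...)
}

# --- independent STAPLE oracle -------------------------------------------
# Straight-from-the-equations EM over the full grid, per-voxel loops, no
# bounding box, no matrix algebra. Shares the stated numerical guards
# (probability clamps at 1e-10) and the E-then-M iteration convention.
staple_oracle <- function(rater_vectors, prior, n_iter,
                          init_performance = 0.9) {
  eps <- 1e-10
  clamp <- function(x) min(max(x, eps), 1 - eps)
  J <- length(rater_vectors)
  nv <- length(rater_vectors[[1]])
  p <- rep(min(init_performance, 0.99999), J)
  q <- rep(min(init_performance, 0.99999), J)
  f1 <- if (identical(prior, "auto")) {
    mean(unlist(rater_vectors))
  } else prior
  f1 <- clamp(f1)
  W <- numeric(nv)
  for (it in seq_len(n_iter)) {
    pc <- vapply(p, clamp, numeric(1))
    qc <- vapply(q, clamp, numeric(1))
    for (i in seq_len(nv)) {
      a <- f1
      b <- 1 - f1
      for (j in seq_len(J)) {
        d <- rater_vectors[[j]][i]
        a <- a * if (d == 1) pc[j] else 1 - pc[j]
        b <- b * if (d == 1) 1 - qc[j] else qc[j]
      }
      W[i] <- a / (a + b)
    }
    for (j in seq_len(J)) {
      num_p <- 0; den_p <- 0; num_q <- 0; den_q <- 0
      for (i in seq_len(nv)) {
        d <- rater_vectors[[j]][i]
        num_p <- num_p + W[i] * d
        den_p <- den_p + W[i]
        num_q <- num_q + (1 - W[i]) * (1 - d)
        den_q <- den_q + (1 - W[i])
      }
      p[j] <- num_p / max(den_p, eps)
      q[j] <- num_q / max(den_q, eps)
    }
  }
  list(posterior = W, p = p, q = q)
}

# Truth mask corrupted by i.i.d. symmetric voxel flips.
flip_noise_rater <- function(truth, flip_prob, seed) {
  set.seed(seed)
  v <- truth$voxels
  flips <- stats::runif(length(v)) < flip_prob
  v[flips] <- 1L - v[flips]
  label_volume(array(v, dim(truth$voxels)), spacing = truth$spacing_mm,
               origin = truth$origin_mm, frame = truth$frame)
}

# Solid ball mask for fusion simulations.
ball_mask <- function(dims = c(16, 16, 16), centre = dims / 2,
                      radius = 4.5, spacing = 1) {
  i <- slice.index(array(0, dims), 1)
  j <- slice.index(array(0, dims), 2)
  k <- slice.index(array(0, dims), 3)
  m <- (i - centre[1])^2 + (j - centre[2])^2 + (k - centre[3])^2 <= radius^2
  label_volume(array(as.integer(m), dims), spacing = spacing)
}

# 26-connectivity check written independently of the package helper:
# iterative label propagation on the voxel array.
connected_26 <- function(volume) {
  v <- volume$voxels
  d <- dim(v)
  fg <- which(v == 1L)
  if (!length(fg)) return(FALSE)
  lab <- array(0L, d)
  lab[fg[1]] <- 1L
  repeat {
    grown <- lab
    idx <- which(grown == 1L)
    sub <- arrayInd(idx, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- cbind(sub[, 1] + dx, sub[, 2] + dy, sub[, 3] + dz)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      sel <- v[nb] == 1L & grown[nb] == 0L
      if (any(sel)) grown[nb[sel, , drop = FALSE]] <- 1L
    }
    if (identical(grown, lab)) break
    lab <- grown
  }
  sum(lab) == length(fg)
}
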