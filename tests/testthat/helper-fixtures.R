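# Shared fixtures, built in code at test time.

# Small volume with a float32-exact affine (entries representable exactly in
# single precision, so NIfTI round-trips are bit-faithful).
tiny_volume <- function(dim = c(4, 4, 4), value = 0,
                        voxel = c(2, 2, 3), origin = c(-10, -20, -30)) {
  aff <- diag(c(voxel, 1))
  aff[1:3, 4] <- origin
  volume3d(array(value, dim), aff, voxel)
}

# Binary cuboid mask on a given grid (1-based inclusive index ranges).
cuboid_mask <- function(dim, xs, ys, zs, affine = diag(4)) {
  a <- array(0, dim)
  a[xs, ys, zs] <- 1
  volume3d(a, affine)
}

translation_affine <- function(dx = 0, dy = 0, dz = 0) {
  m <- diag(4)
  m[1:3, 4] <- c(dx, dy, dz)
  affine_transform(m)
}

# Brute-force nearest-neighbour resampling oracle: explicit per-voxel loop
# through reference affine -> transform^-1 -> mask affine^-1, independent of
# the vectorised implementation.
resample_oracle <- function(mask, reference, transform) {
  out <- array(0, dim(reference$data))
  Minv <- solve(mask$affine)
  Tinv <- solve(unclass(transform))
  d <- dim(reference$data)
  md <- dim(mask$data)
  for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1)) {
    w <- reference$affine %*% c(i, j, k, 1)
    v <- round((Minv %*% (Tinv %*% w))[1:3])
    if (all(v >= 0) && all(v < md))
      out[i + 1, j + 1, k + 1] <- mask$data[v[1] + 1, v[2] + 1, v[3] + 1]
  }
  out
}

# Exhaustive Youden oracle: evaluates J by explicit counting at thresholds
# just above every observed score and far below the minimum, returning the
# maximal J and the half-open score interval(s) attaining it.
youden_oracle <- function(scores, labels) {
  us <- sort(unique(scores))
  probes <- c(us[1] - 1, us + c(diff(us) / 2, 1))
  best_j <- -Inf; intervals <- list()
  for (idx in seq_along(probes)) {
    t <- probes[idx]
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (i in seq_along(scores)) {
      pred <- scores[i] < t
      if (labels[i] && pred) tp <- tp + 1
      else if (labels[i]) fn <- fn + 1
      else if (pred) fp <- fp + 1
      else tn <- tn + 1
    }
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    lo <- if (idx == 1) -Inf else us[idx - 1]
    hi <- if (idx > length(us)) Inf else us[idx]
    if (j > best_j + 1e-12) { best_j <- j; intervals <- list(c(lo, hi)) }
    else if (abs(j - best_j) <= 1e-12) intervals <- c(intervals, list(c(lo, hi)))
  }
  list(j = best_j, intervals = intervals)
}

# Midpoint of the earliest J-optimal interval (-Inf/Inf endpoints mapped to
# the implementation's boundary candidates).
youden_oracle_threshold <- function(scores, labels) {
  o <- youden_oracle(scores, labels)
  iv <- o$intervals[[1]]
  t <- if (!is.finite(iv[1])) -Inf else if (!is.finite(iv[2])) Inf
       else mean(iv)
  list(threshold = t, j = o$j)
}
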