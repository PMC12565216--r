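# Independent brute-force oracles used to validate the fast implementations.

# GLCM by explicit double loop over every pixel and offset.
oracle_glcm <- function(levels, distance = 1,
                        directions = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                        n_levels = max(levels, na.rm = TRUE) + 1) {
  nr <- nrow(levels)
  nc <- ncol(levels)
  counts <- matrix(0, n_levels, n_levels)
  for (d in directions) {
    dr <- d[1] * distance
    dc <- d[2] * distance
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        r2 <- r + dr
        c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        i <- levels[r, c]
        j <- levels[r2, c2]
        if (is.na(i) || is.na(j)) next
        counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1
      }
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}

# The four features by direct loops over matrix entries.
oracle_features <- function(p) {
  ng <- nrow(p)
  contrast <- 0
  energy <- 0
  cross <- 0
  pxy <- numeric(2 * ng - 1)
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      li <- i - 1
      lj <- j - 1
      contrast <- contrast + p[i, j] * (li - lj)^2
      energy <- energy + p[i, j]^2
      cross <- cross + li * lj * p[i, j]
      pxy[li + lj + 1] <- pxy[li + lj + 1] + p[i, j]
    }
  }
  px <- rowSums(p)
  mu <- sum((0:(ng - 1)) * px)
  sig2 <- sum(((0:(ng - 1)) - mu)^2 * px)
  correlation <- if (sig2 > 0) (cross - mu^2) / sig2 else NA_real_
  se <- 0
  for (q in pxy) if (q > 0) se <- se - q * log2(q)
  list(contrast = contrast, correlation = correlation,
       energy = energy, sum_entropy = se)
}

# Tie-corrected Spearman by explicit average-ranking then Pearson covariance.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Disk membership by exhaustive distance check over a bounding square.
oracle_disk_count <- function(area) {
  r <- sqrt(area / pi)
  s <- ceiling(r) + 1
  g <- expand.grid(x = -s:s, y = -s:s)
  sum(g$x^2 + g$y^2 <= r^2 + 1e-12)
}

random_masked_grid <- function(nr, nc, n_levels, mask_frac = 0.2) {
  m <- matrix(sample(0:(n_levels - 1), nr * nc, replace = TRUE), nr, nc)
  m[sample(length(m), round(mask_frac * length(m)))] <- NA
  m
}

make_test_image <- function(nr = 32, nc = 32, fill = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- if (is.null(fill)) {
    matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  } else {
    matrix(as.integer(fill), nr, nc)
  }
  bmode_image(px)
}
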