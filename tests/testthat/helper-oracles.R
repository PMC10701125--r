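# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain loops, exhaustive enumeration) so they cannot
# share a bug with the vectorized / compiled implementation paths.

# AUC by exhaustive pair counting: concordant pairs count 1, ties 1/2.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# Symmetric normalized GLCM by explicit enumeration of all voxel pairs.
glcm_oracle <- function(lev, nlevels, dr, dc) {
  counts <- matrix(0, nlevels, nlevels)
  nr <- nrow(lev); nc <- ncol(lev)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    a <- lev[i, j]; b <- lev[i2, j2]
    if (a > 0 && b > 0) {
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts
}

# Run-length counts by walking every scan line and applying rle().
glrlm_oracle <- function(lev, nlevels, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  counts <- matrix(0, nlevels, max(nr, nc))
  starts <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    pi <- i - dr; pj <- j - dc
    if (pi < 1 || pi > nr || pj < 1 || pj > nc)
      starts[[length(starts) + 1]] <- c(i, j)
  }
  for (st in starts) {
    line <- integer(0)
    i <- st[1]; j <- st[2]
    while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
      line <- c(line, lev[i, j])
      i <- i + dr; j <- j + dc
    }
    r <- rle(line)
    for (k in seq_along(r$values)) {
      v <- r$values[k]
      if (v > 0) counts[v, r$lengths[k]] <- counts[v, r$lengths[k]] + 1
    }
  }
  counts
}

# Confusion counts the slow way.
confusion_oracle <- function(pred, truth) {
  c(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

# A small, quick-to-render phantom configuration (160 x 160 at 2 mm still
# holds the default body ellipse).
small_cohort_config <- function(n_patients = 4, seed = 1, n_slices = 2,
                                ...) {
  cohort_config(n_patients = n_patients, seed = seed,
                geometry = list(matrix_size = 160, pixel_spacing = 2,
                                slice_thickness = 5, n_slices = n_slices),
                ...)
}

# Deterministic toy slab: values filled in order, single slice.
toy_slab <- function(values, nrow, spacing = 1) {
  ct_slab(array(values, c(nrow, length(values) / nrow, 1)),
          pixel_spacing = spacing)
}

full_mask <- function(slab) muscle_mask(array(1L, dim(slab$voxels)))
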