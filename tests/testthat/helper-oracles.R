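# Independent oracles used to check the implementation, written from the
# definitions rather than reusing package internals.

# Breadth-first-search connected-component count (8- or 4-adjacency).
bfs_count_objects <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8L) {
    nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  } else {
    nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  count <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (t in seq_len(nrow(nb))) {
        q <- p + nb[t, ]
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
  }
  count
}

# Brute-force minimum pairwise distance between the true pixels of two masks.
brute_min_distance <- function(a, b) {
  ia <- which(a); ib <- which(b)
  ra <- (ia - 1) %% nrow(a) + 1; ca <- (ia - 1) %/% nrow(a) + 1
  rb <- (ib - 1) %% nrow(b) + 1; cb <- (ib - 1) %/% nrow(b) + 1
  sqrt(min(outer(ra, rb, "-")^2 + outer(ca, cb, "-")^2))
}

# Exhaustive optimal 2-means SSW on a small 1-D sample: the optimal
# partition is contiguous in sorted order, so scan every split point.
exhaustive_k2_ssw <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  for (s in 1:(n - 1)) {
    a <- xs[1:s]; b <- xs[(s + 1):n]
    ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    best <- min(best, ssw)
  }
  best
}

# Exhaustive Otsu: maximize between-class variance over all 256 bin cuts.
exhaustive_otsu <- function(x, levels = 256L) {
  bins <- pmin(floor(x * levels), levels - 1L)
  h <- tabulate(bins + 1L, nbins = levels)
  p <- h / sum(h)
  mu <- sum((0:(levels - 1L)) * p)
  best_var <- -1; best_t <- NA
  w0 <- 0; m0 <- 0
  for (t in 0:(levels - 2L)) {
    w0 <- w0 + p[t + 1L]
    m0 <- m0 + t * p[t + 1L]
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    v <- (mu * w0 - m0)^2 / (w0 * w1)
    if (v > best_var) { best_var <- v; best_t <- t }
  }
  (best_t + 1) / levels  # upper edge of the winning bin
}

# Anti-aliasing-free disk mask used to build tiny fixtures.
disk_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
}

random_mask <- function(shape, p = 0.3) {
  matrix(stats::runif(prod(shape)) < p, shape[1], shape[2])
}
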