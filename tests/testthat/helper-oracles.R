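# Independent scalar-loop oracles for the loss equations and metrics.
# Deliberately naive (explicit loops over pixels and channels) so they share
# no code path with the package implementations.

oracle_class_weights <- function(mask, epsilon = 1e-8) {
  g <- list(1 - mask, mask)
  sapply(g, function(gk) {
    s <- 0
    for (n in seq_along(gk)) s <- s + gk[n]
    1 / (s^2 + epsilon)
  })
}

oracle_gen_dice <- function(mask, probs, epsilon = 1e-8) {
  g <- list(1 - mask, mask)
  p <- list(1 - probs, probs)
  w <- oracle_class_weights(mask, epsilon)
  num <- 0; den <- 0
  for (k in 1:2) {
    sn <- 0; sd <- 0
    for (n in seq_along(mask)) {
      sn <- sn + g[[k]][n] * p[[k]][n]
      sd <- sd + g[[k]][n] + p[[k]][n]
    }
    num <- num + w[k] * sn
    den <- den + w[k] * sd
  }
  1 - 2 * num / (den + epsilon)
}

# Algorithm-1 weight mask by direct per-pixel double loop.
oracle_gw_mask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  rows_fg <- c()
  for (x in 1:H) for (y in 1:W) if (mask[x, y] == 1) rows_fg <- c(rows_fg, x)
  minM <- min(rows_fg); maxM <- max(rows_fg)
  t2 <- matrix(0, H, W)
  for (x in 1:H) for (y in 1:W) {
    if (mask[x, y] == 1) {
      t2[x, y] <- if (maxM == minM) 1 else ((x - maxM) / (maxM - minM))^2
    }
  }
  t2
}

oracle_gw_dice <- function(mask, probs, epsilon = 1e-8) {
  g <- list(1 - mask, mask)
  t <- list(1 - mask, oracle_gw_mask(mask))
  p <- list(1 - probs, probs)
  w <- oracle_class_weights(mask, epsilon)
  num <- 0; den <- 0
  for (k in 1:2) {
    sn <- 0; sd <- 0
    for (n in seq_along(mask)) {
      sn <- sn + g[[k]][n] * t[[k]][n] * p[[k]][n]
      sd <- sd + t[[k]][n] + p[[k]][n]
    }
    num <- num + w[k] * sn
    den <- den + w[k] * sd
  }
  1 - 2 * num / (den + epsilon)
}

# AUC as the Mann-Whitney pair statistic: fraction of (positive, negative)
# pixel pairs ranked correctly, ties counted half.
oracle_auc_pairs <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# A random mask with at least one foreground pixel.
random_mask <- function(H = 8, W = 8, p = 0.3) {
  repeat {
    m <- matrix(rbinom(H * W, 1, p), H, W)
    if (sum(m) > 0 && sum(m) < H * W) return(m)
  }
}

# A rectangular blob mask.
blob_mask <- function(H, W, rows, cols) {
  m <- matrix(0, H, W)
  m[rows, cols] <- 1
  m
}

# Erase exactly k foreground pixels from the top (or bottom) of the tumor,
# in (row, col) scan order, so top- and bottom-erased predictions drop the
# same area.
erase_band <- function(mask, k, from = c("top", "bottom")) {
  from <- match.arg(from)
  idx <- which(mask == 1)
  ord <- order(row(mask)[idx], col(mask)[idx])
  if (from == "bottom") ord <- rev(ord)
  out <- mask
  out[idx[ord[seq_len(k)]]] <- 0
  out
}

# Small cached target-domain phantom dataset shared across test files.
.test_cache <- new.env()
cached_dataset <- function() {
  if (is.null(.test_cache$ds))
    .test_cache$ds <- generate_dataset(
      phantom_spec(n_patients = 12, size = c(64, 64)), seed = 42)
  .test_cache$ds
}
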