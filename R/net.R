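# Minimal encoder-decoder segmentation network with hand-written
# forward/backward passes. Convolutions run as im2col + BLAS matrix
# products; all tensors are base-R arrays (H, W, C). This is deliberately a
# small desk-scale network: the framework around it (losses, transfer
# protocol, ensembling) is architecture-agnostic.

# ---- primitive ops ---------------------------------------------------------

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  pad <- array(0, c(H + 2, W + 2, C))
  pad[2:(H + 1), 2:(W + 1), ] <- x
  out <- matrix(0, H * W, 9 * C)
  col <- 1L
  for (c in seq_len(C)) for (kx in 1:3) for (ky in 1:3) {
    out[, col] <- pad[ky:(ky + H - 1), kx:(kx + W - 1), c]
    col <- col + 1L
  }
  out
}

col2im3 <- function(dcol, H, W, C) {
  dpad <- array(0, c(H + 2, W + 2, C))
  col <- 1L
  for (c in seq_len(C)) for (kx in 1:3) for (ky in 1:3) {
    dpad[ky:(ky + H - 1), kx:(kx + W - 1), c] <-
      dpad[ky:(ky + H - 1), kx:(kx + W - 1), c] + dcol[, col]
    col <- col + 1L
  }
  dpad[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

conv3_forward <- function(x, layer) {
  d <- dim(x)
  xcol <- im2col3(x)
  wmat <- matrix(layer$W, ncol = dim(layer$W)[4])
  y <- xcol %*% wmat
  y <- y + rep(layer$b, each = nrow(y))
  list(out = array(y, c(d[1], d[2], length(layer$b))), xcol = xcol, dim_in = d)
}

conv3_backward <- function(dy, cache, layer) {
  d <- dim(dy)
  dymat <- matrix(dy, ncol = d[3])
  dW <- array(crossprod(cache$xcol, dymat), dim = dim(layer$W))
  db <- colSums(dymat)
  wmat <- matrix(layer$W, ncol = d[3])
  dxcol <- tcrossprod(dymat, wmat)
  dx <- col2im3(dxcol, cache$dim_in[1], cache$dim_in[2], cache$dim_in[3])
  list(dx = dx, dW = dW, db = db)
}

conv1_forward <- function(x, layer) {
  d <- dim(x)
  xmat <- matrix(x, ncol = d[3])
  y <- xmat %*% matrix(layer$W, ncol = dim(layer$W)[4])
  y <- y + rep(layer$b, each = nrow(y))
  list(out = array(y, c(d[1], d[2], length(layer$b))), xmat = xmat, dim_in = d)
}

conv1_backward <- function(dy, cache, layer) {
  d <- dim(dy)
  dymat <- matrix(dy, ncol = d[3])
  dW <- array(crossprod(cache$xmat, dymat), dim = dim(layer$W))
  db <- colSums(dymat)
  dx <- array(tcrossprod(dymat, matrix(layer$W, ncol = d[3])),
              dim = cache$dim_in)
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, cache) dy * cache$mask

meanpool2_forward <- function(x) {
  d <- dim(x)
  i <- seq(1, d[1], by = 2); j <- seq(1, d[2], by = 2)
  out <- (x[i, j, , drop = FALSE] + x[i + 1, j, , drop = FALSE] +
          x[i, j + 1, , drop = FALSE] + x[i + 1, j + 1, , drop = FALSE]) / 4
  list(out = out, dim_in = d)
}

meanpool2_backward <- function(dy, cache) {
  d <- dim(dy)
  dx <- dy[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
           drop = FALSE] / 4
  array(dx, cache$dim_in)
}

upsample2_forward <- function(x) {
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
           drop = FALSE]
  list(out = out, dim_in = d)
}

upsample2_backward <- function(dy, cache) {
  d <- dim(dy)
  i <- seq(1, d[1], by = 2); j <- seq(1, d[2], by = 2)
  dy[i, j, , drop = FALSE] + dy[i + 1, j, , drop = FALSE] +
    dy[i, j + 1, , drop = FALSE] + dy[i + 1, j + 1, , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# ---- network ---------------------------------------------------------------

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' The five stand-in model variants
#'
#' Small encoder-decoder variants differing in depth (resolution levels),
#' width (base channels), and initialization seed. They stand in for an
#' ensemble of distinct segmentation architectures; the surrounding transfer
#' and fusion machinery is architecture-agnostic.
#'
#' @return data.frame with `variant`, `levels`, `base_channels`, `init_seed`.
#' @export
model_variants <- function() {
  data.frame(variant = paste0("v", 1:5),
             levels = c(2, 2, 3, 3, 2),
             base_channels = c(8, 12, 8, 12, 16),
             init_seed = c(101, 202, 303, 404, 505))
}

# Initialize network weights for a variant description.
net_init <- function(levels = 2, base_channels = 8, seed = 1) {
  stopifnot(levels >= 2)
  with_local_seed(seed, {
    ch <- base_channels * 2^(seq_len(levels) - 1)
    enc <- list(); dec <- list()
    cin <- 1
    for (l in seq_len(levels)) {
      enc[[l]] <- list(W = he_init(3, 3, cin, ch[l]), b = rep(0, ch[l]))
      cin <- ch[l]
    }
    for (l in seq_len(levels - 1)) {
      cin_l <- ch[l + 1] + ch[l]  # upsampled path + skip connection
      dec[[l]] <- list(W = he_init(3, 3, cin_l, ch[l]), b = rep(0, ch[l]))
    }
    head <- list(W = he_init(1, 1, ch[1], 1), b = 0)
    list(meta = list(levels = levels, base_channels = base_channels,
                     channels = ch),
         enc = enc, dec = dec, head = head)
  })
}

# Forward pass. `dropout` (rate on the bottleneck activation) is only active
# when training = TRUE. Returns the probability map and, if requested, the
# tape of caches needed for the backward pass.
net_forward <- function(net, img, training = FALSE, dropout = 0,
                        keep_cache = FALSE) {
  L <- net$meta$levels
  x <- array(as_pixel_matrix(img), c(nrow(img), ncol(img), 1))
  if (nrow(img) %% 2^(L - 1) != 0 || ncol(img) %% 2^(L - 1) != 0)
    stop(sprintf("image size must be divisible by %d for %d levels",
                 2^(L - 1), L))
  tape <- list(enc = vector("list", L), pool = vector("list", L - 1),
               dec = vector("list", L - 1), up = vector("list", L - 1))
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    cf <- conv3_forward(x, net$enc[[l]])
    rf <- relu_forward(cf$out)
    tape$enc[[l]] <- list(conv = cf, relu = rf)
    skips[[l]] <- rf$out
    x <- rf$out
    if (l < L) {
      pf <- meanpool2_forward(x)
      tape$pool[[l]] <- pf
      x <- pf$out
    }
  }
  if (training && dropout > 0) {
    keep <- array(stats::rbinom(length(x), 1, 1 - dropout) / (1 - dropout),
                  dim(x))
    tape$drop <- keep
    x <- x * keep
  }
  for (l in rev(seq_len(L - 1))) {
    uf <- upsample2_forward(x)
    xc <- concat_c(uf$out, skips[[l]])
    cf <- conv3_forward(xc, net$dec[[l]])
    rf <- relu_forward(cf$out)
    tape$up[[l]] <- uf
    tape$dec[[l]] <- list(conv = cf, relu = rf, n_up = dim(uf$out)[3])
    x <- rf$out
  }
  hf <- conv1_forward(x, net$head)
  p <- stats::plogis(hf$out[, , 1])
  out <- list(p = p)
  if (keep_cache) { tape$head <- hf; out$tape <- tape }
  out
}

# Backward pass from dLoss/dp; returns gradients shaped like the net.
net_backward <- function(net, fwd, dLdp) {
  L <- net$meta$levels
  tape <- fwd$tape
  p <- fwd$p
  dlogit <- dLdp * p * (1 - p)
  d <- array(dlogit, c(dim(dlogit), 1))
  grads <- list(enc = vector("list", L), dec = vector("list", L - 1),
                head = NULL)
  hb <- conv1_backward(d, tape$head, net$head)
  grads$head <- list(W = hb$dW, b = hb$db)
  d <- hb$dx
  dskip <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dr <- relu_backward(d, tape$dec[[l]]$relu)
    cb <- conv3_backward(dr, tape$dec[[l]]$conv, net$dec[[l]])
    grads$dec[[l]] <- list(W = cb$dW, b = cb$db)
    n_up <- tape$dec[[l]]$n_up
    dskip[[l]] <- cb$dx[, , n_up + seq_len(dim(cb$dx)[3] - n_up), drop = FALSE]
    d <- upsample2_backward(cb$dx[, , seq_len(n_up), drop = FALSE],
                            tape$up[[l]])
  }
  if (!is.null(tape$drop)) d <- d * tape$drop
  for (l in rev(seq_len(L))) {
    if (l < L) d <- meanpool2_backward(d, tape$pool[[l]]) + dskip[[l]]
    dr <- relu_backward(d, tape$enc[[l]]$relu)
    cb <- conv3_backward(dr, tape$enc[[l]]$conv, net$enc[[l]])
    grads$enc[[l]] <- list(W = cb$dW, b = cb$db)
    d <- cb$dx
  }
  grads
}

# ---- flat parameter utilities (optimizer state, checkpoints) ---------------

net_param_refs <- function(net) {
  refs <- list()
  for (l in seq_along(net$enc)) refs[[paste0("enc", l)]] <- c("enc", l)
  for (l in seq_along(net$dec)) refs[[paste0("dec", l)]] <- c("dec", l)
  refs$head <- "head"
  refs
}

net_get <- function(net, ref) if (length(ref) == 1) net[[ref]] else net[[ref[1]]][[as.integer(ref[2])]]
net_set <- function(net, ref, val) {
  if (length(ref) == 1) net[[ref]] <- val
  else net[[ref[1]]][[as.integer(ref[2])]] <- val
  net
}

adam_init <- function(net) {
  st <- list(t = 0, m = list(), v = list())
  for (nm in names(net_param_refs(net))) {
    layer <- net_get(net, net_param_refs(net)[[nm]])
    st$m[[nm]] <- list(W = layer$W * 0, b = layer$b * 0)
    st$v[[nm]] <- list(W = layer$W * 0, b = layer$b * 0)
  }
  st
}

# One Adam (adaptive-moment) update; `grads` shaped like the net.
adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  refs <- net_param_refs(net)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(refs)) {
    layer <- net_get(net, refs[[nm]])
    g <- net_get(grads, refs[[nm]])
    for (pn in c("W", "b")) {
      state$m[[nm]][[pn]] <- beta1 * state$m[[nm]][[pn]] + (1 - beta1) * g[[pn]]
      state$v[[nm]][[pn]] <- beta2 * state$v[[nm]][[pn]] + (1 - beta2) * g[[pn]]^2
      mhat <- state$m[[nm]][[pn]] / bc1
      vhat <- state$v[[nm]][[pn]] / bc2
      layer[[pn]] <- layer[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
    net <- net_set(net, refs[[nm]], layer)
  }
  list(net = net, state = state)
}

sgd_step <- function(net, grads, lr) {
  refs <- net_param_refs(net)
  for (nm in names(refs)) {
    layer <- net_get(net, refs[[nm]])
    g <- net_get(grads, refs[[nm]])
    layer$W <- layer$W - lr * g$W
    layer$b <- layer$b - lr * g$b
    net <- net_set(net, refs[[nm]], layer)
  }
  net
}

# Accumulate b into a (same structure), scaled.
grads_add <- function(a, b, scale = 1) {
  if (is.null(a)) a <- rapply(b, function(x) x * 0, how = "replace")
  refs <- net_param_refs(list(enc = b$enc, dec = b$dec, head = b$head,
                              meta = NULL))
  for (nm in names(refs)) {
    ga <- net_get(a, refs[[nm]]); gb <- net_get(b, refs[[nm]])
    ga$W <- ga$W + scale * gb$W; ga$b <- ga$b + scale * gb$b
    a <- net_set(a, refs[[nm]], ga)
  }
  a
}
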