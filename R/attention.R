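#' Configuration of the multi-channel fused attention block
#'
#' The block runs three selective-kernel (SK) channel-attention branches in
#' parallel at different bottleneck reduction ratios, concatenates their
#' outputs along channels, multiplies by the (replicated) input map, and
#' re-weights the product with a spatial attention map.
#'
#' @param reduction_ratios ordered positive integers; bottleneck factors of
#'   the three parallel SK branches. Default `c(4, 8, 16)`.
#' @param branch_kernels pair of odd integers; kernel sizes of the two SK
#'   convolution branches. Default `c(3, 5)`.
#' @param spatial_kernel odd integer; kernel size of the spatial attention
#'   convolution. Default `7`.
#' @return an object of class `mccbam_config`.
#' @export
mccbam_config <- function(reduction_ratios = c(4L, 8L, 16L),
                          branch_kernels = c(3L, 5L),
                          spatial_kernel = 7L) {
  reduction_ratios <- as.integer(reduction_ratios)
  branch_kernels <- as.integer(branch_kernels)
  spatial_kernel <- as.integer(spatial_kernel)
  if (any(reduction_ratios < 1L)) stop("reduction ratios must be >= 1")
  if (length(branch_kernels) != 2L || any(branch_kernels %% 2L == 0L) ||
      any(branch_kernels < 1L))
    stop("branch kernels must be two odd integers >= 1")
  if (spatial_kernel %% 2L == 0L || spatial_kernel < 1L)
    stop("spatial kernel must be an odd integer >= 1")
  structure(list(reduction_ratios = reduction_ratios,
                 branch_kernels = branch_kernels,
                 spatial_kernel = spatial_kernel),
            class = "mccbam_config")
}

#' Seeded attention weights
#'
#' Initializes all parameters of the attention block for a feature map with
#' `channels` input channels: per SK branch two channel-preserving
#' convolutions (3x3 and 5x5 by default) and a two-layer bottleneck
#' `C -> ceiling(C/r) -> C`, plus the spatial attention convolution
#' (`k x k x 2 -> 1`). Initialization is uniform with fan-in scaling and is
#' deterministic given `seed`.
#'
#' @param channels number of input channels C.
#' @param cfg an [mccbam_config()].
#' @param seed integer RNG seed.
#' @return nested list of arrays with one SK weight set per reduction ratio
#'   (named by ratio) and a `spatial` kernel/bias pair.
#' @export
attention_weights <- function(channels, cfg = mccbam_config(), seed = 1L) {
  C <- as.integer(channels)
  stopifnot(C >= 1L)
  k1 <- cfg$branch_kernels[1L]
  k2 <- cfg$branch_kernels[2L]
  with_seed(seed, {
    sk <- lapply(cfg$reduction_ratios, function(r) {
      Cr <- as.integer(ceiling(C / r))
      list(r = r,
           W3 = init_uniform(c(k1, k1, C, C), k1 * k1 * C),
           b3 = numeric(C),
           W5 = init_uniform(c(k2, k2, C, C), k2 * k2 * C),
           b5 = numeric(C),
           W1 = init_uniform(c(C, Cr), C),
           b1 = numeric(Cr),
           W2 = init_uniform(c(Cr, C), Cr),
           b2 = numeric(C))
    })
    names(sk) <- as.character(cfg$reduction_ratios)
    k <- cfg$spatial_kernel
    list(sk = sk,
         spatial = list(W = init_uniform(c(k, k, 2L, 1L), k * k * 2),
                        b = 0))
  })
}

conv_fwd <- function(x, W, b) {
  d <- dim(W)
  cpp_conv2d_fwd(x, matrix(W, nrow = d[1L] * d[2L] * d[3L]), b, d[1L], d[2L])
}

conv_bwd <- function(x, W, dy) {
  d <- dim(W)
  out <- cpp_conv2d_bwd(x, matrix(W, nrow = d[1L] * d[2L] * d[3L]), dy,
                        d[1L], d[2L])
  out$dW <- array(out$dW, dim = d)
  out
}

sk_weights_for <- function(weights, r) {
  if (!is.null(weights$sk)) {
    w <- weights$sk[[as.character(r)]]
    if (is.null(w)) stop("no SK weight set for reduction ratio ", r)
    w
  } else weights
}

sk_forward <- function(fm, skw) {
  H <- dim(fm)[1L]; W <- dim(fm)[2L]; C <- dim(fm)[3L]
  U3 <- conv_fwd(fm, skw$W3, skw$b3)
  U5 <- conv_fwd(fm, skw$W5, skw$b5)
  s <- colMeans(matrix(U3 + U5, nrow = H * W))      # GAP of U3 (+) U5
  z_pre <- as.vector(s %*% skw$W1) + skw$b1
  z <- pmax(z_pre, 0)
  a <- sigmoid(as.vector(z %*% skw$W2) + skw$b2)    # Ma; Mb = 1 - Ma
  ab <- rep(a, each = H * W)
  fmc <- U3 * ab + U5 * (1 - ab)
  list(out = fmc, U3 = U3, U5 = U5, s = s, z_pre = z_pre, z = z, a = a,
       fm = fm)
}

sk_backward <- function(dout, cache, skw) {
  H <- dim(dout)[1L]; W <- dim(dout)[2L]; C <- dim(dout)[3L]
  HW <- H * W
  ab <- rep(cache$a, each = HW)
  dU3 <- dout * ab
  dU5 <- dout * (1 - ab)
  da <- colSums(matrix(dout * (cache$U3 - cache$U5), nrow = HW))
  da_pre <- da * cache$a * (1 - cache$a)
  dW2 <- outer(cache$z, da_pre)
  db2 <- da_pre
  dz <- as.vector(skw$W2 %*% da_pre)
  dz_pre <- dz * (cache$z_pre > 0)
  dW1 <- outer(cache$s, dz_pre)
  db1 <- dz_pre
  ds <- as.vector(skw$W1 %*% dz_pre)
  dUs <- array(rep(ds / HW, each = HW), dim = dim(dout))  # GAP backward
  dU3 <- dU3 + dUs
  dU5 <- dU5 + dUs
  g3 <- conv_bwd(cache$fm, skw$W3, dU3)
  g5 <- conv_bwd(cache$fm, skw$W5, dU5)
  list(dfm = g3$dx + g5$dx,
       grads = list(W3 = g3$dW, b3 = as.vector(g3$db),
                    W5 = g5$dW, b5 = as.vector(g5$db),
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

spatial_forward <- function(p, spw) {
  H <- dim(p)[1L]; W <- dim(p)[2L]; C <- dim(p)[3L]
  pm <- matrix(p, nrow = H * W)
  avg <- rowMeans(pm)
  mx <- pm[, 1L]
  amax <- rep(1L, H * W)
  if (C > 1L) for (c in 2:C) {
    upd <- pm[, c] > mx
    mx[upd] <- pm[upd, c]
    amax[upd] <- c
  }
  x2 <- array(c(avg, mx), dim = c(H, W, 2L))
  pre <- conv_fwd(x2, spw$W, spw$b)
  s <- sigmoid(pre)
  list(map = s, x2 = x2, pre = pre, amax = amax, C = C)
}

spatial_backward <- function(ds, cache, spw) {
  s <- sigmoid(cache$pre)
  dpre <- ds * s * (1 - s)
  g <- conv_bwd(cache$x2, spw$W, dpre)
  HW <- length(cache$amax)
  davg <- as.vector(g$dx[, , 1L])
  dmx <- as.vector(g$dx[, , 2L])
  dpm <- matrix(rep(davg / cache$C, cache$C), nrow = HW)
  idx <- cbind(seq_len(HW), cache$amax)
  dpm[idx] <- dpm[idx] + dmx
  list(dp = array(dpm, dim = c(dim(cache$x2)[1:2], cache$C)),
       grads = list(W = g$dW, b = as.vector(g$db)))
}

mccbam_forward <- function(fm, cfg, weights) {
  H <- dim(fm)[1L]; W <- dim(fm)[2L]; C <- dim(fm)[3L]
  sk_caches <- lapply(cfg$reduction_ratios, function(r)
    sk_forward(fm, sk_weights_for(weights, r)))
  names(sk_caches) <- as.character(cfg$reduction_ratios)
  nb <- length(sk_caches)
  cat <- do.call(concat_channels, lapply(sk_caches, `[[`, "out"))
  fmrep <- do.call(concat_channels, rep(list(fm), nb))
  p <- cat * fmrep
  sp <- spatial_forward(p, weights$spatial)
  svec <- as.vector(sp$map)                         # recycles per channel
  list(out = p * svec, sk = sk_caches, cat = cat, fmrep = fmrep, p = p,
       sp = sp, nb = nb, C = C)
}

mccbam_backward <- function(dout, cache, cfg, weights) {
  H <- dim(dout)[1L]; W <- dim(dout)[2L]
  HW <- H * W
  svec <- as.vector(cache$sp$map)
  dp <- dout * svec
  ds <- matrix(rowSums(matrix(dout * cache$p, nrow = HW)), nrow = H)
  ds <- array(ds, dim = c(H, W, 1L))
  spb <- spatial_backward(ds, cache$sp, weights$spatial)
  dp <- dp + spb$dp
  dcat <- dp * cache$fmrep
  dfmrep <- dp * cache$cat
  C <- cache$C
  dfm <- array(0, dim = c(H, W, C))
  for (b in seq_len(cache$nb))
    dfm <- dfm + dfmrep[, , (b - 1L) * C + seq_len(C), drop = FALSE]
  grads <- list(spatial = spb$grads)
  for (r in names(cache$sk)) {
    b <- match(r, names(cache$sk))
    skb <- sk_backward(dcat[, , (b - 1L) * C + seq_len(C), drop = FALSE],
                       cache$sk[[r]], sk_weights_for(weights, r))
    dfm <- dfm + skb$dfm
    grads[[paste0("sk", r)]] <- skb$grads
  }
  list(dfm = dfm, grads = grads)
}

#' Selective-kernel channel gate
#'
#' Computes the complementary per-channel gates of one SK branch: the input
#' map is convolved with the two branch kernels (3x3 and 5x5 by default),
#' the element sum is globally average-pooled, squeezed through the
#' bottleneck `C -> ceiling(C/r) -> C` (rectifier between, sigmoid at the
#' end) to give `Ma`; the complementary gate is `Mb = 1 - Ma`.
#'
#' @param fm H x W x C numeric array (all values finite).
#' @param r reduction ratio of the bottleneck.
#' @param weights full [attention_weights()] (the SK set matching `r` is
#'   selected) or a single SK weight set.
#' @return list with per-channel vectors `Ma` and `Mb`, each in (0, 1),
#'   `Ma + Mb = 1` elementwise.
#' @export
sk_channel_gate <- function(fm, r, weights) {
  fm <- as_feature_map(fm)
  if (r < 1) stop("reduction ratio must be >= 1")
  skw <- sk_weights_for(weights, r)
  cache <- sk_forward(fm, skw)
  list(Ma = cache$a, Mb = 1 - cache$a)
}

#' Selective-kernel channel attention
#'
#' Applies one SK branch: the gates of [sk_channel_gate()] mix the two
#' branch convolution outputs, `Ma (x) U3 (+) Mb (x) U5`, broadcast per
#' channel. Output shape equals input shape.
#'
#' @inheritParams sk_channel_gate
#' @return H x W x C array.
#' @export
sk_channel_attention <- function(fm, r, weights) {
  fm <- as_feature_map(fm)
  if (r < 1) stop("reduction ratio must be >= 1")
  sk_forward(fm, sk_weights_for(weights, r))$out
}

#' Spatial attention map
#'
#' Channel-wise average and maximum pooling produce two H x W maps; their
#' concatenation is convolved with a `k x k` kernel (same padding, stride 1)
#' and passed through a sigmoid.
#'
#' @param fm H x W x C numeric array.
#' @param k odd kernel size.
#' @param weights full [attention_weights()] or a `list(W, b)` spatial set.
#' @return H x W x 1 array with entries strictly in (0, 1).
#' @export
spatial_attention_map <- function(fm, k = 7L, weights) {
  fm <- as_feature_map(fm)
  if (k %% 2L == 0L) stop("spatial kernel size must be odd")
  spw <- if (!is.null(weights$spatial)) weights$spatial else weights
  if (dim(spw$W)[1L] != k) stop("weights were built for a different kernel size")
  spatial_forward(fm, spw)$map
}

#' Multi-channel fused attention block
#'
#' The three SK channel-attention outputs are concatenated along channels
#' (H x W x 3C), element-multiplied with the input map replicated three
#' times along channels, and the spatial attention map computed from that
#' product is multiplied back into it. Output shape is H x W x 3C.
#'
#' @param fm H x W x C numeric array.
#' @param cfg an [mccbam_config()].
#' @param weights matching [attention_weights()].
#' @return H x W x 3C array.
#' @export
mccbam <- function(fm, cfg = mccbam_config(), weights) {
  fm <- as_feature_map(fm)
  mccbam_forward(fm, cfg, weights)$out
}
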