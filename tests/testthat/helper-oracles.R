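# Independent straight-line transcriptions used as oracles. Explicit loops,
# no code shared with the package implementation.

oracle_conv2d <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  out <- array(0, dim = c(H, Wd, Cout))
  for (oc in 1:Cout)
    for (j in 1:Wd)
      for (i in 1:H) {
        acc <- b[oc]
        for (ci in 1:Cin)
          for (dj in 1:kw)
            for (di in 1:kh) {
              si <- i + di - 1 - ph
              sj <- j + dj - 1 - pw
              if (si >= 1 && si <= H && sj >= 1 && sj <= Wd)
                acc <- acc + x[si, sj, ci] * W[di, dj, ci, oc]
            }
        out[i, j, oc] <- acc
      }
  out
}

oracle_sigmoid <- function(v) 1 / (1 + exp(-v))

oracle_sk_gate <- function(fm, skw) {
  H <- dim(fm)[1]; Wd <- dim(fm)[2]; C <- dim(fm)[3]
  U3 <- oracle_conv2d(fm, skw$W3, skw$b3)
  U5 <- oracle_conv2d(fm, skw$W5, skw$b5)
  s <- numeric(C)
  for (c in 1:C) s[c] <- mean(U3[, , c] + U5[, , c])
  Cr <- length(skw$b1)
  z <- numeric(Cr)
  for (k in 1:Cr) {
    acc <- skw$b1[k]
    for (c in 1:C) acc <- acc + s[c] * skw$W1[c, k]
    z[k] <- max(acc, 0)
  }
  Ma <- numeric(C)
  for (c in 1:C) {
    acc <- skw$b2[c]
    for (k in 1:Cr) acc <- acc + z[k] * skw$W2[k, c]
    Ma[c] <- oracle_sigmoid(acc)
  }
  list(Ma = Ma, Mb = 1 - Ma, U3 = U3, U5 = U5)
}

oracle_sk_attention <- function(fm, skw) {
  g <- oracle_sk_gate(fm, skw)
  out <- array(0, dim = dim(fm))
  for (c in seq_len(dim(fm)[3]))
    out[, , c] <- g$Ma[c] * g$U3[, , c] + g$Mb[c] * g$U5[, , c]
  out
}

oracle_spatial_map <- function(fm, spw) {
  H <- dim(fm)[1]; Wd <- dim(fm)[2]; C <- dim(fm)[3]
  x2 <- array(0, dim = c(H, Wd, 2))
  for (j in 1:Wd)
    for (i in 1:H) {
      x2[i, j, 1] <- mean(fm[i, j, ])
      x2[i, j, 2] <- max(fm[i, j, ])
    }
  pre <- oracle_conv2d(x2, spw$W, spw$b)
  oracle_sigmoid(pre)
}

oracle_mccbam <- function(fm, cfg, w) {
  H <- dim(fm)[1]; Wd <- dim(fm)[2]; C <- dim(fm)[3]
  nb <- length(cfg$reduction_ratios)
  cat <- array(0, dim = c(H, Wd, nb * C))
  for (b in seq_len(nb)) {
    skw <- w$sk[[as.character(cfg$reduction_ratios[b])]]
    cat[, , (b - 1) * C + 1:C] <- oracle_sk_attention(fm, skw)
  }
  p <- array(0, dim = dim(cat))
  for (b in seq_len(nb))
    for (c in 1:C)
      p[, , (b - 1) * C + c] <- cat[, , (b - 1) * C + c] * fm[, , c]
  s <- oracle_spatial_map(p, w$spatial)
  out <- array(0, dim = dim(p))
  for (c in seq_len(nb * C)) out[, , c] <- p[, , c] * s[, , 1]
  out
}

oracle_dense_conv_replicate <- function(m, kern) {
  H <- nrow(m); W <- ncol(m)
  kh <- nrow(kern); kw <- ncol(kern)
  hh <- (kh - 1) / 2; hw <- (kw - 1) / 2
  out <- matrix(0, H, W)
  for (j in 1:W)
    for (i in 1:H) {
      acc <- 0
      for (dj in 1:kw)
        for (di in 1:kh) {
          si <- min(max(i + di - 1 - hh, 1), H)
          sj <- min(max(j + dj - 1 - hw, 1), W)
          acc <- acc + kern[di, dj] * m[si, sj]
        }
      out[i, j] <- acc
    }
  out
}

oracle_confusion_metrics <- function(y_true, y_pred, labels) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  K <- length(labels)
  cm <- matrix(0L, K, K, dimnames = list(labels, labels))
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  per <- list()
  for (cl in labels) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(y_true)) {
      if (y_true[i] == cl && y_pred[i] == cl) tp <- tp + 1L
      if (y_true[i] != cl && y_pred[i] == cl) fp <- fp + 1L
      if (y_true[i] == cl && y_pred[i] != cl) fn <- fn + 1L
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    per[[cl]] <- c(precision = p, recall = r, f1 = f1)
  }
  correct <- 0L
  for (i in seq_along(y_true))
    if (y_true[i] == y_pred[i]) correct <- correct + 1L
  list(confusion = cm, per_class = per,
       accuracy = correct / length(y_true))
}

# exhaustive pairwise (Mann-Whitney) AUC: ties count 1/2
oracle_auc_pairwise <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos)
    for (n in neg)
      tot <- tot + (if (p > n) 1 else if (p == n) 0.5 else 0)
  tot / (length(pos) * length(neg))
}
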