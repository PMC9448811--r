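backbone_conv_names <- function(model) {
  nm <- vapply(model$backbone$layers, function(l)
    if (l$type == "conv") l$name else NA_character_, character(1))
  nm[!is.na(nm)]
}

# Gradient of the pre-softmax class logit at the requested layer, together
# with that layer's activation.
gradcam_site <- function(model, fwd, class_idx, target_layer) {
  dlogits <- numeric(3L)
  dlogits[class_idx] <- 1
  H <- dim(fwd$fused)[1L]; W <- dim(fwd$fused)[2L]
  HW <- H * W
  dgap <- as.vector(model$head$W %*% dlogits)
  dfused <- array(rep(dgap / HW, each = HW), dim = dim(fwd$fused))
  if (target_layer == "fused")
    return(list(A = fwd$fused, G = dfused))
  C <- dim(fwd$fm)[3L]
  if (!is.null(model$attention)) {
    dfm <- dfused[, , seq_len(C), drop = FALSE]
    datt <- dfused[, , -seq_len(C), drop = FALSE]
    if (target_layer == "mccbam")
      return(list(A = fwd$att$out, G = datt))
    dfm <- dfm + mccbam_backward(datt, fwd$att, model$cfg$attention,
                                 model$attention)$dfm
  } else {
    if (target_layer == "mccbam")
      stop("model was built without the attention branch")
    dfm <- dfused
  }
  if (target_layer == "backbone")
    return(list(A = fwd$fm, G = dfm))
  if (!target_layer %in% backbone_conv_names(model))
    stop("target layer is not a convolutional layer: ", target_layer)
  # walk the backbone backwards until the requested layer's output
  dout <- dfm
  layers <- model$backbone$layers
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cache <- fwd$bb$caches[[i]]
    if (l$type == "conv" && l$name == target_layer)
      return(list(A = cache$out, G = dout))
    if (l$type == "conv") {
      dpre <- dout * cache$mask
      dout <- conv_bwd(cache$input, l$W, dpre)$dx
    } else {
      dout <- cpp_maxpool2_bwd(cache$idx, dout, cache$H, cache$W)
    }
  }
  stop("target layer not reached: ", target_layer)
}

#' Grad-CAM heatmap
#'
#' Channel importances are the spatial means of the gradient of the
#' pre-softmax class logit at the target layer; the heatmap is the
#' rectified importance-weighted sum of that layer's activations, bilinearly
#' upsampled to the input size and min-max normalized to `[0, 1]`. A map
#' whose rectified sum is identically zero (e.g. zero gradients) is
#' returned as all zeros with `all_zero = TRUE`.
#'
#' @param model an `hccanet` model.
#' @param image preprocessed H x W x 3 input array.
#' @param target_class grade label or index 1..3.
#' @param target_layer `"fused"` (default; the fused convolutional map the
#'   head consumes), `"mccbam"`, `"backbone"`, or a backbone convolution
#'   layer name such as `"block5_conv3"`.
#' @return object of class `gradcam_map`: `heatmap` (input-sized matrix in
#'   `[0, 1]`), `target_class`, `target_layer`, `all_zero`.
#' @export
gradcam <- function(model, image, target_class,
                    target_layer = "fused") {
  class_idx <- if (is.character(target_class))
    match(target_class, model$classes) else as.integer(target_class)
  if (is.na(class_idx) || class_idx < 1L || class_idx > 3L)
    stop("unknown target class")
  fwd <- hccanet_forward(model, image, keep = TRUE)
  site <- gradcam_site(model, fwd, class_idx, target_layer)
  HW <- dim(site$A)[1L] * dim(site$A)[2L]
  w <- colMeans(matrix(site$G, nrow = HW))
  cam <- matrix(matrix(site$A, nrow = HW) %*% w, nrow = dim(site$A)[1L])
  cam <- pmax(cam, 0)
  cam <- cpp_resize_bilinear(cam, dim(image)[1L], dim(image)[2L])
  cam <- pmax(cam, 0)  # bilinear interpolation cannot undershoot, kept as guard
  mx <- max(cam)
  mn <- min(cam)
  all_zero <- mx == 0
  if (mx > mn) cam <- (cam - mn) / (mx - mn)
  else if (mx > 0) cam[] <- 1  # constant positive map: uniformly important
  structure(list(heatmap = cam, target_class = model$classes[class_idx],
                 target_layer = target_layer, all_zero = all_zero),
            class = "gradcam_map")
}

# diverging blue -> neutral -> red colormap; red channel is monotone in v
heat_colormap <- function(v) {
  stops <- c(0, 0.5, 1)
  rs <- c(0, 240, 255) / 255
  gs <- c(0, 240, 0) / 255
  bs <- c(255, 240, 0) / 255
  cbind(stats::approx(stops, rs, v)$y,
        stats::approx(stops, gs, v)$y,
        stats::approx(stops, bs, v)$y)
}

#' Overlay a Grad-CAM heatmap on an image
#'
#' The heatmap is rendered with a blue (unimportant) to red (critical)
#' colormap and alpha-blended onto the image. `alpha = 0` returns the
#' original image, `alpha = 1` the pure colormap render.
#'
#' @param map a [gradcam()] result (or an H x W matrix in `[0, 1]`).
#' @param img H x W x 3 image in `[0, 255]`.
#' @param alpha blend weight of the colormap in `[0, 1]`.
#' @return H x W x 3 array in `[0, 255]`.
#' @export
overlay <- function(map, img, alpha = 0.5) {
  hm <- if (inherits(map, "gradcam_map")) map$heatmap else map
  if (!identical(dim(hm), dim(img)[1:2]))
    stop("heatmap and image shapes differ")
  stopifnot(alpha >= 0, alpha <= 1)
  cols <- heat_colormap(as.vector(hm)) * 255
  render <- array(cols, dim = c(dim(hm), 3L))
  (1 - alpha) * img + alpha * render
}
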