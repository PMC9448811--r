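vgg16_block_channels <- list(c(64L, 64L), c(128L, 128L),
                             c(256L, 256L, 256L),
                             c(512L, 512L, 512L), c(512L, 512L, 512L))

#' Backbone configuration (VGG16 topology)
#'
#' Thirteen 3x3 convolution layers in five blocks, each block followed by
#' 2x2 max pooling, so a `224 x 224 x 3` input yields a `7 x 7 x 512`
#' feature map at full width. `width_multiplier` scales every stage's
#' channel count for CPU-scale experiments; `freeze_until` names the first
#' trainable layer (everything before it is frozen for fine-tuning).
#'
#' @param freeze_until layer name; default `"block3_conv1"` (the alias
#'   `"Block_Conv3"` is accepted), i.e. blocks 1-2 frozen, training from the
#'   third convolutional block onward.
#' @param pretrained load externally supplied backbone weights from the file
#'   named by `options(hccanet.vgg16_weights=)` when available; otherwise
#'   seeded random initialization is used. Never required.
#' @param input_size `c(height, width, 3)`; height and width must be
#'   divisible by 32 (five 2x poolings).
#' @param width_multiplier real in (0, 1].
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(freeze_until = "block3_conv1",
                            pretrained = FALSE,
                            input_size = c(224L, 224L, 3L),
                            width_multiplier = 1) {
  if (identical(freeze_until, "Block_Conv3")) freeze_until <- "block3_conv1"
  stopifnot(length(input_size) == 3L, input_size[3L] == 3L,
            width_multiplier > 0, width_multiplier <= 1)
  if (any(input_size[1:2] %% 32L != 0L))
    stop("input height and width must be divisible by 32")
  structure(list(freeze_until = freeze_until, pretrained = pretrained,
                 input_size = as.integer(input_size),
                 width_multiplier = width_multiplier),
            class = "backbone_config")
}

backbone_layer_plan <- function(width_multiplier) {
  plan <- list()
  cin <- 3L
  for (b in seq_along(vgg16_block_channels)) {
    for (ci in seq_along(vgg16_block_channels[[b]])) {
      cout <- max(1L, as.integer(round(
        vgg16_block_channels[[b]][ci] * width_multiplier)))
      plan[[length(plan) + 1L]] <-
        list(type = "conv", name = sprintf("block%d_conv%d", b, ci),
             cin = cin, cout = cout)
      cin <- cout
    }
    plan[[length(plan) + 1L]] <-
      list(type = "pool", name = sprintf("block%d_pool", b))
  }
  plan
}

#' Build the convolutional backbone
#'
#' @param cfg a [backbone_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `hccanet_backbone`: the layer stack with
#'   trainable flags set from the freeze boundary, and the output channel
#'   count.
#' @export
build_backbone <- function(cfg = backbone_config(), seed = 1L) {
  plan <- backbone_layer_plan(cfg$width_multiplier)
  conv_names <- vapply(plan[vapply(plan, `[[`, "", "type") == "conv"],
                       `[[`, "", "name")
  if (!cfg$freeze_until %in% conv_names)
    stop("unknown freeze layer: ", cfg$freeze_until)
  pre <- NULL
  if (cfg$pretrained) {
    path <- getOption("hccanet.vgg16_weights", "")
    if (nzchar(path) && file.exists(path)) pre <- readRDS(path)
  }
  frozen <- TRUE
  layers <- with_seed(seed, lapply(plan, function(l) {
    if (l$type == "pool")
      return(list(type = "pool", name = l$name))
    if (l$name == cfg$freeze_until) frozen <<- FALSE
    W <- if (!is.null(pre[[l$name]]))
      pre[[l$name]]$W else init_uniform(c(3L, 3L, l$cin, l$cout),
                                        9 * l$cin)
    b <- if (!is.null(pre[[l$name]])) pre[[l$name]]$b else numeric(l$cout)
    list(type = "conv", name = l$name, W = W, b = b, trainable = !frozen)
  }))
  out_channels <- layers[[length(layers) - 1L]]$b
  structure(list(layers = layers, cfg = cfg,
                 out_channels = length(out_channels)),
            class = "hccanet_backbone")
}

backbone_forward <- function(bb, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(bb$layers)) else NULL
  for (i in seq_along(bb$layers)) {
    l <- bb$layers[[i]]
    if (l$type == "conv") {
      pre <- conv_fwd(x, l$W, l$b)
      out <- pre * (pre > 0)
      if (keep) caches[[i]] <- list(input = x, mask = pre > 0, out = out)
      x <- out
    } else {
      pooled <- cpp_maxpool2_fwd(x)
      if (keep) caches[[i]] <- list(idx = pooled$idx, H = dim(x)[1L],
                                    W = dim(x)[2L])
      x <- pooled$y
    }
  }
  list(out = x, caches = caches)
}

backbone_backward <- function(bb, caches, dout) {
  grads <- list()
  for (i in rev(seq_along(bb$layers))) {
    l <- bb$layers[[i]]
    cache <- caches[[i]]
    if (l$type == "conv") {
      dpre <- dout * cache$mask
      g <- conv_bwd(cache$input, l$W, dpre)
      if (l$trainable) {
        grads[[paste0("bb.", l$name, ".W")]] <- g$dW
        grads[[paste0("bb.", l$name, ".b")]] <- as.vector(g$db)
      }
      dout <- g$dx
    } else {
      dout <- cpp_maxpool2_bwd(cache$idx, dout, cache$H, cache$W)
    }
  }
  list(dx = dout, grads = grads)
}

#' Full network configuration
#'
#' @param backbone a [backbone_config()].
#' @param attention an [mccbam_config()].
#' @param use_attention include the parallel attention branch (default
#'   TRUE); with FALSE the head sees the backbone map alone.
#' @param seed RNG seed for all weight initialization.
#' @return object of class `hccanet_config`.
#' @export
hccanet_config <- function(backbone = backbone_config(),
                           attention = mccbam_config(),
                           use_attention = TRUE, seed = 1L) {
  structure(list(backbone = backbone, attention = attention,
                 use_attention = use_attention, seed = as.integer(seed)),
            class = "hccanet_config")
}

#' Build the grading network
#'
#' The backbone's final convolutional feature map (C channels) feeds both an
#' identity path and the parallel attention branch (3C channels); the two
#' are fused by channel concatenation (4C), globally average-pooled and
#' mapped by a single affine layer to softmax scores over the three grades.
#'
#' @param cfg an [hccanet_config()].
#' @return object of class `hccanet`.
#' @export
build_hccanet <- function(cfg = hccanet_config()) {
  backbone <- build_backbone(cfg$backbone, seed = cfg$seed)
  C <- backbone$out_channels
  attention <- if (cfg$use_attention)
    attention_weights(C, cfg$attention, seed = cfg$seed + 1L) else NULL
  fused_channels <- if (cfg$use_attention)
    C * (1L + length(cfg$attention$reduction_ratios)) else C
  head <- with_seed(cfg$seed + 2L,
    list(W = init_uniform(c(fused_channels, 3L), fused_channels),
         b = numeric(3L)))
  structure(list(backbone = backbone, attention = attention, head = head,
                 cfg = cfg, classes = grade_levels,
                 fused_channels = fused_channels),
            class = "hccanet")
}

softmax <- function(l) {
  e <- exp(l - max(l))
  e / sum(e)
}

hccanet_forward <- function(model, x, keep = FALSE) {
  bf <- backbone_forward(model$backbone, x, keep = keep)
  fm <- bf$out
  if (!is.null(model$attention)) {
    att <- mccbam_forward(fm, model$cfg$attention, model$attention)
    fused <- concat_channels(fm, att$out)
  } else {
    att <- NULL
    fused <- fm
  }
  HW <- dim(fused)[1L] * dim(fused)[2L]
  gap <- colMeans(matrix(fused, nrow = HW))
  logits <- as.vector(gap %*% model$head$W) + model$head$b
  list(probs = softmax(logits), logits = logits, fm = fm, fused = fused,
       gap = gap, att = att, bb = bf, keep = keep)
}

hccanet_backward <- function(model, fwd, dlogits) {
  grads <- list(head.W = outer(fwd$gap, dlogits),
                head.b = dlogits)
  H <- dim(fwd$fused)[1L]; W <- dim(fwd$fused)[2L]
  HW <- H * W
  dgap <- as.vector(model$head$W %*% dlogits)
  dfused <- array(rep(dgap / HW, each = HW), dim = dim(fwd$fused))
  C <- dim(fwd$fm)[3L]
  if (!is.null(model$attention)) {
    dfm <- dfused[, , seq_len(C), drop = FALSE]
    datt <- dfused[, , -seq_len(C), drop = FALSE]
    ab <- mccbam_backward(datt, fwd$att, model$cfg$attention,
                          model$attention)
    dfm <- dfm + ab$dfm
    for (blk in names(ab$grads))
      for (nm in names(ab$grads[[blk]]))
        grads[[paste0("att.", blk, ".", nm)]] <- ab$grads[[blk]][[nm]]
  } else {
    dfm <- dfused
  }
  bb <- backbone_backward(model$backbone, fwd$bb$caches, dfm)
  c(grads, bb$grads)
}

#' Class probabilities for a batch of images
#'
#' @param object an `hccanet` model.
#' @param images list of H x W x 3 arrays matching the configured input
#'   size (already preprocessed/standardized).
#' @param ... unused.
#' @return n x 3 matrix of class probabilities (columns I, II, III).
#' @export
predict.hccanet <- function(object, images, ...) {
  probs <- t(vapply(images,
                    function(x) hccanet_forward(object, x)$probs,
                    numeric(3L)))
  colnames(probs) <- object$classes
  probs
}

# ---- parameter plumbing (flat named lists for the optimizer) ----

get_params <- function(model, trainable_only = FALSE) {
  params <- list()
  for (l in model$backbone$layers) {
    if (l$type != "conv") next
    if (trainable_only && !l$trainable) next
    params[[paste0("bb.", l$name, ".W")]] <- l$W
    params[[paste0("bb.", l$name, ".b")]] <- l$b
  }
  if (!is.null(model$attention)) {
    for (r in names(model$attention$sk))
      for (nm in c("W3", "b3", "W5", "b5", "W1", "b1", "W2", "b2"))
        params[[paste0("att.sk", r, ".", nm)]] <- model$attention$sk[[r]][[nm]]
    params[["att.spatial.W"]] <- model$attention$spatial$W
    params[["att.spatial.b"]] <- model$attention$spatial$b
  }
  params[["head.W"]] <- model$head$W
  params[["head.b"]] <- model$head$b
  params
}

set_params <- function(model, params) {
  for (i in seq_along(model$backbone$layers)) {
    l <- model$backbone$layers[[i]]
    if (l$type != "conv") next
    wn <- paste0("bb.", l$name, ".W")
    if (!is.null(params[[wn]])) {
      model$backbone$layers[[i]]$W <- params[[wn]]
      model$backbone$layers[[i]]$b <- params[[paste0("bb.", l$name, ".b")]]
    }
  }
  if (!is.null(model$attention)) {
    for (r in names(model$attention$sk))
      for (nm in c("W3", "b3", "W5", "b5", "W1", "b1", "W2", "b2")) {
        pn <- paste0("att.sk", r, ".", nm)
        if (!is.null(params[[pn]])) model$attention$sk[[r]][[nm]] <- params[[pn]]
      }
    if (!is.null(params[["att.spatial.W"]])) {
      model$attention$spatial$W <- params[["att.spatial.W"]]
      model$attention$spatial$b <- params[["att.spatial.b"]]
    }
  }
  if (!is.null(params[["head.W"]])) {
    model$head$W <- params[["head.W"]]
    model$head$b <- params[["head.b"]]
  }
  model
}

#' Count model parameters
#'
#' @param model an `hccanet` model or `hccanet_backbone`.
#' @param trainable_only count only parameters the optimizer updates.
#' @return integer count.
#' @export
n_params <- function(model, trainable_only = FALSE) {
  if (inherits(model, "hccanet_backbone"))
    model <- list(backbone = model, attention = NULL,
                  head = list(W = numeric(0), b = numeric(0)))
  sum(vapply(get_params(model, trainable_only), length, integer(1)))
}

#' Architecture summary
#'
#' @param model an `hccanet` model.
#' @return data frame with layer name, type, output channels and trainable
#'   flag (backbone), plus attention/head rows.
#' @export
model_summary <- function(model) {
  rows <- lapply(model$backbone$layers, function(l)
    data.frame(name = l$name, type = l$type,
               channels = if (l$type == "conv") length(l$b) else NA_integer_,
               trainable = if (l$type == "conv") l$trainable else NA))
  C <- model$backbone$out_channels
  rows[[length(rows) + 1L]] <-
    data.frame(name = "mccbam", type = "attention",
               channels = if (is.null(model$attention)) NA_integer_ else 3L * C,
               trainable = !is.null(model$attention))
  rows[[length(rows) + 1L]] <-
    data.frame(name = "head", type = "dense",
               channels = 3L, trainable = TRUE)
  do.call(rbind, rows)
}
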