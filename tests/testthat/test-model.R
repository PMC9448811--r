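test_that("full-width backbone maps 224x224x3 to the canonical 7x7x512", {
  bb <- build_backbone(backbone_config(), seed = 1L)
  set.seed(1)
  x <- array(rnorm(224 * 224 * 3), c(224L, 224L, 3L))
  out <- hccanet:::backbone_forward(bb, x)$out
  expect_identical(dim(out), c(7L, 7L, 512L))
  expect_true(all(is.finite(out)))
})

test_that("freeze boundary controls trainable flags and parameter counts", {
  bb_default <- build_backbone(backbone_config(width_multiplier = 1 / 8))
  frozen <- vapply(bb_default$layers, function(l)
    if (l$type == "conv") !l$trainable else NA, logical(1))
  expect_true(all(frozen[c(1, 2, 4, 5)]))        # blocks 1-2 frozen
  expect_false(any(frozen[-c(1, 2, 4, 5)], na.rm = TRUE))
  bb_all <- build_backbone(backbone_config(width_multiplier = 1 / 8,
                                           freeze_until = "block1_conv1"))
  expect_false(any(vapply(bb_all$layers, function(l)
    if (l$type == "conv") !l$trainable else FALSE, logical(1))))
  expect_lt(n_params(bb_default, trainable_only = TRUE),
            n_params(bb_all, trainable_only = TRUE))
  expect_error(build_backbone(backbone_config(freeze_until = "nope")),
               "unknown freeze layer")
  # the study's own name for the boundary is accepted as an alias
  expect_identical(backbone_config(freeze_until = "Block_Conv3")$freeze_until,
                   "block3_conv1")
})

test_that("fused map has 4C channels and softmax output lies on the simplex", {
  m <- tiny_model(input = 32L, wm = 1 / 8)
  C <- m$backbone$out_channels
  expect_identical(m$fused_channels, 4L * C)
  set.seed(2)
  batch <- replicate(2, array(rnorm(32 * 32 * 3), c(32L, 32L, 3L)),
                     simplify = FALSE)
  probs <- predict(m, batch)
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), c(1, 1), tolerance = 1e-6)
  fwd <- hccanet:::hccanet_forward(m, batch[[1]])
  expect_identical(dim(fwd$fused)[3], 4L * C)
})

test_that("full-width fusion yields 512 + 1536 = 2048 channels", {
  m <- build_hccanet(hccanet_config(
    backbone_config(input_size = c(32L, 32L, 3L)), seed = 3L))
  expect_identical(m$fused_channels, 2048L)
  set.seed(3)
  fwd <- hccanet:::hccanet_forward(m, array(rnorm(32 * 32 * 3),
                                            c(32L, 32L, 3L)))
  expect_identical(dim(fwd$fused)[3], 2048L)
  expect_true(all(is.finite(fwd$fused)))
})

test_that("a 2-image forward pass at 224x224x3 completes and is finite", {
  m <- tiny_model(input = 224L, wm = 1 / 8)
  set.seed(4)
  for (i in 1:2) {
    p <- hccanet:::hccanet_forward(m, array(rnorm(224 * 224 * 3),
                                            c(224L, 224L, 3L)))$probs
    expect_true(all(is.finite(p)))
  }
})

test_that("disabling the attention branch reduces trainable parameters", {
  with_att <- tiny_model(use_attention = TRUE)
  without <- tiny_model(use_attention = FALSE)
  expect_lt(n_params(without, TRUE), n_params(with_att, TRUE))
  expect_identical(without$fused_channels, without$backbone$out_channels)
})

test_that("analytic gradients match central finite differences", {
  m <- tiny_model(input = 32L, wm = 1 / 16, seed = 5L)
  set.seed(9)
  x <- array(rnorm(32 * 32 * 3), c(32L, 32L, 3L))
  fwd <- hccanet:::hccanet_forward(m, x, keep = TRUE)
  dl <- fwd$probs; dl[2] <- dl[2] - 1
  g <- hccanet:::hccanet_backward(m, fwd, dl)
  loss_of <- function(mod) -log(hccanet:::hccanet_forward(mod, x)$probs[2])
  p <- hccanet:::get_params(m, trainable_only = TRUE)
  eps <- 1e-6
  for (nm in c("head.W", "att.sk4.W1", "att.sk16.W2", "att.spatial.W",
               "bb.block5_conv3.W", "bb.block3_conv1.b")) {
    i <- min(3, length(p[[nm]]))
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
    lp <- loss_of(hccanet:::set_params(m, p2))
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    lm <- loss_of(hccanet:::set_params(m, p2))
    num <- (lp - lm) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                 label = paste("gradient of", nm))
  }
})

test_that("one optimization step leaves frozen weights bit-identical", {
  m <- tiny_model(input = 32L, wm = 1 / 16, seed = 6L)
  before <- hccanet:::get_params(m)
  set.seed(10)
  xs <- replicate(4, array(rnorm(32 * 32 * 3), c(32L, 32L, 3L)),
                  simplify = FALSE)
  fit <- train(m, list(x = xs, y = c("I", "II", "III", "I")),
               cfg = train_config(epochs = 1L, batch_size = 4L, seed = 1L))
  after <- hccanet:::get_params(fit$model)
  frozen_names <- grep("^bb\\.block[12]_", names(before), value = TRUE)
  expect_gt(length(frozen_names), 0L)
  for (nm in frozen_names) expect_identical(after[[nm]], before[[nm]])
  expect_false(identical(after[["head.W"]], before[["head.W"]]))
})

test_that("architecture summary reports every layer with channels and flags", {
  m <- tiny_model(wm = 1 / 8)
  s <- model_summary(m)
  expect_identical(sum(s$type == "conv"), 13L)
  expect_identical(sum(s$type == "pool"), 5L)
  expect_identical(s$channels[s$name == "mccbam"],
                   3L * m$backbone$out_channels)
})

test_that("input sizes not divisible by 32 are rejected", {
  expect_error(backbone_config(input_size = c(100L, 100L, 3L)),
               "divisible by 32")
})
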