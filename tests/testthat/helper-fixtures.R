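# Shared fixtures, built in code at test time.

random_fm <- function(seed, d = c(4L, 4L, 2L)) {
  set.seed(seed)
  array(rnorm(prod(d)), dim = d)
}

# attention weights with all FC (and optionally spatial) parameters zeroed
zeroed_fc_weights <- function(channels, cfg = mccbam_config(), seed = 1L,
                              zero_spatial = FALSE) {
  w <- attention_weights(channels, cfg, seed)
  for (r in names(w$sk)) {
    w$sk[[r]]$W1[] <- 0; w$sk[[r]]$b1[] <- 0
    w$sk[[r]]$W2[] <- 0; w$sk[[r]]$b2[] <- 0
  }
  if (zero_spatial) { w$spatial$W[] <- 0; w$spatial$b <- 0 }
  w
}

tiny_model <- function(input = 32L, wm = 1 / 16, seed = 5L,
                       use_attention = TRUE, freeze = "block3_conv1") {
  build_hccanet(hccanet_config(
    backbone_config(input_size = c(input, input, 3L),
                    width_multiplier = wm, freeze_until = freeze),
    use_attention = use_attention, seed = seed))
}

small_synth_set <- function(n_per_class, size = 64L, seed = 11L) {
  generate_dataset(synthetic_dataset_spec(
    n_per_class = n_per_class, image_size = c(size, size), seed = seed))
}

standardize_all <- function(imgs, std = fit_standardizer(imgs)) {
  list(x = lapply(imgs, apply_standardizer, state = std), std = std)
}

# cheap order-sensitive content digest for comparing image multisets
digest_vec <- function(x) {
  v <- as.vector(x)
  sum(v * (seq_along(v) %% 97 + 1)) + sum(v^2)
}
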