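#' @useDynLib hccanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-item 32-bit seed from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647L)
}

# Bind H x W x C arrays along the channel axis.
concat_channels <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  stopifnot(length(d) == 3L)
  for (a in arrs) stopifnot(identical(dim(a)[1:2], d[1:2]))
  channels <- vapply(arrs, function(a) dim(a)[3L], integer(1))
  out <- array(0, dim = c(d[1L], d[2L], sum(channels)))
  at <- 0L
  for (a in arrs) {
    out[, , at + seq_len(dim(a)[3L])] <- a
    at <- at + dim(a)[3L]
  }
  out
}

# Uniform fan-in initialization: U(-s, s) with s = sqrt(6 / fan_in), the
# rectifier-preserving (He) scale, so activations neither die nor blow up
# through the deep stack.
init_uniform <- function(dims, fan_in) {
  s <- sqrt(6 / fan_in)
  array(runif(prod(dims), -s, s), dim = dims)
}

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be an H x W x C array")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  x
}
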