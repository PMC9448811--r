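#' Denoising filter specification
#'
#' @param family one of `"mean"`, `"median"`, `"gaussian"`, `"bilateral"`.
#' @param kernel odd window size (the study sweeps 3, 5, 7).
#' @param gaussian_sigma standard deviation of the gaussian kernel; when
#'   `NULL` it is derived from the kernel size as
#'   `0.3 * ((k - 1)/2 - 1) + 0.8`, the usual kernel-to-sigma convention.
#' @param bilateral_sigma_color,bilateral_sigma_space range and spatial
#'   sigmas of the bilateral filter (intensity units / pixels).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(family = c("gaussian", "mean", "median", "bilateral"),
                        kernel = 3L, gaussian_sigma = NULL,
                        bilateral_sigma_color = 75,
                        bilateral_sigma_space = 75) {
  family <- match.arg(family)
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 1L) stop("kernel size must be odd and >= 1")
  if (is.null(gaussian_sigma))
    gaussian_sigma <- 0.3 * ((kernel - 1) / 2 - 1) + 0.8
  if (gaussian_sigma <= 0 || bilateral_sigma_color <= 0 ||
      bilateral_sigma_space <= 0)
    stop("sigmas must be positive")
  structure(list(family = family, kernel = kernel,
                 gaussian_sigma = gaussian_sigma,
                 bilateral_sigma_color = bilateral_sigma_color,
                 bilateral_sigma_space = bilateral_sigma_space),
            class = "filter_spec")
}

#' Normalized 2-D gaussian kernel
#'
#' @param k odd kernel size.
#' @param sigma positive standard deviation in pixels.
#' @return `k x k` matrix summing to 1.
#' @export
gaussian_kernel <- function(k, sigma) {
  if (k %% 2L == 0L) stop("kernel size must be odd")
  d <- seq_len(k) - (k + 1) / 2
  g <- exp(-d^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

apply_per_channel <- function(img, fun) {
  if (is.matrix(img)) return(fun(img))
  out <- img
  for (c in seq_len(dim(img)[3L])) out[, , c] <- fun(img[, , c])
  out
}

#' Denoise an image
#'
#' Applies one of four filter families per channel with replicate-border
#' handling: mean (box average), median, gaussian (dense convolution with a
#' normalized kernel) or bilateral (joint spatial/range gaussian weights).
#'
#' @param img H x W x 3 array or single-channel matrix.
#' @param spec a [filter_spec()].
#' @return filtered image, same shape.
#' @export
denoise <- function(img, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  k <- spec$kernel
  fun <- switch(spec$family,
    mean = function(m) cpp_filter_mean(m, k),
    median = function(m) cpp_filter_median(m, k),
    gaussian = local({
      kern <- gaussian_kernel(k, spec$gaussian_sigma)
      function(m) cpp_conv2_replicate(m, kern)
    }),
    bilateral = function(m)
      cpp_filter_bilateral(m, k, spec$bilateral_sigma_color,
                           spec$bilateral_sigma_space))
  apply_per_channel(img, fun)
}

#' Resize an image bilinearly
#'
#' Half-pixel centre alignment (the convention of mainstream image
#' libraries), edge clamped.
#'
#' @param img H x W x C array or matrix.
#' @param target `c(height, width)`, default `c(224, 224)` to fit the
#'   backbone input.
#' @return resized image.
#' @export
resize_image <- function(img, target = c(224L, 224L)) {
  stopifnot(length(target) == 2L, all(target >= 1L))
  if (is.matrix(img)) return(cpp_resize_bilinear(img, target[1L], target[2L]))
  C <- dim(img)[3L]
  out <- array(0, dim = c(target[1L], target[2L], C))
  for (c in seq_len(C))
    out[, , c] <- cpp_resize_bilinear(img[, , c], target[1L], target[2L])
  out
}

#' Fit a per-feature standardizer on a training set
#'
#' Each pixel position x channel is a feature; across the fitting images its
#' mean is subtracted and the result divided by its standard deviation, so
#' every feature of the fitting set has mean 0 and variance 1. Zero-variance
#' features are masked and map to 0.
#'
#' @param train_images list of equally shaped arrays (at least 2).
#' @return object of class `standardizer` with `mean`, `sd` and
#'   `zero_variance` arrays.
#' @export
fit_standardizer <- function(train_images) {
  if (length(train_images) < 2L) stop("need at least 2 images to fit")
  d <- dim(train_images[[1L]])
  n <- length(train_images)
  x <- matrix(0, nrow = prod(d), ncol = n)
  for (i in seq_len(n)) {
    if (!identical(dim(train_images[[i]]), d)) stop("images differ in shape")
    x[, i] <- as.vector(train_images[[i]])
  }
  mu <- rowMeans(x)
  # population standard deviation, matching the usual scaler convention
  sdv <- sqrt(rowMeans((x - mu)^2))
  zv <- sdv == 0
  structure(list(mean = array(mu, dim = d),
                 sd = array(ifelse(zv, 1, sdv), dim = d),
                 zero_variance = array(zv, dim = d),
                 dim = d),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param state a [fit_standardizer()] result.
#' @param img image with the shape the state was fitted on.
#' @return standardized array; zero-variance features are 0.
#' @export
apply_standardizer <- function(state, img) {
  stopifnot(inherits(state, "standardizer"))
  if (!identical(dim(img), state$dim)) stop("image shape differs from fit")
  out <- (img - state$mean) / state$sd
  out[state$zero_variance] <- 0
  out
}

#' Read an RGB image (PNG or TIFF)
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return H x W x 3 array with intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB image (PNG or TIFF), 8-bit
#'
#' @param img H x W x 3 array in `[0, 255]` (clipped).
#' @param path destination path; format chosen by extension.
#' @export
write_image <- function(img, path) {
  x <- pmin(pmax(img / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext))
  invisible(path)
}
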