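grade_levels <- c("I", "II", "III")

# Gland-coverage intervals defining the three differentiation grades:
# grade I > 95%, grade II 50-95%, grade III 5-50% glandular area.
grade_intervals <- list(
  I = c(0.95, 1.0),
  II = c(0.50, 0.95),
  III = c(0.05, 0.50)
)

#' Synthetic gland-texture dataset specification
#'
#' Describes a three-class texture dataset emulating histology patches of
#' colorectal adenocarcinoma at three differentiation grades. Each image is
#' a stroma-like textured background on which ring-shaped "glands" (bright
#' lumen, dark epithelial rim) are placed until a target area coverage drawn
#' from the grade's interval is reached; the ground-truth gland mask is kept
#' alongside. Grade I images are > 95% gland-covered, grade II 50-95%,
#' grade III 5-50%.
#'
#' @param n_per_class images per grade (default 210, i.e. 630 in total).
#' @param image_size `c(height, width)` in pixels; default `c(448, 448)` and
#'   freely scalable.
#' @param noise_sd additive gaussian pixel noise, 0-255 intensity units.
#' @param seed base RNG seed; every image derives its own seed from it.
#' @return object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_per_class = 210L,
                                   image_size = c(448L, 448L),
                                   noise_sd = 8, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  stopifnot(n_per_class >= 1L, length(image_size) == 2L,
            all(image_size >= 32L), noise_sd >= 0)
  structure(list(n_per_class = n_per_class,
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 intervals = grade_intervals),
            class = "synthetic_dataset_spec")
}

#' Generate one synthetic gland image
#'
#' Deterministic given `(spec$seed, per_image_seed)`. The target gland
#' coverage is drawn uniformly from the grade's interval; disks are placed
#' greedily (shrinking proposals that would overshoot the interval's upper
#' bound) until the ground-truth mask reaches the target. Glands are drawn
#' as bright lumina with dark epithelial rims over a smoothed pink stroma
#' texture, then additive gaussian noise is applied.
#'
#' @param grade `"I"`, `"II"` or `"III"`.
#' @param spec a [synthetic_dataset_spec()].
#' @param per_image_seed integer distinguishing images within the dataset.
#' @return list with `image` (H x W x 3, `[0, 255]`), `mask` (H x W logical
#'   ground-truth gland mask), `coverage` (realized fraction) and `grade`.
#' @export
generate_image <- function(grade, spec = synthetic_dataset_spec(),
                           per_image_seed = 1L) {
  if (!grade %in% grade_levels) stop("unknown grade: ", grade)
  iv <- spec$intervals[[grade]]
  H <- spec$image_size[1L]; W <- spec$image_size[2L]
  with_seed(derive_seed(spec$seed, per_image_seed), {
    # upper bound open for grade III (coverage must stay below 50%)
    upper <- if (grade == "III") iv[2L] - 1 / (H * W) else iv[2L]
    target <- runif(1L, iv[1L] + 1e-6, iv[1L] + 0.9 * (upper - iv[1L]))
    rmin <- max(3, round(min(H, W) / 28))
    rmax <- max(rmin + 2, round(min(H, W) / 9))
    placed <- cpp_place_glands(H, W, target, upper, rmin, rmax, 50000L)
    code <- cpp_render_glands(H, W, placed$cy, placed$cx, placed$r, 0.62)
    # stroma background: smoothed noise modulating a pink base tone
    tex <- cpp_conv2_replicate(matrix(runif(H * W, -1, 1), H, W),
                               gaussian_kernel(7L, 1.5))
    base <- list(c(214, 148, 180), c(238, 232, 242), c(118, 82, 150))
    jit <- runif(3L, -10, 10)
    img <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- matrix(base[[1L]][ch], H, W) + 28 * tex
      plane[code == 1L] <- base[[2L]][ch] + 6 * tex[code == 1L]
      plane[code == 2L] <- base[[3L]][ch] + 14 * tex[code == 2L]
      img[, , ch] <- plane + jit[ch]
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(H * W * 3L, 0, spec$noise_sd), dim = dim(img))
    img <- pmin(pmax(img, 0), 255)
    list(image = img, mask = placed$mask == 1L, coverage = placed$coverage,
         grade = grade)
  })
}

new_labeled_dataset <- function(images, masks, labels, source, coverage) {
  labels <- factor(labels, levels = grade_levels)
  structure(list(images = images, masks = masks, labels = labels,
                 source = source, coverage = coverage,
                 class_counts = table(labels)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", length(x$images), "images\n")
  print(x$class_counts)
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$images)

subset_dataset <- function(ds, idx) {
  new_labeled_dataset(ds$images[idx], ds$masks[idx],
                      as.character(ds$labels[idx]), ds$source[idx],
                      ds$coverage[idx])
}

#' Generate a labeled synthetic dataset
#'
#' `n_per_class` images per grade. Images are grouped into synthetic
#' "sources" of six images each (mirroring several patches cut from one
#' tissue section), so grouped splitting can be exercised.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @return a `labeled_dataset` with images, ground-truth masks, grade
#'   labels, source identifiers and realized coverages.
#' @export
generate_dataset <- function(spec = synthetic_dataset_spec()) {
  images <- list(); masks <- list()
  labels <- character(0); source <- character(0); coverage <- numeric(0)
  idx <- 0L
  for (g in grade_levels) {
    for (i in seq_len(spec$n_per_class)) {
      idx <- idx + 1L
      item <- generate_image(g, spec, per_image_seed = idx)
      images[[idx]] <- item$image
      masks[[idx]] <- item$mask
      labels[idx] <- g
      source[idx] <- sprintf("%s_s%03d", g, (i - 1L) %/% 6L + 1L)
      coverage[idx] <- item$coverage
    }
  }
  new_labeled_dataset(images, masks, labels, source, coverage)
}

#' Train/validation/test split specification
#'
#' @param ratios positive fractions summing to 1; default `c(0.8, 0.1, 0.1)`.
#' @param seed RNG seed for the shuffle.
#' @param stratified preserve class proportions per subset (default TRUE).
#' @param group_key optional item field (e.g. `"source"`) whose groups must
#'   never straddle subsets; default `NULL` reproduces plain image-level
#'   splitting (note that patches from one section then can leak across
#'   subsets).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(0.8, 0.1, 0.1), seed = 1L,
                       stratified = TRUE, group_key = NULL) {
  stopifnot(length(ratios) == 3L, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-8)
  structure(list(ratios = ratios, seed = as.integer(seed),
                 stratified = stratified, group_key = group_key),
            class = "split_spec")
}

allocate_counts <- function(n, ratios) {
  n_val <- floor(n * ratios[2L])
  n_test <- floor(n * ratios[3L])
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

#' Split a dataset 8:1:1
#'
#' Subsets are disjoint and their union is the input. With stratification
#' the allocation is per class; subset sizes are floor-allocated with all
#' remainders going to the training subset. With `group_key` set, whole
#' groups are assigned to one subset (sizes then only approximate the
#' ratios; a warning reports the discrepancy when it is large).
#'
#' @param ds a `labeled_dataset`.
#' @param spec a [split_spec()].
#' @return list of `labeled_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n <- length(ds$images)
  if (n == 0L) stop("dataset is empty")
  subsets <- character(n)
  strata <- if (spec$stratified) split(seq_len(n), ds$labels)
            else list(all = seq_len(n))
  with_seed(spec$seed, {
    for (str_idx in strata) {
      if (length(str_idx) == 0L) next
      if (is.null(spec$group_key)) {
        sh <- sample(str_idx)
        cnt <- allocate_counts(length(sh), spec$ratios)
        subsets[sh] <- rep(c("train", "val", "test"), times = cnt)
      } else {
        keys <- ds[[spec$group_key]][str_idx]
        groups <- split(str_idx, keys)
        groups <- groups[sample(length(groups))]
        cnt <- allocate_counts(length(str_idx), spec$ratios)
        got <- c(train = 0L, val = 0L, test = 0L)
        # fill val and test first (smallest quotas), remainder to train
        for (g in groups) {
          tgt <- if (got["test"] + length(g) <= cnt["test"]) "test"
                 else if (got["val"] + length(g) <= cnt["val"]) "val"
                 else "train"
          subsets[g] <- tgt
          got[tgt] <- got[tgt] + length(g)
        }
        if (got["val"] < cnt["val"] || got["test"] < cnt["test"])
          warning("group sizes incompatible with the requested ratios; ",
                  "validation/test subsets are smaller than the quota")
      }
    }
  })
  list(train = subset_dataset(ds, which(subsets == "train")),
       val = subset_dataset(ds, which(subsets == "val")),
       test = subset_dataset(ds, which(subsets == "test")))
}

#' Augmentation specification
#'
#' @param target_count total size of the augmented training set (default
#'   4500; the three classes are balanced to `target_count/3` each).
#' @param operations subset of `c("rotation", "crop", "scale")`.
#' @param rotation_range maximal absolute rotation in degrees (default 30).
#' @param crop_range crop side fraction interval (default `c(0.8, 1)`).
#' @param scale_range zoom factor interval (default `c(0.9, 1.1)`).
#' @param seed RNG seed.
#' @return object of class `augment_spec`.
#' @export
augment_spec <- function(target_count = 4500L,
                         operations = c("rotation", "crop", "scale"),
                         rotation_range = 30, crop_range = c(0.8, 1),
                         scale_range = c(0.9, 1.1), seed = 1L) {
  operations <- match.arg(operations, several.ok = TRUE)
  stopifnot(target_count >= 1L, rotation_range > 0,
            crop_range[1L] < crop_range[2L], crop_range[1L] > 0,
            scale_range[1L] < scale_range[2L], scale_range[1L] > 0)
  structure(list(target_count = as.integer(target_count),
                 operations = operations, rotation_range = rotation_range,
                 crop_range = crop_range, scale_range = scale_range,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

rotate_image <- function(img, angle_deg) {
  th <- angle_deg * pi / 180
  # inverse mapping: rotate sample coordinates by -angle
  apply_per_channel(img, function(m)
    cpp_affine_warp(m, cos(th), -sin(th), sin(th), cos(th), 0, 0))
}

crop_resize_image <- function(img, frac, cy_off, cx_off) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  h <- max(2L, round(H * frac)); w <- max(2L, round(W * frac))
  i0 <- 1L + round(cy_off * (H - h)); j0 <- 1L + round(cx_off * (W - w))
  resize_image(img[i0:(i0 + h - 1L), j0:(j0 + w - 1L), , drop = FALSE],
               c(H, W))
}

scale_image <- function(img, factor) {
  # zoom about the centre; inverse mapping scales by 1/factor
  s <- 1 / factor
  apply_per_channel(img, function(m) cpp_affine_warp(m, s, 0, 0, s, 0, 0))
}

#' Augment a training split to a fixed size
#'
#' Keeps every original and adds label-preserving variants (rotation within
#' +-30 degrees, random crop at 0.8-1.0 side fraction resized back, zoom at
#' 0.9-1.1) cycling over the originals of each class until per-class totals
#' reach `target_count / 3`. Every variant records its source item and
#' operation parameters in the `augmentation_log` attribute.
#'
#' @param train a `labeled_dataset` (the training split).
#' @param spec an [augment_spec()].
#' @return a `labeled_dataset` of exactly `target_count` items with an
#'   `augmentation_log` attribute (data frame).
#' @export
augment_to <- function(train, spec = augment_spec()) {
  stopifnot(inherits(train, "labeled_dataset"))
  n <- length(train$images)
  if (spec$target_count < n)
    stop("target_count is smaller than the input split (", n, ")")
  if (spec$target_count == n) {
    attr(train, "augmentation_log") <-
      data.frame(variant = character(0), source = character(0),
                 op = character(0), param = numeric(0))
    return(train)
  }
  classes <- levels(train$labels)
  present <- classes[classes %in% train$labels]
  quota <- rep(spec$target_count %/% length(present), length(present))
  names(quota) <- present
  rem <- spec$target_count - sum(quota)
  if (rem > 0L) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  images <- train$images; masks <- train$masks
  labels <- as.character(train$labels); source <- train$source
  coverage <- train$coverage
  log <- list()
  with_seed(spec$seed, {
    for (cl in present) {
      cl_idx <- which(train$labels == cl)
      need <- quota[[cl]] - length(cl_idx)
      if (need < 0L)
        stop("class ", cl, " already exceeds its balanced quota")
      for (v in seq_len(need)) {
        src <- cl_idx[(v - 1L) %% length(cl_idx) + 1L]
        op <- sample(spec$operations, 1L)
        img <- train$images[[src]]
        param <- switch(op,
          rotation = {
            ang <- runif(1L, -spec$rotation_range, spec$rotation_range)
            img <- rotate_image(img, ang); ang
          },
          crop = {
            f <- runif(1L, spec$crop_range[1L], spec$crop_range[2L])
            img <- crop_resize_image(img, f, runif(1L), runif(1L)); f
          },
          scale = {
            f <- runif(1L, spec$scale_range[1L], spec$scale_range[2L])
            img <- scale_image(img, f); f
          })
        k <- length(images) + 1L
        images[[k]] <- img
        masks[k] <- list(NULL)
        labels[k] <- cl
        source[k] <- train$source[src]
        coverage[k] <- train$coverage[src]
        log[[length(log) + 1L]] <-
          data.frame(variant = sprintf("aug_%05d", k),
                     source = sprintf("item_%05d", src),
                     op = op, param = param)
      }
    }
  })
  out <- new_labeled_dataset(images, masks, labels, source, coverage)
  attr(out, "augmentation_log") <-
    if (length(log)) do.call(rbind, log)
    else data.frame(variant = character(0), source = character(0),
                    op = character(0), param = numeric(0))
  out
}

#' Write a dataset to disk
#'
#' Layout: `root/<grade>/<name>.png`, ground-truth masks as PNG in
#' `root/_masks/`, and a `manifest.csv` with columns path, grade, source.
#'
#' @param ds a `labeled_dataset`.
#' @param root destination directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(ds, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "_masks"), showWarnings = FALSE)
  rows <- vector("list", length(ds$images))
  for (i in seq_along(ds$images)) {
    g <- as.character(ds$labels[i])
    dir.create(file.path(root, g), showWarnings = FALSE)
    name <- sprintf("%s_%05d.png", g, i)
    path <- file.path(root, g, name)
    write_image(ds$images[[i]], path)
    if (!is.null(ds$masks[[i]]))
      png::writePNG(ds$masks[[i]] * 1, file.path(root, "_masks", name))
    rows[[i]] <- data.frame(path = file.path(g, name), grade = g,
                            source = ds$source[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param root dataset directory containing `manifest.csv`.
#' @return a `labeled_dataset` (masks are reloaded when present).
#' @export
read_dataset <- function(root) {
  manifest <- utils::read.csv(file.path(root, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- list(); masks <- list()
  for (i in seq_len(nrow(manifest))) {
    images[[i]] <- read_image(file.path(root, manifest$path[i]))
    mp <- file.path(root, "_masks", basename(manifest$path[i]))
    masks[[i]] <- if (file.exists(mp)) png::readPNG(mp) > 0.5 else NULL
  }
  new_labeled_dataset(images, masks, manifest$grade, manifest$source,
                      rep(NA_real_, nrow(manifest)))
}
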