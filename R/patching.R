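#' Patch sampling specification
#'
#' Patches are sampled from annotated regions after resampling the source
#' image to the working resolution (default 0.5 micron per pixel: bilinear
#' for pixels, nearest for labels). With `class_balanced = TRUE` (the
#' default) the center class is drawn uniformly among the classes present in
#' the image, then a pixel of that class is drawn uniformly; otherwise the
#' center pixel is uniform over all annotated pixels.
#'
#' @param shape integer length-2 patch shape, e.g. `c(412, 412)` (U-net
#'   default) or `c(128, 128)` (DenseNet default).
#' @param spacing target microns per pixel.
#' @param class_balanced logical.
#' @return list of class `patch_spec`.
#' @export
patch_spec <- function(shape = c(128, 128), spacing = 0.5,
                       class_balanced = TRUE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape > 0), spacing > 0)
  structure(list(shape = shape, spacing = spacing,
                 class_balanced = isTRUE(class_balanced)),
            class = "patch_spec")
}

#' Resample a labeled image to a target spacing
#'
#' Pixels are interpolated bilinearly, labels by nearest neighbour, both
#' with half-pixel-center alignment, so a structure at base spacing maps to
#' the geometrically corresponding pixels at the target spacing.
#'
#' @param image a [labeled_image()].
#' @param spacing target microns per pixel (must be >= the base spacing).
#' @return a [labeled_image()] at the new spacing.
#' @export
resample_labeled_image <- function(image, spacing) {
  stopifnot(spacing >= image$spacing)
  if (abs(spacing - image$spacing) < 1e-12) return(image)
  f <- image$spacing / spacing
  d <- dim(image$pixels)
  H2 <- max(1L, as.integer(round(d[1] * f)))
  W2 <- max(1L, as.integer(round(d[2] * f)))
  px <- cpp_resize_bilinear(image$pixels * 1.0, H2, W2)
  lb <- cpp_resize_nearest(image$labels, H2, W2)
  labeled_image(px, lb, spacing, image$case_id)
}

# mirror (reflect-101) index vector into 1..n
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * n - 2L
  m <- (i - 1L) %% period
  m[m < 0] <- m[m < 0] + period
  ifelse(m < n, m, period - m) + 1L
}

crop_mirror <- function(arr, y0, x0, h, w) {
  ys <- reflect_index(seq.int(y0, length.out = h), dim(arr)[1])
  xs <- reflect_index(seq.int(x0, length.out = w), dim(arr)[2])
  if (length(dim(arr)) == 3) arr[ys, xs, , drop = FALSE] else arr[ys, xs]
}

#' Sample one training patch from an annotated image
#'
#' The image is resampled to the spec's spacing, a patch center is chosen
#' among annotated pixels (class-balanced or uniform), and the patch is
#' cropped with mirror padding at borders. Uses R's RNG stream; seed the
#' session for reproducibility.
#'
#' @param image a [labeled_image()] with at least one annotated pixel.
#' @param spec a [patch_spec()].
#' @param resampled optional pre-resampled image (cached by [patch_sampler()])
#'   to avoid repeating the rescale.
#' @return list with `pixels` (h x w x 3, 0..255) and `labels` (h x w).
#' @export
sample_patch <- function(image, spec, resampled = NULL) {
  img <- if (is.null(resampled)) resample_labeled_image(image, spec$spacing)
         else resampled
  ann <- which(img$labels != unlabeled_value())
  if (length(ann) == 0) stop("image '", image$case_id,
                             "' has no annotated pixels")
  if (spec$class_balanced) {
    present <- sort(unique(img$labels[ann]))
    cls <- present[sample.int(length(present), 1)]
    pool <- ann[img$labels[ann] == cls]
  } else {
    pool <- ann
  }
  center <- pool[sample.int(length(pool), 1)]
  H <- dim(img$labels)[1]
  cy <- (center - 1) %% H + 1
  cx <- (center - 1) %/% H + 1
  h <- spec$shape[1]
  w <- spec$shape[2]
  y0 <- cy - h %/% 2
  x0 <- cx - w %/% 2
  list(pixels = crop_mirror(img$pixels, y0, x0, h, w),
       labels = crop_mirror(img$labels, y0, x0, h, w))
}

#' Build a caching patch sampler over a set of images
#'
#' Resamples every image to the spec's spacing once, then draws patches from
#' a uniformly chosen image per call.
#'
#' @param images list of [labeled_image()].
#' @param spec a [patch_spec()].
#' @return function(n) returning a list of n patches.
#' @export
patch_sampler <- function(images, spec) {
  cache <- lapply(images, resample_labeled_image, spacing = spec$spacing)
  keep <- vapply(cache, function(im) {
    any(im$labels != unlabeled_value())
  }, TRUE)
  cache <- cache[keep]
  if (length(cache) == 0) stop("no image with annotated pixels")
  function(n) {
    lapply(seq_len(n), function(i) {
      im <- cache[[sample.int(length(cache), 1)]]
      sample_patch(im, spec, resampled = im)
    })
  }
}

# ---- augmentation -----------------------------------------------------------

#' Augmentation configuration
#'
#' Geometric transforms (right-angle rotations, horizontal/vertical flips)
#' are applied identically to pixels and labels; photometric transforms
#' (Gaussian blur, Gaussian noise, HSV color jitter) touch pixels only.
#' Both blur and noise are included, each with its own probability.
#'
#' @param p_rotate probability of drawing a rotation (uniform over
#'   0/90/180/270 degrees).
#' @param p_hflip,p_vflip flip probabilities.
#' @param p_blur probability of Gaussian blur; sigma drawn from
#'   `blur_sigma` range (pixels).
#' @param p_noise probability of additive Gaussian noise; sd drawn from
#'   `noise_sd` range (on the 0..1 intensity scale).
#' @param p_color probability of HSV jitter with amplitudes `hue`,
#'   `saturation`, `value` (additive, uniform in +/- amplitude).
#' @return list of class `augment_config`.
#' @export
augment_config <- function(p_rotate = 1, p_hflip = 0.5, p_vflip = 0.5,
                           p_blur = 0.25, blur_sigma = c(0.5, 1.5),
                           p_noise = 0.25, noise_sd = c(0.01, 0.05),
                           p_color = 0.5, hue = 0.02, saturation = 0.1,
                           value = 0.1) {
  probs <- c(p_rotate, p_hflip, p_vflip, p_blur, p_noise, p_color)
  stopifnot(all(probs >= 0), all(probs <= 1),
            all(c(hue, saturation, value) >= 0),
            all(blur_sigma > 0), all(noise_sd >= 0))
  structure(list(p_rotate = p_rotate, p_hflip = p_hflip, p_vflip = p_vflip,
                 p_blur = p_blur, blur_sigma = blur_sigma,
                 p_noise = p_noise, noise_sd = noise_sd,
                 p_color = p_color, hue = hue, saturation = saturation,
                 value = value),
            class = "augment_config")
}

rot90_mat <- function(m, k) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

rot90_arr <- function(a, k) {
  k <- k %% 4
  if (k == 0) return(a)
  out <- NULL
  for (ch in seq_len(dim(a)[3])) {
    r <- rot90_mat(a[, , ch], k)
    if (is.null(out)) out <- array(0, c(dim(r), dim(a)[3]))
    out[, , ch] <- r
  }
  out
}

# vectorized HSV -> RGB on 0..1 values
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Augment a patch
#'
#' @param pixels h x w x 3 array in 0..255.
#' @param labels h x w integer matrix.
#' @param config an [augment_config()].
#' @return list with transformed `pixels` and `labels`.
#' @export
augment <- function(pixels, labels, config) {
  if (runif(1) < config$p_rotate) {
    k <- sample(0:3, 1)
    if (k > 0) {
      pixels <- rot90_arr(pixels, k)
      labels <- rot90_mat(labels, k)
    }
  }
  if (runif(1) < config$p_hflip) {
    pixels <- pixels[, rev(seq_len(dim(pixels)[2])), , drop = FALSE]
    labels <- labels[, rev(seq_len(ncol(labels))), drop = FALSE]
  }
  if (runif(1) < config$p_vflip) {
    pixels <- pixels[rev(seq_len(dim(pixels)[1])), , , drop = FALSE]
    labels <- labels[rev(seq_len(nrow(labels))), , drop = FALSE]
  }
  if (runif(1) < config$p_blur) {
    sigma <- runif(1, config$blur_sigma[1], config$blur_sigma[2])
    pixels <- cpp_gauss_blur(pixels * 1.0, sigma)
  }
  if (runif(1) < config$p_noise) {
    sd <- runif(1, config$noise_sd[1], config$noise_sd[2])
    pixels <- pixels + rnorm(length(pixels), 0, sd * 255)
  }
  if (runif(1) < config$p_color) {
    d <- dim(pixels)
    X <- pmin(pmax(matrix(pixels, d[1] * d[2], 3) / 255, 0), 1)
    hsv <- t(grDevices::rgb2hsv(t(X), maxColorValue = 1))
    hsv[, 1] <- hsv[, 1] + runif(1, -config$hue, config$hue)
    hsv[, 2] <- pmin(pmax(hsv[, 2] +
                            runif(1, -config$saturation, config$saturation),
                          0), 1)
    hsv[, 3] <- pmin(pmax(hsv[, 3] +
                            runif(1, -config$value, config$value), 0), 1)
    pixels <- array(hsv_to_rgb(hsv[, 1], hsv[, 2], hsv[, 3]) * 255, d)
  }
  list(pixels = pmin(pmax(pixels, 0), 255), labels = labels)
}

#' Build an augmenter function from a configuration
#' @param config an [augment_config()].
#' @return function(patch) -> patch, where a patch is a
#'   `list(pixels, labels)`.
#' @export
augmenter <- function(config = augment_config()) {
  function(patch) augment(patch$pixels, patch$labels, config)
}
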