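# Run code under a temporary RNG state so generation is reproducible without
# disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive an independent, order-free sub-seed from a root seed and an index.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %%
               2147483587)
}

#' Configuration for the synthetic leaf/rust generator
#'
#' Describes the synthetic study images: one elliptical leaf per image on a
#' contrasting background, carrying zero or more reddish-orange rust spots
#' rendered as filled discs, with exact leaf and rust masks. Hues are jittered
#' per pixel but kept colour-separable (rust is the only region with red
#' dominating green), which is what the twelve state features and the
#' pixel-wise surrogate segmenter rely on.
#'
#' @param image_size Side length in pixels of the square images (512 mirrors
#'   the study resolution; 64 is the desk-scale size used throughout the
#'   package's tests).
#' @param n_images Number of images to generate.
#' @param rust_spot_count_range Integer interval `c(min, max)` for the number
#'   of rust spots per image.
#' @param rust_radius_range Interval for the spot radius, in pixels.
#' @param leaf_axis_range Interval for the leaf ellipse semi-axes, as a
#'   fraction of `image_size`.
#' @param leaf_hue,rust_hue,background_hue Mean RGB triples (0-255 scale).
#' @param hue_jitter Half-width of the uniform per-pixel jitter applied to
#'   each channel.
#' @param seed Root seed; the same config and seed give a bit-identical
#'   dataset. Per-image streams are derived from it, so generation order does
#'   not matter.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(image_size = 512L,
                             n_images = 20L,
                             rust_spot_count_range = c(0L, 4L),
                             rust_radius_range = NULL,
                             leaf_axis_range = c(0.22, 0.40),
                             leaf_hue = c(70, 150, 60),
                             rust_hue = c(205, 90, 40),
                             background_hue = c(105, 95, 80),
                             hue_jitter = 18,
                             seed = 1L) {
  if (is.null(rust_radius_range)) {
    rust_radius_range <- c(max(2, image_size / 24), max(3, image_size / 12))
  }
  stopifnot(image_size >= 16, n_images >= 1,
            length(rust_spot_count_range) == 2,
            rust_spot_count_range[1] >= 0,
            rust_spot_count_range[1] <= rust_spot_count_range[2],
            leaf_axis_range[1] > 0, leaf_axis_range[2] < 0.5)
  structure(
    list(image_size = as.integer(image_size), n_images = as.integer(n_images),
         rust_spot_count_range = as.integer(rust_spot_count_range),
         rust_radius_range = as.numeric(rust_radius_range),
         leaf_axis_range = as.numeric(leaf_axis_range),
         leaf_hue = leaf_hue, rust_hue = rust_hue,
         background_hue = background_hue, hue_jitter = hue_jitter,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Pixel-centre coordinate grids (0-based): row index y, column index x.
coord_grids <- function(n) {
  y <- matrix(rep(0:(n - 1), n), nrow = n)          # row index
  x <- matrix(rep(0:(n - 1), each = n), nrow = n)   # column index
  list(x = x, y = y)
}

fill_region <- function(image, mask, hue, jitter) {
  idx <- which(mask == 1L)
  n <- length(idx)
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[idx] <- pmin(255, pmax(0, hue[ch] + stats::runif(n, -jitter, jitter)))
    image[, , ch] <- plane
  }
  image
}

#' Generate one synthetic labelled leaf image
#'
#' Renders a filled elliptical leaf (random centre, semi-axes and orientation,
#' greenish hue with per-pixel jitter) on a contrasting background, then
#' places `k` rust spots (discs, reddish-orange) fully inside the leaf, where
#' `k` is drawn from `rust_spot_count_range`. The returned masks mark exactly
#' the rendered leaf and spot pixels.
#'
#' @param config A [generator_config()].
#' @param index 0-based image index (`index < n_images`); also seeds the
#'   per-image random stream, so any image can be regenerated independently.
#' @return A [labeled_image()] with id `img_<index>` (zero-padded).
#' @export
generate_leaf_image <- function(config, index) {
  stopifnot(inherits(config, "generator_config"), index >= 0,
            index < config$n_images)
  n <- config$image_size
  with_seed(derive_seed(config$seed, index), {
    g <- coord_grids(n)
    # leaf ellipse
    cx <- stats::runif(1, 0.38, 0.62) * (n - 1)
    cy <- stats::runif(1, 0.38, 0.62) * (n - 1)
    a <- stats::runif(1, config$leaf_axis_range[1], config$leaf_axis_range[2]) * n
    b <- stats::runif(1, config$leaf_axis_range[1], config$leaf_axis_range[2]) * n
    th <- stats::runif(1, 0, pi)
    u <- (g$x - cx) * cos(th) + (g$y - cy) * sin(th)
    v <- -(g$x - cx) * sin(th) + (g$y - cy) * cos(th)
    leaf <- matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), nrow = n)

    # rust spots: discs fully inside the leaf
    lo <- config$rust_spot_count_range[1]
    hi <- config$rust_spot_count_range[2]
    k <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    rust <- matrix(0L, n, n)
    leaf_idx <- which(leaf == 1L)
    for (s in seq_len(k)) {
      placed <- FALSE
      for (attempt in 1:100) {
        rad <- stats::runif(1, config$rust_radius_range[1],
                            config$rust_radius_range[2])
        ctr <- leaf_idx[sample.int(length(leaf_idx), 1)]
        scy <- (ctr - 1) %% n          # 0-based row
        scx <- (ctr - 1) %/% n         # 0-based column
        disc <- (g$x - scx)^2 + (g$y - scy)^2 <= rad^2
        if (all(leaf[disc] == 1L)) {
          rust[disc] <- 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place a rust spot inside the leaf after 100 attempts; ",
             "leaf_axis_range and rust_radius_range are inconsistent",
             call. = FALSE)
      }
    }

    img <- array(0, dim = c(n, n, 3))
    img <- fill_region(img, matrix(1L, n, n), config$background_hue,
                       config$hue_jitter)
    img <- fill_region(img, leaf, config$leaf_hue, config$hue_jitter)
    if (any(rust == 1L)) {
      img <- fill_region(img, rust, config$rust_hue, config$hue_jitter)
    }
    labeled_image(round(img), rust, leaf,
                  id = sprintf("img_%04d", index))
  })
}

#' Generate a synthetic dataset
#'
#' @param config A [generator_config()].
#' @return An [image_vector()] of `n_images` items with sequential zero-padded
#'   ids, generation 0. Bit-identical under the same config and seed.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  items <- lapply(seq_len(config$n_images) - 1L,
                  function(i) generate_leaf_image(config, i))
  image_vector(items, generation_index = 0L)
}

#' Split a dataset into pre-training and test sets
#'
#' Samples `round(test_fraction * n)` images (round-half-up) without
#' replacement into the test set; the rest form the pre-training set. An
#' image and its label masks never separate. With `n = 438` and
#' `test_fraction = 0.2` this yields 350 pre-training and 88 test images.
#'
#' @param images An [image_vector()].
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param seed Seed for the sampling.
#' @return A list with `image_vector` elements `pretrain` and `test`.
#' @export
split_dataset <- function(images, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(images, "image_vector"),
            test_fraction > 0, test_fraction < 1)
  n <- length(images)
  n_test <- as.integer(floor(test_fraction * n + 0.5))
  if (n_test < 1L || n_test >= n) {
    stop("split would leave an empty pre-training or test set", call. = FALSE)
  }
  test_idx <- with_seed(derive_seed(seed, 0L), sample.int(n, n_test))
  list(
    pretrain = image_vector(images$items[-test_idx], images$generation_index),
    test = image_vector(images$items[test_idx], images$generation_index)
  )
}
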