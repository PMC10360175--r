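#' The eight augmentation actions
#'
#' Action ids and their meanings. Ids are fixed: 0 original, 1 vertical flip
#' (top/bottom mirror), 2 horizontal flip (left/right mirror), 3 both flips,
#' 4 clockwise rotation by 30 degrees about the image centre, 5 affine shear
#' with forward map `(x', y') = (x + 0.2 y, y)`, 6 crop (trim the first 25
#' rows and columns, resize back to the original size), 7 additive white
#' Gaussian noise on the image only.
#'
#' @return A tibble with columns `action`, `name`, `description`.
#' @export
action_registry <- function() {
  tibble::tibble(
    action = 0:7,
    name = c("original", "vflip", "hflip", "vhflip", "rotate30",
             "affine_shear", "crop_resize", "gauss_noise"),
    description = c(
      "identity; the child equals the father",
      "mirror along the horizontal centre line (top/bottom swap)",
      "mirror along the vertical centre line (left/right swap)",
      "vertical then horizontal flip",
      "rotate 30 degrees clockwise about the image centre",
      "shear with matrix [[1, 0.2, 0], [0, 1, 0]] (x' = x + 0.2 y)",
      "trim the first 25 rows and 25 columns, resize back",
      "add white Gaussian noise (sd 10 by default) to the image only"
    )
  )
}

validate_action <- function(action) {
  if (length(action) != 1L || is.na(action) || action != as.integer(action) ||
      action < 0 || action > 7) {
    stop("unknown action id: ", action, " (valid ids are 0..7)", call. = FALSE)
  }
  as.integer(action)
}

# Inverse-mapping resampler shared by the geometric actions.
#
# `src_xy(xo, yo)` maps 0-based output pixel-centre coordinates (x = column,
# y = row) to source coordinates. Image channels are sampled bilinearly,
# labels with nearest neighbour, so label rasters stay in {0,1}. Out-of-frame
# sources are filled with `fill` (0: black image pixels, background labels).
warp_raster <- function(raster, src_xy, interp = c("bilinear", "nearest"),
                        fill = 0) {
  interp <- match.arg(interp)
  is_label <- is.matrix(raster)
  h <- dim(raster)[1]; w <- dim(raster)[2]
  g <- list(x = matrix(rep(0:(w - 1), each = h), nrow = h),
            y = matrix(rep(0:(h - 1), w), nrow = h))
  s <- src_xy(g$x, g$y)
  sample_plane <- function(plane) {
    out <- matrix(fill + 0, h, w)
    if (interp == "nearest") {
      xi <- round(s$x); yi <- round(s$y)
      ok <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
      out[ok] <- plane[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    } else {
      x0 <- floor(s$x); y0 <- floor(s$y)
      fx <- s$x - x0; fy <- s$y - y0
      ok <- x0 >= -1 & x0 <= (w - 1) & y0 >= -1 & y0 <= (h - 1)
      px <- function(yy, xx) {
        inside <- yy >= 0 & yy <= (h - 1) & xx >= 0 & xx <= (w - 1)
        v <- matrix(fill + 0, h, w)
        v[inside] <- plane[cbind(yy[inside] + 1L, xx[inside] + 1L)]
        v
      }
      v <- (1 - fx) * (1 - fy) * px(y0, x0) +
        fx * (1 - fy) * px(y0, x0 + 1) +
        (1 - fx) * fy * px(y0 + 1, x0) +
        fx * fy * px(y0 + 1, x0 + 1)
      out[ok] <- v[ok]
    }
    out
  }
  if (is_label) {
    out <- sample_plane(raster)
    storage.mode(out) <- "integer"
    out
  } else {
    res <- array(0, dim = dim(raster))
    for (ch in seq_len(dim(raster)[3])) res[, , ch] <- sample_plane(raster[, , ch])
    res
  }
}

# Geometric map for one action applied to a single raster (image array or
# label matrix). Exposed internally so the label co-transformation invariant
# can be checked against the same map applied to a bare raster.
transform_raster <- function(raster, action, interp) {
  h <- if (is.matrix(raster)) nrow(raster) else dim(raster)[1]
  w <- if (is.matrix(raster)) ncol(raster) else dim(raster)[2]
  switch(as.character(action),
    "1" = if (is.matrix(raster)) raster[h:1, , drop = FALSE] else raster[h:1, , , drop = FALSE],
    "2" = if (is.matrix(raster)) raster[, w:1, drop = FALSE] else raster[, w:1, , drop = FALSE],
    "3" = if (is.matrix(raster)) raster[h:1, w:1, drop = FALSE] else raster[h:1, w:1, , drop = FALSE],
    "4" = {
      # clockwise (on screen, y down) rotation about the exact centre;
      # inverse map rotates output coordinates counter-clockwise
      th <- 30 * pi / 180
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      warp_raster(raster, function(xo, yo) {
        dx <- xo - cx; dy <- yo - cy
        list(x = cx + cos(th) * dx + sin(th) * dy,
             y = cy - sin(th) * dx + cos(th) * dy)
      }, interp = interp)
    },
    "5" = {
      # forward map (x', y') = (x + 0.2 y, y) => inverse x = x' - 0.2 y'
      warp_raster(raster, function(xo, yo) list(x = xo - 0.2 * yo, y = yo),
                  interp = interp)
    },
    "6" = {
      if (h <= 25 || w <= 25) {
        stop("crop needs height and width > 25 pixels", call. = FALSE)
      }
      # output grid [0, n-1] maps onto the kept region [25, n-1]
      warp_raster(raster, function(xo, yo) {
        list(x = 25 + xo * (w - 26) / (w - 1),
             y = 25 + yo * (h - 26) / (h - 1))
      }, interp = interp)
    },
    stop("transform_raster: not a geometric action: ", action, call. = FALSE)
  )
}

#' Apply one augmentation action to a labelled image
#'
#' Geometric actions (1-6) transform the image and both label masks with the
#' identical geometric map; the image is resampled bilinearly and the labels
#' with nearest neighbour, so masks remain binary. Action 7 adds clipped
#' Gaussian noise to the image only and leaves both labels bit-identical.
#' Action 0 returns an identical copy. All actions preserve the image
#' dimensions.
#'
#' @param item A [labeled_image()].
#' @param action Integer action id in 0..7 (see [action_registry()]).
#' @param noise_sd Standard deviation of the Gaussian noise (8-bit scale) for
#'   action 7.
#' @param noise_seed Optional seed for action 7; when `NULL` the current RNG
#'   stream is used.
#' @return A new [labeled_image()] with the same id and dimensions.
#' @export
apply_action <- function(item, action, noise_sd = 10, noise_seed = NULL) {
  stopifnot(inherits(item, "labeled_image"))
  action <- validate_action(action)
  if (action == 0L) return(item)
  if (action == 7L) {
    add_noise <- function() {
      noise <- stats::rnorm(length(item$image), 0, noise_sd)
      array(pmin(255, pmax(0, as.vector(item$image) + noise)),
            dim(item$image))
    }
    img <- if (is.null(noise_seed)) add_noise() else with_seed(noise_seed, add_noise())
    return(labeled_image(img, item$rust_label, item$leaf_label, item$id))
  }
  labeled_image(
    image = transform_raster(item$image, action, interp = "bilinear"),
    rust_label = transform_raster(item$rust_label, action, interp = "nearest"),
    leaf_label = transform_raster(item$leaf_label, action, interp = "nearest"),
    id = item$id
  )
}

#' Apply an action vector to an image vector
#'
#' Element `i` of the child is `apply_action(vec[[i]], actions[i])`; the
#' positional father/child correspondence is preserved and the generation
#' index is incremented. Noise draws (action 7) come from per-position
#' streams derived from `noise_seed`, so the result is reproducible and
#' independent of evaluation order.
#'
#' @param vec An [image_vector()] (the father).
#' @param actions Integer vector of action ids, one per image.
#' @param noise_sd,noise_seed Passed to [apply_action()].
#' @return The child [image_vector()].
#' @export
apply_action_vector <- function(vec, actions, noise_sd = 10, noise_seed = 1L) {
  stopifnot(inherits(vec, "image_vector"))
  if (length(actions) != length(vec)) {
    stop("action vector length (", length(actions),
         ") must equal image vector length (", length(vec), ")", call. = FALSE)
  }
  items <- lapply(seq_along(actions), function(i) {
    apply_action(vec[[i]], actions[i], noise_sd = noise_sd,
                 noise_seed = derive_seed(noise_seed, i))
  })
  image_vector(items, generation_index = vec$generation_index + 1L)
}
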