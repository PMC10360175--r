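#' Geometric and colour features of a masked region
#'
#' The six per-region components of the state: normalized centroid, area
#' fraction, and per-channel mean colour. All components lie in `[0, 1]`; an
#' empty mask yields all zeros.
#'
#' @param image RGB array `h x w x 3`, values 0-255.
#' @param mask Binary matrix `h x w`.
#' @return Named numeric vector `c(x, y, A, R, G, B)`: `x` = mean column
#'   index of mask pixels / (w-1), `y` = mean row index / (h-1), `A` = mask
#'   pixel count / (h*w), `R`,`G`,`B` = channel means over mask pixels / 255.
#' @export
region_features <- function(image, mask) {
  mask <- normalize_label(mask)
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask == 1L)
  if (length(idx) == 0L) {
    return(c(x = 0, y = 0, A = 0, R = 0, G = 0, B = 0))
  }
  rows0 <- (idx - 1L) %% h        # 0-based row
  cols0 <- (idx - 1L) %/% h       # 0-based column
  c(
    x = mean(cols0) / (w - 1),
    y = mean(rows0) / (h - 1),
    A = length(idx) / (h * w),
    R = mean(image[, , 1][idx]) / 255,
    G = mean(image[, , 2][idx]) / 255,
    B = mean(image[, , 3][idx]) / 255
  )
}

#' Mask source for state extraction
#'
#' State features need a leaf mask and a rust mask per image. In `oracle`
#' mode the item's own label masks are used (deterministic; the default). In
#' `identifier` mode the masks are predictions of two trained segmentation
#' models: a LeafIdentifier (trained on leaf labels) and a RustIdentifier
#' (trained on rust labels).
#'
#' @param mode `"oracle"` or `"identifier"`.
#' @param leaf_identifier,rust_identifier Segmentation models (see
#'   [pretrain()]); required in identifier mode.
#' @return A list of class `mask_source`.
#' @export
mask_source <- function(mode = c("oracle", "identifier"),
                        leaf_identifier = NULL, rust_identifier = NULL) {
  mode <- match.arg(mode)
  if (mode == "identifier" &&
      (is.null(leaf_identifier) || is.null(rust_identifier))) {
    stop("identifier mode needs both a leaf and a rust identifier model",
         call. = FALSE)
  }
  structure(list(mode = mode, leaf_identifier = leaf_identifier,
                 rust_identifier = rust_identifier),
            class = "mask_source")
}

#' Names of the twelve state features, in their fixed order
#' @return Character vector of length 12.
#' @export
state_feature_names <- function() {
  c("x_l", "y_l", "A_l", "R_l", "G_l", "B_l",
    "x_r", "y_r", "A_r", "R_r", "G_r", "B_r")
}

#' Extract the 12-feature state of one image
#'
#' Concatenates the leaf-region and rust-region features (see
#' [region_features()]): leaf centroid, area and mean colour followed by the
#' same six quantities for the rust region.
#'
#' @param item A [labeled_image()].
#' @param source A [mask_source()].
#' @return Named numeric vector of length 12, all components in `[0, 1]`.
#' @export
extract_state <- function(item, source = mask_source("oracle")) {
  stopifnot(inherits(item, "labeled_image"), inherits(source, "mask_source"))
  if (source$mode == "oracle") {
    leaf_mask <- item$leaf_label
    rust_mask <- item$rust_label
  } else {
    leaf_mask <- predict_mask(source$leaf_identifier, item$image)
    rust_mask <- predict_mask(source$rust_identifier, item$image)
  }
  lf <- region_features(item$image, leaf_mask)
  rf <- region_features(item$image, rust_mask)
  stats::setNames(c(lf, rf), state_feature_names())
}

#' Extract the state vector of an image vector
#'
#' One row per image, aligned with the image vector's order; the state vector
#' always has exactly as many elements as the father image vector.
#'
#' @param vec An [image_vector()].
#' @param source A [mask_source()].
#' @return A tibble with column `id` plus the twelve feature columns of
#'   [state_feature_names()], one row per image.
#' @export
extract_state_vector <- function(vec, source = mask_source("oracle")) {
  stopifnot(inherits(vec, "image_vector"), length(vec) >= 1)
  rows <- purrr::map(vec$items, function(it) {
    s <- extract_state(it, source)
    tibble::tibble(id = it$id, !!!as.list(s))
  })
  dplyr::bind_rows(rows)
}

# Strip the id column into a plain m x 12 matrix for the Q-network.
state_matrix <- function(states) {
  as.matrix(states[, state_feature_names(), drop = FALSE])
}
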