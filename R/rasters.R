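#' Labelled leaf image
#'
#' The atomic unit of the framework: an 8-bit RGB raster together with two
#' binary masks, one marking rust (disease-spot) pixels and one marking the
#' whole leaf (spots included). All three rasters share the same height and
#' width; masks contain only 0 and 1.
#'
#' @param image Numeric array `height x width x 3` with values in `[0, 255]`.
#' @param rust_label Integer/numeric matrix `height x width`, values in
#'   `{0, 1}`; 1 marks a disease-spot pixel.
#' @param leaf_label Matrix like `rust_label`; 1 marks a leaf pixel
#'   (disease spots are part of the leaf).
#' @param id Stable string identifier.
#'
#' @return An object of class `labeled_image` (a named list with elements
#'   `image`, `rust_label`, `leaf_label`, `id`).
#' @export
labeled_image <- function(image, rust_label, leaf_label, id) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3] == 3L)
  rust_label <- normalize_label(rust_label)
  leaf_label <- normalize_label(leaf_label)
  if (!identical(dim(image)[1:2], dim(rust_label)) ||
      !identical(dim(image)[1:2], dim(leaf_label))) {
    stop("image and label rasters must share height and width", call. = FALSE)
  }
  if (any(image < 0) || any(image > 255)) {
    stop("image values must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(image = image, rust_label = rust_label, leaf_label = leaf_label,
         id = as.character(id)),
    class = "labeled_image"
  )
}

# Coerce a label raster to an integer {0,1} matrix; accepts {0,255} and
# [0,1]-scaled input (as produced by PNG readers).
normalize_label <- function(m) {
  m <- as.matrix(m)
  u <- unique(as.vector(m))
  if (all(u %in% c(0, 1))) {
    # already binary
  } else if (all(u %in% c(0, 255))) {
    m <- m / 255
  } else if (all(u >= 0 & u <= 1)) {
    m <- round(m)
  } else {
    stop("label raster must be binary ({0,1} or {0,255})", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_image '%s'> %dx%d, rust px: %d, leaf px: %d\n",
              x$id, d[1], d[2], sum(x$rust_label), sum(x$leaf_label)))
  invisible(x)
}

#' Ordered image vector
#'
#' An ordered sequence of [labeled_image()] objects with positional identity:
#' position `i` of a child vector is always derived from position `i` of its
#' father, so the father/child correspondence survives augmentation rounds.
#'
#' @param items List of `labeled_image` objects.
#' @param generation_index Non-negative integer `t`; 0 for an original
#'   (un-augmented) set.
#'
#' @return An object of class `image_vector`.
#' @export
image_vector <- function(items, generation_index = 0L) {
  stopifnot(is.list(items),
            all(vapply(items, inherits, logical(1), "labeled_image")),
            generation_index >= 0)
  structure(
    list(items = items, generation_index = as.integer(generation_index)),
    class = "image_vector"
  )
}

#' @export
length.image_vector <- function(x) length(x$items)

#' @export
`[[.image_vector` <- function(x, i) x$items[[i]]

#' @export
print.image_vector <- function(x, ...) {
  cat(sprintf("<image_vector> %d images, generation %d\n",
              length(x$items), x$generation_index))
  invisible(x)
}

#' Concatenate image vectors
#'
#' Used to build retraining sets (original set plus one augmented descendant
#' per image). The result keeps the generation index of the first argument.
#'
#' @param ... `image_vector` objects.
#' @return A single `image_vector`.
#' @export
concat_image_vectors <- function(...) {
  vs <- list(...)
  stopifnot(all(vapply(vs, inherits, logical(1), "image_vector")))
  image_vector(unlist(lapply(vs, function(v) v$items), recursive = FALSE),
               generation_index = vs[[1]]$generation_index)
}

#' Write a labelled dataset to a directory
#'
#' Lays out `images/<id>.png`, `rust_labels/<id>.png`, `leaf_labels/<id>.png`
#' and a `manifest.tsv` with columns `id`, `image_path`, `rust_label_path`,
#' `leaf_label_path`. Labels are written as single-channel PNGs with pixel
#' values 0/255.
#'
#' @param vec An [image_vector()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(vec, dir) {
  stopifnot(inherits(vec, "image_vector"))
  for (sub in c("images", "rust_labels", "leaf_labels")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- lapply(vec$items, function(it) {
    ip <- file.path("images", paste0(it$id, ".png"))
    rp <- file.path("rust_labels", paste0(it$id, ".png"))
    lp <- file.path("leaf_labels", paste0(it$id, ".png"))
    png::writePNG(it$image / 255, file.path(dir, ip))
    png::writePNG(it$rust_label + 0, file.path(dir, rp))
    png::writePNG(it$leaf_label + 0, file.path(dir, lp))
    tibble::tibble(id = it$id, image_path = ip,
                   rust_label_path = rp, leaf_label_path = lp)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a labelled dataset from a directory
#'
#' Reads the layout written by [write_dataset()]. Label PNGs with values
#' `{0, 255}` are normalized to `{0, 1}`.
#'
#' @param dir Dataset directory containing `manifest.tsv`.
#' @return An [image_vector()] in manifest order, generation 0.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir, call. = FALSE)
  manifest <- utils::read.table(mf, sep = "\t", header = TRUE,
                                colClasses = "character")
  items <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    for (col in c("image_path", "rust_label_path", "leaf_label_path")) {
      if (!file.exists(file.path(dir, row[[col]]))) {
        stop("dataset input error: missing file ", row[[col]], call. = FALSE)
      }
    }
    img <- png::readPNG(file.path(dir, row$image_path))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    img <- round(img[, , 1:3, drop = FALSE] * 255)
    rl <- png::readPNG(file.path(dir, row$rust_label_path))
    ll <- png::readPNG(file.path(dir, row$leaf_label_path))
    if (length(dim(rl)) == 3L) rl <- rl[, , 1]
    if (length(dim(ll)) == 3L) ll <- ll[, , 1]
    labeled_image(img, rl, ll, id = row$id)
  })
  image_vector(items, generation_index = 0L)
}
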