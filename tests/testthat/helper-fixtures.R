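# Small generator configurations and brute-force oracles shared by the tests.

tiny_gen <- function(n_images = 6L, image_size = 32L, seed = 11L, ...) {
  generator_config(image_size = image_size, n_images = n_images, seed = seed,
                   ...)
}

# hand-built item: uniform background, rectangular leaf, one rectangular spot
make_item <- function(h = 20L, w = 20L, id = "fixture") {
  img <- array(40, dim = c(h, w, 3))
  leaf <- matrix(0L, h, w)
  leaf[5:15, 4:16] <- 1L
  rust <- matrix(0L, h, w)
  rust[8:10, 6:8] <- 1L
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[leaf == 1L] <- c(60, 150, 60)[ch]
    plane[rust == 1L] <- c(200, 90, 40)[ch]
    img[, , ch] <- plane
  }
  labeled_image(img, rust, leaf, id = id)
}

# independent per-pixel loop oracle for the confusion counts
brute_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
      else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
      else if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(K_TP = tp, K_FP = fp, K_TN = tn, K_FN = fn)
}

# independent per-pixel metric oracle (0/0 terms -> 1)
brute_metrics <- function(pred, truth) {
  cc <- brute_confusion(pred, truth)
  rat <- function(n, d) if (d == 0) 1 else n / d
  tp <- cc[["K_TP"]]; fp <- cc[["K_FP"]]; tn <- cc[["K_TN"]]; fn <- cc[["K_FN"]]
  c(PA = (tp + tn) / (tp + fp + tn + fn),
    MPA = (rat(tp, tp + fp) + rat(tn, tn + fn)) / 2,
    CPA = rat(tp, tp + fp),
    IoU = rat(tp, tp + fn + fp),
    MIoU = (rat(tp, tp + fn + fp) + rat(tn, tn + fp + fn)) / 2)
}

# explicit per-pixel summation oracle for the region features
brute_region <- function(image, mask) {
  h <- nrow(mask); w <- ncol(mask)
  sx <- sy <- n <- 0
  sc <- c(0, 0, 0)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] == 1) {
        n <- n + 1
        sy <- sy + (i - 1)
        sx <- sx + (j - 1)
        for (ch in 1:3) sc[ch] <- sc[ch] + image[i, j, ch]
      }
    }
  }
  if (n == 0) return(c(x = 0, y = 0, A = 0, R = 0, G = 0, B = 0))
  c(x = (sx / n) / (w - 1), y = (sy / n) / (h - 1), A = n / (h * w),
    R = sc[1] / n / 255, G = sc[2] / n / 255, B = sc[3] / n / 255)
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# a trained surrogate on a small synthetic split, cached per test run
fixture_split <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(generator_config(image_size = 64, n_images = 25,
                                              seed = 3))
      cache <<- split_dataset(ds, 0.2, seed = 1)
    }
    cache
  }
})

fixture_pretrain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- fixture_split()
      cache <<- pretrain("surrogate", sp$pretrain, sp$test,
                         train_config(epochs = 10, learning_rate = 0.5,
                                      seed = 1))
    }
    cache
  }
})
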