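#' Registered segmentation backends
#'
#' `surrogate` (default) is a seeded pixel-wise logistic classifier over
#' local colour/window features, trainable in seconds on desk-scale images.
#' `oracle` is a testing aid that memorizes ground-truth masks keyed by image
#' content and predicts them back (a perfect model on known images).
#' `deeplabv3plus` is a declared adapter slot without an implementation: the
#' framework treats the segmentation model as pluggable and this package
#' ships only the lightweight backends.
#'
#' @return Character vector of backend names.
#' @export
backend_registry <- function() c("surrogate", "oracle", "deeplabv3plus")

#' Training configuration for a segmentation backend
#'
#' @param epochs Number of full-batch gradient epochs (0 is allowed and
#'   leaves the parameters untouched, useful for no-op fine-tuning).
#' @param learning_rate Positive step size.
#' @param batch_size Pixels sampled per epoch; `Inf` (default) uses every
#'   pixel of the training images.
#' @param seed Seed for parameter initialization and any pixel sampling.
#' @param target Which label the model learns: `"rust"` or `"leaf"`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 60L, learning_rate = 2, batch_size = Inf,
                         seed = 1L, target = c("rust", "leaf")) {
  target <- match.arg(target)
  stopifnot(epochs >= 0, learning_rate > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = batch_size, seed = as.integer(seed),
                 target = target),
            class = "train_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Per-pixel design matrix: intercept, normalized RGB, and 3x3 box means of
# each channel (a minimal local-window context).
pixel_features <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  box3 <- function(m) {
    p <- matrix(0, h + 2, w + 2)
    p[2:(h + 1), 2:(w + 1)] <- m
    # replicate edges so border pixels keep a sensible neighbourhood mean
    p[1, ] <- p[2, ]; p[h + 2, ] <- p[h + 1, ]
    p[, 1] <- p[, 2]; p[, w + 2] <- p[, w + 1]
    (p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
     p[2:(h + 1), 1:w] + p[2:(h + 1), 2:(w + 1)] + p[2:(h + 1), 3:(w + 2)] +
     p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]) / 9
  }
  r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255
  cbind(1, as.vector(r), as.vector(g), as.vector(b),
        as.vector(box3(r)), as.vector(box3(g)), as.vector(box3(b)))
}

n_pixel_features <- 7L

# Stack the design matrices and targets of a whole image vector.
stack_pixels <- function(vec, target) {
  lab <- if (target == "rust") "rust_label" else "leaf_label"
  X <- do.call(rbind, lapply(vec$items, function(it) pixel_features(it$image)))
  y <- unlist(lapply(vec$items, function(it) as.vector(it[[lab]])))
  list(X = X, y = as.numeric(y))
}

# Weighted logistic-regression gradient descent; returns params and losses.
fit_logistic <- function(X, y, w0, epochs, lr, batch_size, seed) {
  n <- length(y)
  n_pos <- sum(y == 1); n_neg <- n - n_pos
  # class-balanced pixel weights (rust covers a small area fraction)
  wt <- ifelse(y == 1,
               if (n_pos > 0) n / (2 * n_pos) else 0,
               if (n_neg > 0) n / (2 * n_neg) else 0)
  w <- w0
  losses <- numeric(epochs)
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      if (is.finite(batch_size) && batch_size < n) {
        idx <- sample.int(n, batch_size)
      } else {
        idx <- seq_len(n)
      }
      Xi <- X[idx, , drop = FALSE]; yi <- y[idx]; wi <- wt[idx]
      p <- sigmoid(drop(Xi %*% w))
      eps <- 1e-12
      losses[e] <- -mean(wi * (yi * log(p + eps) + (1 - yi) * log(1 - p + eps)))
      grad <- drop(crossprod(Xi, wi * (p - yi))) / length(yi)
      w <- w - lr * grad
    }
  })
  list(w = w, losses = losses)
}

new_seg_model <- function(arch_id, target, params, train_log) {
  structure(list(arch_id = arch_id, target = target, params = params,
                 train_log = train_log),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> backend '%s', target '%s', %d training epochs logged\n",
              x$arch_id, x$target, nrow(x$train_log)))
  invisible(x)
}

# Content hash used by the oracle backend to key ground-truth masks: three
# fixed pseudo-random projections of the raster make collisions negligible.
raster_key <- function(image) {
  v <- as.vector(image)
  n <- length(v)
  i <- seq_len(n)
  sprintf("%d:%.8e:%.8e:%.8e", n, sum(v),
          sum(v * ((i * 2654435761) %% 1000003)) ,
          sum(v * ((i * 97 + 13) %% 65521)))
}

#' Pre-train a segmentation model
#'
#' Trains a backend from scratch on the pre-training set, recording the
#' per-epoch loss and the test-set metrics. The surrogate backend is a
#' class-balanced logistic classifier over [pixel_features] trained by
#' full-batch gradient descent; it is fully seeded and single-threaded, so
#' repeated calls are bit-identical.
#'
#' @param backend Backend name from [backend_registry()].
#' @param train_set,test_set [image_vector()]s with labels for `cfg$target`.
#' @param cfg A [train_config()].
#' @return A list with elements `model` (a `seg_model`) and `history` (a
#'   tibble with `epoch`, `loss`, and the test metrics `PA`..`MIoU`, `dice`).
#' @export
pretrain <- function(backend = "surrogate", train_set, test_set, cfg = train_config()) {
  if (!backend %in% backend_registry()) {
    stop("unknown backend: ", backend, call. = FALSE)
  }
  stopifnot(inherits(train_set, "image_vector"), length(train_set) >= 1,
            inherits(test_set, "image_vector"), length(test_set) >= 1)
  if (backend == "deeplabv3plus") {
    stop("the 'deeplabv3plus' adapter slot is declared but not implemented",
         call. = FALSE)
  }
  if (backend == "oracle") {
    lab <- if (cfg$target == "rust") "rust_label" else "leaf_label"
    lut <- list()
    for (it in c(train_set$items, test_set$items)) {
      lut[[raster_key(it$image)]] <- it[[lab]]
    }
    model <- new_seg_model("oracle", cfg$target, list(lut = lut),
                           tibble::tibble(epoch = integer(), loss = numeric()))
    ev <- evaluate_model(model, test_set, target = cfg$target)
    history <- dplyr::mutate(ev$metrics, epoch = 0L, loss = 0, dice = ev$dice$d,
                             .before = 1)
    return(list(model = model, history = history))
  }
  dat <- stack_pixels(train_set, cfg$target)
  w0 <- with_seed(cfg$seed, stats::rnorm(n_pixel_features, 0, 0.01))
  history <- NULL
  w <- w0
  losses <- numeric(0)
  # train in one pass but snapshot test metrics every few epochs
  chunk <- max(1L, cfg$epochs %/% 10L)
  done <- 0L
  while (done < cfg$epochs) {
    k <- min(chunk, cfg$epochs - done)
    fit <- fit_logistic(dat$X, dat$y, w, k, cfg$learning_rate,
                        cfg$batch_size, derive_seed(cfg$seed, done))
    w <- fit$w
    losses <- c(losses, fit$losses)
    done <- done + k
    m <- new_seg_model("surrogate", cfg$target, list(w = w),
                       tibble::tibble(epoch = seq_along(losses), loss = losses))
    ev <- evaluate_model(m, test_set, target = cfg$target)
    history <- dplyr::bind_rows(
      history,
      dplyr::mutate(ev$metrics, epoch = done, loss = losses[done],
                    dice = ev$dice$d, .before = 1))
  }
  model <- new_seg_model("surrogate", cfg$target, list(w = w),
                         tibble::tibble(epoch = seq_along(losses), loss = losses))
  if (cfg$epochs == 0L) {
    ev <- evaluate_model(model, test_set, target = cfg$target)
    history <- dplyr::mutate(ev$metrics, epoch = 0L, loss = NA_real_,
                             dice = ev$dice$d, .before = 1)
  }
  list(model = model, history = history)
}

#' Snapshot and restore a segmentation model
#'
#' `snapshot()` captures the full model state as a plain serializable list
#' (with a version and backend header); `restore()` rebuilds a model that
#' predicts bit-identically. Restoring never aliases the blob, so later
#' fine-tuning cannot mutate a stored snapshot.
#'
#' @param model A `seg_model`.
#' @return `snapshot()`: a list of class `seg_snapshot`; `restore()`: a
#'   `seg_model`.
#' @export
snapshot <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  structure(list(version = 1L, arch_id = model$arch_id,
                 target = model$target, params = model$params,
                 train_log = model$train_log),
            class = "seg_snapshot")
}

#' @rdname snapshot
#' @param blob A `seg_snapshot` (from [snapshot()] or [load_snapshot()]).
#' @export
restore <- function(blob) {
  if (!inherits(blob, "seg_snapshot") || is.null(blob$version) ||
      is.null(blob$arch_id)) {
    stop("corrupt or incompatible snapshot blob", call. = FALSE)
  }
  if (!blob$arch_id %in% backend_registry()) {
    stop("snapshot built by unknown backend '", blob$arch_id, "'", call. = FALSE)
  }
  new_seg_model(blob$arch_id, blob$target, blob$params, blob$train_log)
}

#' @rdname snapshot
#' @param path File path for the serialized snapshot.
#' @export
save_snapshot <- function(model, path) {
  saveRDS(snapshot(model), path)
  invisible(path)
}

#' @rdname snapshot
#' @export
load_snapshot <- function(path) restore(readRDS(path))

#' Fine-tune a segmentation model
#'
#' Continues training from the model's current parameters on the retraining
#' set (typically the original set plus one augmented descendant per image)
#' and returns a NEW model; the input model is never modified, which is what
#' lets the environment restore the pre-trained snapshot at every step.
#'
#' @param model A `seg_model`.
#' @param retrain_set Nonempty [image_vector()].
#' @param cfg A [train_config()]; its `target` must match the model's.
#' @return A new `seg_model`.
#' @export
finetune <- function(model, retrain_set, cfg = train_config(epochs = 3, learning_rate = 0.3)) {
  stopifnot(inherits(model, "seg_model"),
            inherits(retrain_set, "image_vector"), length(retrain_set) >= 1)
  if (model$arch_id == "oracle") return(model)
  if (cfg$epochs == 0L) return(model)
  dat <- stack_pixels(retrain_set, model$target)
  fit <- fit_logistic(dat$X, dat$y, model$params$w, cfg$epochs,
                      cfg$learning_rate, cfg$batch_size, cfg$seed)
  log <- dplyr::bind_rows(
    model$train_log,
    tibble::tibble(epoch = nrow(model$train_log) + seq_along(fit$losses),
                   loss = fit$losses))
  new_seg_model(model$arch_id, model$target, list(w = fit$w), log)
}

#' Predict a binary mask
#'
#' @param model A `seg_model`.
#' @param image RGB array `h x w x 3`, values 0-255.
#' @return Integer matrix `h x w` with values in `{0, 1}`.
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "seg_model"))
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("predict_mask expects an h x w x 3 raster", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  if (model$arch_id == "oracle") {
    m <- model$params$lut[[raster_key(image)]]
    if (is.null(m)) m <- matrix(0L, h, w)
    return(m)
  }
  p <- sigmoid(drop(pixel_features(image) %*% model$params$w))
  out <- matrix(as.integer(p > 0.5), h, w)
  out
}

#' Evaluate a segmentation model on a test set
#'
#' Predicts every test image, computes the ordered per-image IoU values, the
#' metrics from the pooled confusion counts, and the Dice-style score.
#'
#' @param model A `seg_model`.
#' @param test_set Nonempty [image_vector()].
#' @param target `"rust"` or `"leaf"`; defaults to the model's target.
#' @param dice_factor Passed to [dice_ratio()].
#' @return List with `ious` (numeric, ordered as `test_set`), `metrics`
#'   (one-row tibble, pooled counts), `per_image_metrics` (mean of per-image
#'   metric rows), and `dice` (a `dice_score`).
#' @export
evaluate_model <- function(model, test_set, target = NULL, dice_factor = 2) {
  stopifnot(inherits(test_set, "image_vector"), length(test_set) >= 1)
  if (is.null(target)) target <- model$target
  lab <- if (target == "rust") "rust_label" else "leaf_label"
  pooled <- c(K_TP = 0, K_FP = 0, K_TN = 0, K_FN = 0)
  ious <- numeric(length(test_set))
  per_img <- vector("list", length(test_set))
  for (i in seq_along(ious)) {
    it <- test_set[[i]]
    pred <- predict_mask(model, it$image)
    cc <- confusion_counts(pred, it[[lab]])
    pooled <- pooled + cc
    ious[i] <- safe_ratio(cc[["K_TP"]],
                          cc[["K_TP"]] + cc[["K_FP"]] + cc[["K_FN"]])
    per_img[[i]] <- compute_metrics(cc)
  }
  list(
    ious = ious,
    metrics = compute_metrics(pooled),
    per_image_metrics = dplyr::summarise_all(dplyr::bind_rows(per_img), mean),
    dice = dice_ratio(ious, dice_factor = dice_factor)
  )
}
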