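#' Tidy the per-step training history of a fitted agent
#'
#' @param x A `dqn_fit`.
#' @param ... Unused.
#' @return A tibble with one row per environment step: `episode`, `step`,
#'   `global_step`, `epsilon`, `loss`, `reward`, `buffer_size`, plus the
#'   environment's per-step metrics when available (`dice`, `PA`, ...).
#' @method tidy dqn_fit
#' @export
tidy.dqn_fit <- function(x, ...) {
  h <- x$history
  extra <- x$info[, setdiff(names(x$info), names(h)), drop = FALSE]
  if (ncol(extra) > 0 && nrow(extra) == nrow(h)) {
    h <- dplyr::bind_cols(h, extra)
  }
  h
}

#' One-row summary of a fitted agent
#'
#' @param x A `dqn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: episode/step counts, transitions stored, final
#'   epsilon and loss, and the first- and last-quartile mean step rewards.
#' @export
glance.dqn_fit <- function(x, ...) {
  h <- x$history
  qr <- quartile_rewards(h)
  tibble::tibble(
    episodes = max(h$episode),
    steps = nrow(h),
    transitions = length(x$buffer),
    final_epsilon = h$epsilon[nrow(h)],
    final_loss = h$loss[nrow(h)],
    mean_reward_first_quartile = qr$first,
    mean_reward_last_quartile = qr$last
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Reward curve of a fitted agent
#'
#' @param object A `dqn_fit`.
#' @param ... Unused.
#' @return A ggplot: per-step reward over the training run, with episode
#'   boundaries implicit in the step index.
#' @method autoplot dqn_fit
#' @export
autoplot.dqn_fit <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$global_step, y = .data$reward)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$episode)), size = 1) +
    ggplot2::labs(x = "environment step", y = "step reward",
                  colour = "episode") +
    ggplot2::theme_minimal()
}

#' Plot a pre-training history
#'
#' @param history History tibble from [pretrain()].
#' @return A ggplot of the test metrics against the training epoch.
#' @export
plot_pretrain_history <- function(history) {
  long <- tidyr::pivot_longer(
    history[, c("epoch", "PA", "MPA", "CPA", "IoU", "MIoU")],
    -"epoch", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "test-set value") +
    ggplot2::theme_minimal()
}

#' Display a labelled image with its masks
#'
#' @param item A [labeled_image()].
#' @return A ggplot showing the RGB image with rust- and leaf-mask outlines
#'   overlaid as filled tiles.
#' @export
plot_labeled_image <- function(item) {
  stopifnot(inherits(item, "labeled_image"))
  h <- dim(item$image)[1]; w <- dim(item$image)[2]
  df <- tidyr::expand_grid(row = seq_len(h), col = seq_len(w))
  df$fill <- grDevices::rgb(item$image[, , 1][cbind(df$row, df$col)],
                            item$image[, , 2][cbind(df$row, df$col)],
                            item$image[, , 3][cbind(df$row, df$col)],
                            maxColorValue = 255)
  df$rust <- item$rust_label[cbind(df$row, df$col)] == 1L
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::geom_point(data = df[df$rust, ], size = 0.1, colour = "white",
                        alpha = 0.3) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(item$id)
}
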