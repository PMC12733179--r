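#' Tidy a training history
#'
#' One row per epoch with the weight in use (median across labels in macro
#' mode), validation precision/recall/F-beta at the fixed threshold, and
#' the mean training loss.
#'
#' @param x A `fola_history` from [fola_train()] and friends.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fola_history
#' @export
tidy.fola_history <- function(x, ...) {
  x$epochs |>
    dplyr::mutate(wpos = purrr::map_dbl(.data$wpos, ~ median(.x))) |>
    dplyr::select("epoch", "wpos", "val_precision", "val_recall",
                  "val_fbeta", "mean_loss")
}

#' Glance at a training history
#'
#' @inheritParams tidy.fola_history
#' @return A one-row tibble: epochs trained, mode, beta, final weight
#'   (median in macro mode), final validation micro and macro F, seed.
#' @method glance fola_history
#' @export
glance.fola_history <- function(x, ...) {
  tibble(
    epochs = nrow(x$epochs),
    mode = x$config$mode,
    beta = x$config$beta,
    final_wpos = if (is.null(x$final_weights)) NA_real_ else median(x$final_weights$wpos),
    val_fbeta = x$epochs$val_fbeta[nrow(x$epochs)],
    micro_f = x$final_report$micro_f,
    macro_f = x$final_report$macro_f,
    seed = x$seed
  )
}

#' @export
print.fola_history <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fola_history> %d epoch(s), %s mode, beta = %g\n  final wpos (median) = %s, final val F = %.4f\n",
    g$epochs, g$mode, g$beta,
    if (is.na(g$final_wpos)) "-" else sprintf("%.4g", g$final_wpos), g$val_fbeta
  ))
  invisible(x)
}

#' Plot a training history
#'
#' Validation F-beta and the weight trajectory against the epoch index.
#'
#' @param object A `fola_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fola_history
#' @export
autoplot.fola_history <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("val_fbeta", "wpos"), names_to = "quantity") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
      val_fbeta = "validation F-beta", wpos = "wpos (median)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ablation result
#'
#' Precision, recall and F against the fixed weight for grid rows, with
#' dynamic-weight configurations drawn as horizontal reference lines.
#'
#' @param object An `ablation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ablation_result
#' @export
autoplot.ablation_result <- function(object, ...) {
  df <- as_tibble(object)
  grid_df <- df |>
    dplyr::filter(!is.na(.data$wpos)) |>
    tidyr::pivot_longer(c("f", "precision", "recall"), names_to = "metric")
  p <- ggplot2::ggplot(grid_df,
                       ggplot2::aes(x = .data$wpos, y = .data$value,
                                    colour = .data$metric)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fixed wpos (log scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  dyn <- df |>
    dplyr::filter(is.na(.data$wpos)) |>
    dplyr::group_by(.data$configuration) |>
    dplyr::summarise(f = mean(.data$f), .groups = "drop")
  if (nrow(dyn) > 0) {
    p <- p + ggplot2::geom_hline(
      data = dyn,
      ggplot2::aes(yintercept = .data$f, linetype = .data$configuration)
    ) + ggplot2::labs(linetype = NULL)
  }
  p
}
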