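#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-task accuracies of an evaluation
#'
#' Bar chart of accuracy per transfer task with the mean as a dashed line
#' and the two-class chance level at 0.5.
#'
#' @param object A `farka_eval` from [run_plan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.farka_eval <- function(object, ...) {
  df <- object$tasks
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task_id, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "target-field accuracy",
                  title = sprintf("%s evaluation, mean = %.3f",
                                  toupper(df$mode[1]),
                                  object$mean_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter sweep
#'
#' Mean accuracy against the first swept numeric axis, with one line per
#' kernel family when the sweep includes one.
#'
#' @param object A `farka_sweep` from [sweep_farka()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.farka_sweep <- function(object, ...) {
  axes <- setdiff(names(object), c("mean_accuracy", "report"))
  num_axes <- axes[vapply(object[axes], is.numeric, logical(1))]
  if (length(num_axes) == 0L) {
    stop("sweep has no numeric axis to plot", call. = FALSE)
  }
  x <- num_axes[1]
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[x]],
                                    y = .data$mean_accuracy))
  if ("kernel" %in% axes) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$kernel)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$kernel))
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p +
    ggplot2::labs(x = x, y = "mean target-field accuracy") +
    ggplot2::theme_minimal()
}

#' Plot the learned versus target kernel spectrum
#'
#' Compares the target kernel's retained eigenvalues with the power-law
#' constrained spectrum learned by the quadratic program.
#'
#' @param object A `kernel_bundle` from [kka()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kernel_bundle <- function(object, ...) {
  r <- length(object$delta_star)
  df <- tibble::tibble(
    index = rep(seq_len(r), 2),
    value = c(object$eigen_system$delta_t, object$delta_star),
    spectrum = rep(c("target eigenvalues", "learned spectrum"), each = r)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   colour = .data$spectrum)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "eigenvalue index", y = "value (log scale)") +
    ggplot2::theme_minimal()
}
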