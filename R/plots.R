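#' Plot a solution path
#'
#' Expression of each candidate isoform along the path iterations; requires
#' the path to have been computed with `keep_phi = TRUE`. Candidates that
#' never become active are drawn but sit on zero.
#'
#' @param object A [blasso_path()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.solution_path <- function(object, ...) {
  if (is.null(object$phi)) {
    abort("path was computed with keep_phi = FALSE; nothing to plot")
  }
  df <- as.data.frame(object$phi)
  names(df) <- as.character(seq_len(ncol(df)))
  df$k <- object$points$k
  long <- tidyr::pivot_longer(df, -"k", names_to = "isoform",
                              values_to = "rpkm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$rpkm,
                                     colour = .data$isoform)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "path iteration k", y = "expression (RPKM)",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.solution_path
#' @param x A [blasso_path()] result.
#' @param y Unused.
#' @export
plot.solution_path <- function(x, y, ...) print(autoplot(x, ...))

#' Plot an ROC curve with its selected expression threshold
#'
#' @param object A [roc_threshold()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_threshold <- function(object, ...) {
  roc <- object$roc[order(1 - object$roc$specificity, object$roc$sensitivity), ]
  sel <- roc[roc$threshold == object$threshold, ]
  ggplot2::ggplot(roc, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = sel, colour = "red", size = 2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = paste0("threshold T = ",
                                 format(object$threshold, digits = 4),
                                 " RPKM")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roc_threshold
#' @param x A [roc_threshold()] result.
#' @param y Unused.
#' @export
plot.roc_threshold <- function(x, y, ...) print(autoplot(x, ...))
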