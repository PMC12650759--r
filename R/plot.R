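#' Profile plot for a unit or fragment result
#'
#' Draws the theoretical (T), observed (O) and environment-modified (M)
#' distributions along the residue index, with the uniform reference R as a
#' dashed horizontal level. Local excess of O over the T/M band is the
#' visual signature of exposed hydrophobicity; local deficit marks cavities.
#'
#' @param object An `fodm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fodm_result
#' @export
autoplot.fodm_result <- function(object, ...) {
  df <- tidy(object)
  df$idx <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df[, c("idx", "t", "o", "m")],
                              cols = c("t", "o", "m"),
                              names_to = "profile", values_to = "value")
  long$profile <- factor(toupper(long$profile), levels = c("T", "O", "M"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$idx, y = .data$value,
                                     colour = .data$profile)) +
    ggplot2::geom_hline(yintercept = 1 / object$n, linetype = "dashed",
                        colour = "grey55") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(T = "#2166ac", O = "#d6604d",
                                            M = "grey30")) +
    ggplot2::labs(
      x = "residue (unit order)", y = "hydrophobicity (unit sum)",
      colour = NULL,
      title = sprintf("%s [%s]  RD = %.3f, K = %.1f",
                      object$label %||% "unit", object$mode,
                      object$rd, object$k)) +
    ggplot2::theme_minimal()
}

#' Summary plot of RD and K across study forms
#'
#' The comparative view of a study: RD (with the 0.5 hydrophobic-core
#' discrimination level) and K per analyzed unit, faceted by parameter,
#' forms in configuration order.
#'
#' @param object An `fodm_study`.
#' @param units Optional character vector restricting which unit labels are
#'   drawn (default: all rows with results).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fodm_study
#' @export
autoplot.fodm_study <- function(object, units = NULL, ...) {
  df <- object$results[!is.na(object$results$rd), ]
  if (!is.null(units)) df <- df[df$unit %in% units, ]
  df$form <- factor(df$form, levels = unique(object$results$form))
  long <- tidyr::pivot_longer(df[, c("form", "unit", "rd", "k")],
                              cols = c("rd", "k"),
                              names_to = "parameter", values_to = "value")
  long$parameter <- factor(toupper(long$parameter), levels = c("RD", "K"))
  ref <- data.frame(parameter = factor("RD", levels = c("RD", "K")), y = 0.5)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$form, y = .data$value,
                                     group = .data$unit,
                                     colour = .data$unit)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey55") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
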