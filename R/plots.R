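#' Training-history plot for a GGT fit
#'
#' Train and validation combined loss per epoch, with the best epoch marked.
#'
#' @param object a `ggt_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ggt_fit
#' @export
autoplot.ggt_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "split", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "combined loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-target ranking losses across methods
#'
#' @param losses wide data frame: `target_id` plus one loss column per
#'   method (e.g. [dbm55_ranking_losses()]).
#' @return a ggplot with one point per target and method.
#' @export
plot_ranking_losses <- function(losses) {
  d <- tidyr::pivot_longer(losses, -"target_id", names_to = "method",
                           values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(.data$loss, .data$target_id,
                                  colour = .data$method)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "DockQ ranking loss", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Quality distribution of a labelled decoy pool
#'
#' DockQ against perturbation magnitude, coloured by quality class; a quick
#' visual check that graded perturbations produce graded labels.
#'
#' @param labels label tibble from [make_decoy_pool()].
#' @return a ggplot.
#' @export
plot_decoy_pool <- function(labels) {
  ggplot2::ggplot(labels, ggplot2::aes(.data$trans_ang, .data$dockq,
                                       colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.3, height = 0, alpha = 0.8) +
    ggplot2::labs(x = "ligand translation (Angstrom)", y = "DockQ",
                  colour = "class") +
    ggplot2::theme_minimal()
}
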