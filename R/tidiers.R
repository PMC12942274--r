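#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_boxplot geom_line facet_wrap labs position_dodge theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a fitted segmenter
#'
#' One row per model component with its parameter count and whether it
#' receives gradient updates in phase 2.
#'
#' @param x An `ldseg_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `n_params`, `trainable`.
#' @export
tidy.ldseg_model <- function(x, ...) {
  comp <- list(
    encoder_backbone = lapply(x$encoder$blocks, identity),
    encoder_adapters = x$encoder$adapters,
    prompt_encoder = x$prompt_encoder[setdiff(names(x$prompt_encoder), "spec")],
    mask_decoder = x$decoder[setdiff(names(x$decoder), "spec")],
    student_detector = if (!is.null(x$student)) {
      list(x$student$pyramid, x$student$head)
    }
  )
  dplyr::bind_rows(lapply(names(comp), function(nm) {
    if (is.null(comp[[nm]])) return(NULL)
    ps <- collect_params(comp[[nm]])
    tibble(component = nm,
           n_params = sum(vapply(ps, function(p) length(p$value), numeric(1))),
           trainable = any(vapply(ps, function(p) isTRUE(p$trainable),
                                  logical(1))))
  }))
}

#' Glance at a fitted segmenter
#'
#' @param x An `ldseg_model`.
#' @param ... Unused.
#' @return A one-row tibble: prompt mode, parameter counts, epochs
#'   trained, final training loss, and the current injection gate value.
#' @export
glance.ldseg_model <- function(x, ...) {
  td <- tidy(x)
  tibble(
    prompt_mode = x$prompt_mode,
    n_params = sum(td$n_params),
    n_trainable = sum(vapply(
      trainable_params(list(x$encoder, x$prompt_encoder, x$decoder)),
      function(p) length(p$value), numeric(1))),
    epochs = length(x$history),
    final_loss = x$history[length(x$history)],
    alpha = as.numeric(x$prompt_encoder$alpha$value)
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-case metric tibble.
#' @export
tidy.eval_report <- function(x, ...) x$cases

#' Glance at an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble of mean metrics with the Dice CI bounds.
#' @export
glance.eval_report <- function(x, ...) {
  s <- x$summary
  tibble(
    n = x$meta$n,
    dice = s$mean[s$metric == "dice"],
    iou = s$mean[s$metric == "iou"],
    acc = s$mean[s$metric == "acc"],
    hd = s$mean[s$metric == "hd"],
    assd = s$mean[s$metric == "assd"],
    dice_lower = s$ci_lower[s$metric == "dice"],
    dice_upper = s$ci_upper[s$metric == "dice"]
  )
}

#' Plot an evaluation report
#'
#' Per-case Dice distribution as a boxplot.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot(object$cases, aes(x = "", y = .data$dice)) +
    geom_boxplot(width = 0.4, fill = "grey85") +
    labs(x = NULL, y = "Dice",
         title = paste0("Per-case Dice (", object$meta$prompt_mode,
                        " prompts, n = ", object$meta$n, ")")) +
    theme_minimal()
}

#' Plot an ablation grid
#'
#' Mean test Dice per cell with bootstrap CI bars, faceted by annotation
#' budget when several budgets are present.
#'
#' @param object An `ablation_grid` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ablation_grid <- function(object, ...) {
  df <- dplyr::filter(object, .data$status == "ok")
  df$arm <- interaction(df$prompt_mode, df$distill_mode, sep = " / ")
  p <- ggplot(df, aes(x = .data$arm, y = .data$dice,
                      colour = factor(.data$seed))) +
    geom_point(position = position_dodge(width = 0.4)) +
    geom_errorbar(aes(ymin = .data$dice_lower, ymax = .data$dice_upper),
                  width = 0.2, position = position_dodge(width = 0.4)) +
    labs(x = "prompt mode / distillation", y = "test Dice",
         colour = "seed") +
    theme_minimal()
  if (length(unique(df$budget)) > 1L) {
    p <- p + facet_wrap(~budget, labeller = ggplot2::label_both)
  }
  p
}

#' @importFrom rlang .data
NULL
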