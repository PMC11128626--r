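#' Forest plot of per-variant Wald ratios with pooled estimates
#'
#' @param dat Harmonized instrument tibble.
#' @param panel Optional `mr_panel` tibble whose pooled estimates are drawn
#'   beneath the per-variant ratios.
#' @return A ggplot object.
#' @export
plot_forest <- function(dat, panel = NULL) {
  wr <- wald_ratios(dat)
  if (!"variant_id" %in% names(wr)) wr$variant_id <- as.character(seq_len(nrow(wr)))
  wr <- dplyr::mutate(wr, label = .data$variant_id,
                      low = .data$ratio - 1.96 * .data$ratio_se,
                      high = .data$ratio + 1.96 * .data$ratio_se,
                      kind = "variant")
  rows <- dplyr::select(wr, "label", est = "ratio", "low", "high", "kind")
  if (!is.null(panel)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      label = paste0("pooled: ", panel$method), est = panel$beta,
      low = panel$ci_low, high = panel$ci_high, kind = "pooled"))
  }
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$est, y = .data$label,
                                     colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$low, xmax = .data$high)) +
    ggplot2::labs(x = "causal estimate (log odds per exposure unit)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of outcome against exposure effects with fitted slopes
#'
#' @param dat Harmonized instrument tibble.
#' @param panel Optional `mr_panel`; each method's slope is drawn (MR-Egger
#'   with its intercept, the others through the origin).
#' @return A ggplot object.
#' @export
plot_scatter <- function(dat, panel = NULL) {
  dat <- as_instruments(dat)
  flip <- sign(dat$beta_exposure)
  flip[flip == 0] <- 1
  pts <- tibble::tibble(bx = dat$beta_exposure * flip,
                        by = dat$beta_outcome * flip,
                        sx = dat$se_exposure, sy = dat$se_outcome)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - 1.96 * .data$sy,
                                        ymax = .data$by + 1.96 * .data$sy),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - 1.96 * .data$sx,
                                         xmax = .data$bx + 1.96 * .data$sx),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "effect on exposure", y = "effect on outcome") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    fits <- attr(panel, "fits")
    lines <- tibble::tibble(
      method = panel$method, slope = panel$beta,
      intercept = c(0, if (!is.null(fits)) fits$egger$intercept else 0, 0, 0, 0)[
        seq_len(nrow(panel))]
    )
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Leave-one-out plot
#'
#' @param loo Tibble from [mr_leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  loo$omitted <- factor(loo$omitted, levels = rev(loo$omitted))
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta, y = .data$omitted)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "IVW estimate omitting the variant", y = "omitted variant") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mr_panel <- function(object, ...) {
  object$method <- factor(object$method, levels = rev(object$method))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "causal estimate (log odds)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coloc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$gate, linetype = "dashed") +
    ggplot2::labs(y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mediation_result <- function(object, ...) {
  d <- tibble::tibble(
    component = factor(c("total", "direct A", "direct B", "indirect"),
                       levels = rev(c("total", "direct A", "direct B", "indirect"))),
    est = c(object$total$beta, object$direct_a$beta, object$direct_b$beta,
            object$indirect$estimate),
    low = c(object$total$ci_low, object$direct_a$ci_low, object$direct_b$ci_low,
            object$indirect$ci_low),
    high = c(object$total$ci_high, object$direct_a$ci_high,
             object$direct_b$ci_high, object$indirect$ci_high)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$est, y = .data$component)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$low, xmax = .data$high)) +
    ggplot2::labs(x = "effect (log odds)", y = NULL) +
    ggplot2::theme_minimal()
}
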