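#' Plot per-attempt log-likelihoods of a fit
#'
#' Dot plot of the log-likelihood reached by each optimization attempt;
#' a spread of values indicates a multimodal likelihood surface.
#'
#' @param object A `trait_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trait_fit <- function(object, ...) {
  d <- object$attempt_results[is.finite(object$attempt_results$loglik), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$attempt, y = .data$loglik)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$loglik, linetype = 2) +
    ggplot2::labs(x = "optimization attempt", y = "log-likelihood",
                  title = paste0(object$model_name, " model (best LL ",
                                 sprintf("%.2f", object$loglik), ")"))
}

#' Plot a dependent-vs-independent comparison
#'
#' Side-by-side fitted rates of the two models on a log scale; the subtitle
#' carries the likelihood-ratio test.
#'
#' @param object A `pagel_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pagel_comparison <- function(object, ...) {
  d <- tidy(object)
  g <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~model, scales = "free_x") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "rate (per unit branch length)",
                  title = "Dependent vs independent trait evolution",
                  subtitle = sprintf("chi-squared = %.2f, d.f. = %d, p = %.3g (%s)",
                                     g$statistic, g$df, g$p.value, g$verdict)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot reconstruction confidence across nodes
#'
#' Histogram of each internal node's highest proportional likelihood; mass
#' near 1 means the reconstruction is decisive.
#'
#' @param object An `asr` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asr <- function(object, ...) {
  internal <- object$nodes$type == "internal"
  conf <- apply(object$prob[internal, , drop = FALSE], 1, max)
  ggplot2::ggplot(tibble::tibble(confidence = conf),
                  ggplot2::aes(x = .data$confidence)) +
    ggplot2::geom_histogram(bins = 30, boundary = 1) +
    ggplot2::labs(x = "max proportional likelihood per internal node",
                  y = "nodes", title = "Ancestral-state reconstruction confidence")
}

#' Plot a restricted-model suite
#'
#' Chi-squared statistic per restriction with the alpha-level critical value
#' (1 d.f.) as a reference line.
#'
#' @param suite Tibble from [restricted_suite()].
#' @param alpha Significance level for the reference line.
#' @return A ggplot.
#' @export
plot_restricted_suite <- function(suite, alpha = 0.05) {
  crit <- stats::qchisq(1 - alpha, df = 1)
  ggplot2::ggplot(suite, ggplot2::aes(x = .data$restriction, y = .data$statistic)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = crit, linetype = 2) +
    ggplot2::labs(x = NULL, y = "likelihood-ratio chi-squared (1 d.f.)",
                  title = "Single-rate restrictions of the dependent model",
                  subtitle = sprintf("dashed: critical value at alpha = %g", alpha)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
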