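#' Membership-posterior heatmap
#'
#' Participants (sorted by hard label, then by maximum membership
#' probability) against phenotypes, tile fill = membership probability. The
#' per-cohort analogue of the published assignment heatmap: with sparse
#' priors most rows show one near-yellow tile (probability above 0.9).
#'
#' @param object An `endo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.endo_fit <- function(object, ...) {
  asg <- hard_assign(object)
  ord <- order(asg$phenotype, -asg$max_probability)
  long <- tidy(object, "theta")
  long$participant_id <- factor(long$participant_id,
                                levels = asg$participant_id[ord])
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$phenotype), y = .data$participant_id,
    fill = .data$probability
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Phenotype", y = "Participant",
                  fill = "Membership\nprobability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Answer-cloud weight chart
#'
#' Bar chart of the renormalised answer-cloud weights for one phenotype and
#' question (the numeric content of a rendered word cloud: bar length plays
#' the role of font size).
#'
#' @inheritParams cloud_weights
#' @return A ggplot object.
#' @export
plot_answer_cloud <- function(fit, question_id, phenotype, mass = 0.8) {
  w <- cloud_weights(fit, question_id, phenotype, mass)
  w$token <- factor(w$token, levels = rev(w$token))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$weight, y = .data$token)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Renormalised weight", y = NULL,
      title = sprintf("Phenotype %d — %s (%.0f%% posterior mass)",
                      phenotype, question_id, 100 * mass)
    ) +
    ggplot2::theme_minimal()
}

#' Held-out likelihood comparison across the grid
#'
#' Mean cross-validated test log-likelihood by number of phenotypes, one
#' line per model (multi-modal proposed vs concatenated-vocabulary
#' baseline), faceted by the Dirichlet concentrations.
#'
#' @param object An `endo_eval` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.endo_eval <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, .data$K, .data$alpha, .data$beta,
                     model = "proposed",
                     mean_loglik = .data$mean_loglik_proposed),
    dplyr::transmute(object, .data$K, .data$alpha, .data$beta,
                     model = "baseline",
                     mean_loglik = .data$mean_loglik_baseline)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$K, y = .data$mean_loglik, colour = .data$model
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$alpha), cols = ggplot2::vars(.data$beta),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "Number of phenotypes K",
                  y = "Mean held-out log-likelihood", colour = NULL) +
    ggplot2::theme_minimal()
}
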