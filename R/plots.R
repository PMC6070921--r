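#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_errorbar
#'   geom_point facet_wrap labs scale_fill_manual scale_fill_gradient
#'   theme_minimal
NULL

#' Plot splice-variant fractions with CI95 lower bounds
#'
#' Bar per variant junction: point-estimate fraction with the exact lower
#' confidence bound marked.
#'
#' @param fractions A `variant_fractions` tibble.
#' @return A ggplot.
#' @export
plot_variant_fractions <- function(fractions) {
  df <- fractions |> filter(.data$variant_name != "AR-FL",
                            !is.na(.data$fraction))
  ggplot(df, aes(x = .data$variant_name, y = .data$fraction)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$ci95_lower, ymax = .data$fraction),
                  width = 0.25) +
    labs(x = NULL, y = "fraction of AR transcript",
         title = "Splice-variant fractions (bar = point estimate, whisker to CI95 lower bound)") +
    theme_minimal()
}

#' Cohort overview heatmap
#'
#' Fig 1-style matrix: one column per sample, rows for copy-number state,
#' mutation count, signalling score and the combined AR-V level.
#'
#' @param object An `arv_cohort`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.arv_cohort <- function(object, ...) {
  s <- object$samples
  num_or_na <- function(col) if (col %in% names(s)) as.numeric(s[[col]])
                             else rep(NA_real_, nrow(s))
  long <- bind_rows(
    tibble(sample = s$sample, group = s$group, metric = "copy number",
           value = num_or_na("cn_estimate")),
    tibble(sample = s$sample, group = s$group, metric = "mutations",
           value = num_or_na("n_mutations")),
    tibble(sample = s$sample, group = s$group, metric = "signalling score",
           value = num_or_na("signalling_score")),
    tibble(sample = s$sample, group = s$group,
           metric = "combined AR-V fraction", value = num_or_na("total_arv")))
  long <- long |>
    group_by(.data$metric) |>
    mutate(scaled = {
      rng <- range(.data$value, na.rm = TRUE)
      if (diff(rng) == 0) rep(0.5, length(.data$value))
      else (.data$value - rng[1]) / diff(rng)
    }) |>
    ungroup()
  ggplot(long, aes(x = .data$sample, y = .data$metric,
                   fill = .data$scaled)) +
    geom_tile() +
    facet_wrap(~group, scales = "free_x") +
    scale_fill_gradient(low = "white", high = "firebrick",
                        na.value = "grey90", name = "scaled value") +
    labs(x = NULL, y = NULL, title = "Per-sample AR alteration overview") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
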