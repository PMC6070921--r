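#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy cohort statistics
#'
#' Returns the cohort's test results as one tibble: Mann-Whitney group
#' comparisons and Spearman correlations, with a `kind` column.
#'
#' @param x An `arv_cohort`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.arv_cohort <- function(x, ...) {
  comp <- x$comparisons
  cors <- x$correlations
  out <- list()
  if (nrow(comp) > 0)
    out$comp <- comp |>
      mutate(kind = "mann_whitney",
             term = paste(.data$group_a, "vs", .data$group_b),
             estimate = .data$statistic, p.value = .data$p_two_sided) |>
      select("kind", "term", "estimate", "p.value")
  if (nrow(cors) > 0)
    out$cors <- cors |>
      mutate(kind = "spearman", term = .data$pair, estimate = .data$rho,
             p.value = .data$p) |>
      select("kind", "term", "estimate", "p.value")
  bind_rows(out)
}

#' One-row cohort summary
#'
#' @param x An `arv_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: sample/group counts and alteration totals.
#' @export
glance.arv_cohort <- function(x, ...) {
  s <- x$samples
  has <- function(col) col %in% names(s)
  tibble(
    n_samples = nrow(s),
    n_groups = length(unique(s$group)),
    n_mutated = if (has("n_mutations")) sum(s$n_mutations > 0, na.rm = TRUE)
                else NA_integer_,
    n_cn_altered = if (has("cn_label"))
      sum(s$cn_label %in% c("gain", "amplification"), na.rm = TRUE)
      else NA_integer_,
    n_gsr_positive = if (has("n_gsr")) sum(s$n_gsr > 0, na.rm = TRUE)
                     else NA_integer_,
    n_arv_high = if (has("arv_level")) sum(s$arv_level == "high", na.rm = TRUE)
                 else NA_integer_)
}
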