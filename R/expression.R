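#' Housekeeping-normalise expression counts
#'
#' Divides each sample's gene counts by the geometric mean of its
#' housekeeping-gene counts (0.5 pseudocount), removing library-depth
#' effects without a reference cohort. Samples whose housekeeping counts are
#' all zero are flagged non-normalisable (`NA` normalised values).
#'
#' @param counts Long tibble: `sample`, `gene`, `count`.
#' @param panel A [panel_config] (gene roles from `rna_genes`).
#' @return `counts` with `normalized` and `normalizable` columns.
#' @export
normalize_counts <- function(counts, panel) {
  roles <- panel$rna_genes
  hk <- roles$gene[roles$role == "housekeeping"]
  if (any(counts$count < 0)) param_error("counts must be non-negative")
  scale <- counts |>
    filter(.data$gene %in% hk) |>
    group_by(.data$sample) |>
    summarise(hk_geomean = exp(mean(log(.data$count + 0.5))),
              normalizable = any(.data$count > 0), .groups = "drop")
  counts |>
    left_join(scale, by = "sample") |>
    mutate(normalized = ifelse(.data$normalizable,
                               .data$count / .data$hk_geomean, NA_real_)) |>
    select(-"hk_geomean")
}

#' AR-signalling score (summed z-score)
#'
#' For each AR-regulated gene, z-scores of the normalised counts are
#' computed across the cohort (mean 0, sd 1, n-1 denominator; a
#' zero-variance gene contributes 0); a sample's signalling score is the
#' sum of its z-scores over the five AR-regulated genes.
#'
#' @param normalized Output of [normalize_counts()].
#' @param panel A [panel_config].
#' @return Tibble: `sample`, `signalling_score`.
#' @export
signalling_score <- function(normalized, panel) {
  roles <- panel$rna_genes
  arg <- roles$gene[roles$role == "ar_regulated"]
  n_samples <- length(unique(normalized$sample))
  if (n_samples < 3)
    abort("signalling score requires a cohort of at least 3 samples",
          class = "arv_param_error")
  normalized |>
    filter(.data$gene %in% arg) |>
    group_by(.data$gene) |>
    mutate(z = {
      s <- stats::sd(.data$normalized)
      if (is.na(s) || s == 0) rep(0, length(.data$normalized))
      else (.data$normalized - mean(.data$normalized)) / s
    }) |>
    ungroup() |>
    group_by(.data$sample) |>
    summarise(signalling_score = sum(.data$z), .groups = "drop")
}

#' Classify total splice-variant expression level
#'
#' Zero is negative; up to 5% of AR transcript is low; above 5% is high
#' (the 5% boundary is assigned to low so the rule is deterministic);
#' non-quantifiable input is not assessable.
#'
#' @param fraction Numeric vector of total AR-V fractions (`NA` allowed).
#' @return Character vector: `negative`, `low`, `high`, `not_assessable`.
#' @export
classify_arv_level <- function(fraction) {
  out <- ifelse(is.na(fraction), "not_assessable",
                ifelse(fraction <= 0, "negative",
                       ifelse(fraction <= 0.05, "low", "high")))
  out
}
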