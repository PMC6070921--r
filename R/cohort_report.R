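#' Profile one sample through every assay
#'
#' Runs junction quantification on the RNA reads and copy-number,
#' rearrangement and variant calling on the DNA reads. Assays whose input is
#' `NULL` are skipped and reported as `NA` (never silently defaulted).
#'
#' @param sample A sample entry from [generate_cohort()] (or any list with
#'   `sample`, `group`, `rna`, `dna`).
#' @param panel A [panel_config].
#' @param signatures Signature tibble (built once per cohort for speed).
#' @param min_support Split-read support cut-off for rearrangements.
#' @return One-row summary tibble; full per-assay results in attribute
#'   `detail`.
#' @export
profile_sample <- function(sample, panel,
                           signatures = build_signatures(panel),
                           min_support = 10) {
  sample_id <- sample$sample
  group_id <- sample$group
  out <- tibble(sample = sample_id, group = group_id)
  detail <- list()
  frac_cols <- function(fr, counts, v) {
    row <- fr |> filter(.data$variant_name == v)
    tibble("{tolower(gsub('-', '', v))}_fraction" := row$fraction,
           "{tolower(gsub('-', '', v))}_ci_lower" := row$ci95_lower,
           "{tolower(gsub('-', '', v))}_count" := row$numerator)
  }
  if (!is.null(sample$rna)) {
    counts <- count_junctions(sample$rna$reads, signatures)
    fr <- quantify_fractions(counts, panel)
    total <- total_arv_fraction(fr)
    canon <- counts |> filter(.data$variant_name == "AR-FL")
    out <- bind_cols(
      out,
      frac_cols(fr, counts, "AR-V3"), frac_cols(fr, counts, "AR-V7"),
      frac_cols(fr, counts, "AR-V9"),
      tibble(
        arfl_e2_count = canon$count[canon$upstream == "E2"],
        arfl_e3_count = canon$count[canon$upstream == "E3"],
        total_arv = total,
        arv_level = classify_arv_level(total)))
    detail$counts <- counts
    detail$fractions <- fr
  }
  if (!is.null(sample$dna)) {
    cn <- call_copy_number(sample$dna$reads, panel)
    ev <- call_rearrangements(sample$dna$reads, panel,
                              min_support = min_support)
    vc <- call_sample_variants(sample$dna$reads, panel)
    out <- bind_cols(out, tibble(
      cn_estimate = cn$cn_estimate, cn_label = cn$label,
      n_mutations = nrow(vc),
      mutations = if (nrow(vc) == 0) NA_character_ else
        paste(ifelse(is.na(vc$hotspot),
                     sprintf("%d%s>%s", vc$position, vc$ref, vc$alt),
                     vc$hotspot), collapse = ","),
      n_gsr = nrow(ev),
      gsr_types = if (nrow(ev) == 0) NA_character_ else
        paste(ev$type, collapse = ","),
      gsr_max_vaf = if (nrow(ev) == 0) NA_real_ else
        suppressWarnings(max(ev$vaf, na.rm = TRUE))))
    detail$cn <- cn
    detail$events <- ev
    detail$variants <- vc
  }
  attr(out, "detail") <- detail
  out
}

#' Profile a whole synthetic cohort
#'
#' Per-sample profiling plus cohort-level expression normalisation and
#' AR-signalling scores, assembled into the cohort summary object.
#'
#' @param cohort Output of [generate_cohort()].
#' @param panel A [panel_config].
#' @param min_support Split-read support cut-off.
#' @return An `arv_cohort` object (see [build_cohort_table()]).
#' @export
profile_cohort <- function(cohort, panel, min_support = 10) {
  sigs <- build_signatures(panel)
  summaries <- bind_rows(lapply(cohort$samples, profile_sample, panel = panel,
                                signatures = sigs,
                                min_support = min_support))
  if (!is.null(cohort$expression) &&
      length(unique(cohort$expression$sample)) >= 3) {
    scores <- signalling_score(normalize_counts(cohort$expression, panel),
                               panel)
    summaries <- summaries |> left_join(scores, by = "sample")
  }
  build_cohort_table(summaries)
}

#' Assemble cohort-level statistics from per-sample summaries
#'
#' Computes pairwise Mann-Whitney comparisons of the combined AR-V3/V7/V9
#' fraction across groups, Spearman correlations of each variant fraction
#' (and the combined fraction) against the AR-FL junction count of the
#' matching upstream-exon group, pairwise Spearman correlations between
#' variant junction counts, and a per-group alteration frequency table.
#' Samples missing an assay are excluded pairwise-complete.
#'
#' @param summaries Per-sample summary tibble from [profile_sample()].
#' @return An `arv_cohort` object: list of `samples`, `comparisons`,
#'   `correlations`, `frequency`.
#' @export
build_cohort_table <- function(summaries) {
  groups <- unique(summaries$group)
  comparisons <- list()
  if (length(groups) >= 2 && "total_arv" %in% names(summaries)) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (p in pairs) {
      a <- summaries$total_arv[summaries$group == p[1]]
      b <- summaries$total_arv[summaries$group == p[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) == 0 || length(b) == 0) next
      comparisons[[length(comparisons) + 1]] <-
        mann_whitney_u(a, b) |>
        mutate(group_a = p[1], group_b = p[2], .before = 1)
    }
  }
  comparisons <- bind_rows(comparisons)

  correlations <- list()
  add_cor <- function(label, x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 4 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      correlations[[length(correlations) + 1]] <<-
        spearman_cor(x[ok], y[ok]) |> mutate(pair = label, .before = 1)
  }
  s <- summaries
  if ("arv7_fraction" %in% names(s)) {
    add_cor("AR-V3 fraction vs AR-FL count", s$arv3_fraction, s$arfl_e2_count)
    add_cor("AR-V7 fraction vs AR-FL count", s$arv7_fraction, s$arfl_e3_count)
    add_cor("AR-V9 fraction vs AR-FL count", s$arv9_fraction, s$arfl_e3_count)
    add_cor("total AR-V fraction vs AR-FL count", s$total_arv, s$arfl_e3_count)
    add_cor("AR-V7 count vs AR-V9 count", s$arv7_count, s$arv9_count)
    add_cor("AR-V7 count vs AR-V3 count", s$arv7_count, s$arv3_count)
    add_cor("AR-V9 count vs AR-V3 count", s$arv9_count, s$arv3_count)
  }
  correlations <- bind_rows(correlations)

  col_or_na <- function(df, col, default = NA) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  frequency <- summaries |>
    mutate(cn_label = col_or_na(summaries, "cn_label", NA_character_),
           n_mutations = col_or_na(summaries, "n_mutations"),
           n_gsr = col_or_na(summaries, "n_gsr"),
           arv_level = col_or_na(summaries, "arv_level", NA_character_)) |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      n_mutated = sum(.data$n_mutations > 0, na.rm = TRUE),
      n_cn_gain = sum(.data$cn_label == "gain", na.rm = TRUE),
      n_cn_amplification = sum(.data$cn_label == "amplification",
                               na.rm = TRUE),
      n_gsr_positive = sum(.data$n_gsr > 0, na.rm = TRUE),
      n_arv_negative = sum(.data$arv_level == "negative", na.rm = TRUE),
      n_arv_low = sum(.data$arv_level == "low", na.rm = TRUE),
      n_arv_high = sum(.data$arv_level == "high", na.rm = TRUE),
      n_arv_not_assessable = sum(is.na(.data$arv_level) |
                                   .data$arv_level == "not_assessable"),
      .groups = "drop")

  structure(list(samples = summaries, comparisons = comparisons,
                 correlations = correlations, frequency = frequency),
            class = "arv_cohort")
}

#' @export
print.arv_cohort <- function(x, ...) {
  cat(sprintf("<arv_cohort> %d samples in %d group(s)\n",
              nrow(x$samples), nrow(x$frequency)))
  if (nrow(x$comparisons) > 0) {
    cat("group comparisons (combined AR-V fraction, Mann-Whitney):\n")
    print(as.data.frame(x$comparisons[, c("group_a", "group_b",
                                          "statistic", "p_two_sided")]))
  }
  invisible(x)
}

#' Write the cohort tables as TSV
#'
#' Four files (`samples.tsv`, `comparisons.tsv`, `correlations.tsv`,
#' `frequency.tsv`), written with round-trip-exact numeric formatting.
#'
#' @param x An `arv_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(x$comparisons, file.path(dir, "comparisons.tsv"))
  readr::write_tsv(x$correlations, file.path(dir, "correlations.tsv"))
  readr::write_tsv(x$frequency, file.path(dir, "frequency.tsv"))
  invisible(dir)
}
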