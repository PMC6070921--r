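#' Describe one cohort group for the synthetic-data generator
#'
#' Parameter distributions emulate the study design: hormone-naive groups
#' carry low splice-variant fractions, unaltered AR and modest expression of
#' AR-regulated genes; castration-resistant groups carry higher fractions,
#' frequent AR gains/amplifications, occasional hotspot mutations and
#' structural rearrangements, and higher AR-FL abundance.
#'
#' @param name Group label.
#' @param n Number of samples (>= 1).
#' @param arv_fraction_range Per-variant true-fraction range (uniform),
#'   applied to each of AR-V3/V7/V9.
#' @param rna_depth_range Junction-depth range (log-uniform).
#' @param couple_fractions_to_depth If `TRUE`, variant fractions rise with
#'   the sample's AR-FL abundance (shared latent quantile with jitter),
#'   emulating AR-locus expression driving variant expression.
#' @param cn_alteration_prob Probability of an AR copy-number alteration.
#' @param ar_cn_range Altered-copy-number range (log-uniform).
#' @param hotspot_prob,hotspot_vaf_range Hotspot mutation model.
#' @param gsr_prob,gsr_vaf_range Structural-rearrangement model.
#' @param expression_level Multiplier on AR-regulated gene means.
#' @param dna_depth Mean DNA coverage of control targets.
#' @return A `cohort_group` list.
#' @export
cohort_group <- function(name, n, arv_fraction_range = c(0, 0.02),
                         rna_depth_range = c(150, 800),
                         couple_fractions_to_depth = TRUE,
                         cn_alteration_prob = 0, ar_cn_range = c(2, 40),
                         hotspot_prob = 0, hotspot_vaf_range = c(0.1, 0.5),
                         gsr_prob = 0, gsr_vaf_range = c(0.03, 0.11),
                         expression_level = 1, dna_depth = 150) {
  if (n < 1) param_error("each group needs at least one sample")
  structure(as.list(environment()), class = "cohort_group")
}

#' Cohort specification
#'
#' @param groups List of [cohort_group()]s.
#' @param seed Master seed; per-sample seeds are derived by stable hashing
#'   of (master, sample id).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, seed = 1) {
  structure(list(groups = groups, seed = seed), class = "cohort_spec")
}

#' Default three-group study-like cohort
#'
#' Hormone-naive prostatectomy, lymph-node metastasis and CRPC metastasis
#' groups with increasing splice-variant fractions, AR-FL abundance and AR
#' copy-number alteration rates.
#'
#' @param n_per_group Integer vector of length 3.
#' @param seed Master seed.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n_per_group = c(10, 8, 15), seed = 1) {
  cohort_spec(list(
    cohort_group("prostatectomy", n_per_group[1],
                 arv_fraction_range = c(0, 0.02),
                 rna_depth_range = c(150, 800)),
    cohort_group("lymph_node_met", n_per_group[2],
                 arv_fraction_range = c(0.005, 0.04),
                 rna_depth_range = c(200, 1000),
                 cn_alteration_prob = 0.1),
    cohort_group("crpc_met", n_per_group[3],
                 arv_fraction_range = c(0.02, 0.12),
                 rna_depth_range = c(450, 2400),
                 cn_alteration_prob = 0.8, ar_cn_range = c(2, 70),
                 hotspot_prob = 0.2, gsr_prob = 0.15,
                 expression_level = 2)),
    seed = seed)
}

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

expression_base_means <- c(KLK3 = 2000, FKBP5 = 900, TMPRSS2 = 1200,
                           ACPP = 500, SLC45A3 = 700,
                           TBP = 800, STARD7 = 600, DDX1 = 700)

# draw one sample's truth parameters from its group spec
draw_sample_truth <- function(g, panel) {
  u_depth <- stats::runif(1)
  dr <- g$rna_depth_range
  rna_depth <- exp(log(dr[1]) + u_depth * (log(dr[2]) - log(dr[1])))
  fr <- g$arv_fraction_range
  fracs <- vapply(c("AR-V3", "AR-V7", "AR-V9"), function(v) {
    u <- if (isTRUE(g$couple_fractions_to_depth))
      min(1, max(0, u_depth + stats::runif(1, -0.15, 0.15)))
    else stats::runif(1)
    fr[1] + (fr[2] - fr[1]) * u
  }, numeric(1))
  ar_cn <- if (stats::runif(1) < g$cn_alteration_prob)
    runif_log(1, g$ar_cn_range) else 1
  hotspot <- NULL
  if (stats::runif(1) < g$hotspot_prob) {
    nm <- sample(panel$hotspots$name, 1)
    hotspot <- stats::setNames(stats::runif(1, g$hotspot_vaf_range[1],
                                            g$hotspot_vaf_range[2]), nm)
  }
  gsr <- NULL
  if (stats::runif(1) < g$gsr_prob) {
    span <- ar_span(panel)
    type <- sample(c("deletion", "duplication", "inversion",
                     "translocation"), 1)
    a <- round(stats::runif(1, span[1] + 400, span[2] - 2600))
    b <- if (type == "translocation") {
      ctl <- panel$control_targets
      round(stats::runif(1, ctl$start[1] + 200, ctl$end[1] - 200))
    } else if (type == "duplication") {
      round(a - stats::runif(1, 500, min(2000, a - span[1] - 200)))
    } else {
      round(a + stats::runif(1, 500, 2000))
    }
    gsr <- tibble(breakpoint_a = as.integer(a), breakpoint_b = as.integer(b),
                  type = type,
                  vaf = stats::runif(1, g$gsr_vaf_range[1], g$gsr_vaf_range[2]))
  }
  list(rna_depth = rna_depth, fractions = fracs, ar_cn = ar_cn,
       hotspot = hotspot, gsr = gsr)
}

#' Generate a synthetic cohort with known truth
#'
#' One RNA read set, one DNA read set and one expression-count draw per
#' sample, fully reproducible from the master seed. Optionally writes
#' per-sample FASTQ files and a truth TSV to a directory.
#'
#' @param panel A [panel_config].
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory for FASTQ + truth table.
#' @param assays Subset of `c("rna", "dna", "expression")` to simulate.
#' @return List with `samples` (named list; each holds `sample`, `group`,
#'   `rna`, `dna`, `truth_params`), `expression` (long counts tibble) and
#'   `truth` (one row per sample).
#' @export
generate_cohort <- function(panel, spec, dir = NULL,
                            assays = c("rna", "dna", "expression")) {
  samples <- list()
  truth_rows <- list()
  expr_rows <- list()
  for (g in spec$groups) {
    for (i in seq_len(g$n)) {
      id <- sprintf("%s_%02d", g$name, i)
      sseed <- derive_seed(spec$seed, id)
      tr <- with_seed(sseed, draw_sample_truth(g, panel))
      rna <- NULL
      if ("rna" %in% assays) {
        rna <- simulate_rna_reads(panel, fractions = tr$fractions,
                                  depth = tr$rna_depth,
                                  seed = derive_seed(sseed, "rna"))
      }
      dna <- NULL
      if ("dna" %in% assays) {
        dna <- simulate_dna_reads(panel, dna_truth(
          ar_copy_number = tr$ar_cn, gsr_events = tr$gsr,
          hotspot_vafs = tr$hotspot, depth = g$dna_depth,
          seed = derive_seed(sseed, "dna")))
      }
      expr <- NULL
      if ("expression" %in% assays) {
        expr <- with_seed(derive_seed(sseed, "expression"), {
          lib <- exp(stats::rnorm(1, 0, 0.3))
          roles <- panel$rna_genes
          mu <- expression_base_means[roles$gene] * lib *
            ifelse(roles$role == "ar_regulated", g$expression_level, 1)
          tibble(sample = id, gene = roles$gene,
                 count = stats::rnbinom(nrow(roles), size = 10, mu = mu))
        })
        expr_rows[[id]] <- expr
      }
      samples[[id]] <- list(sample = id, group = g$name, rna = rna,
                            dna = dna, truth_params = tr)
      truth_rows[[id]] <- tibble(
        sample = id, group = g$name, seed = sseed,
        rna_depth = tr$rna_depth,
        arv3_true = tr$fractions[["AR-V3"]],
        arv7_true = tr$fractions[["AR-V7"]],
        arv9_true = tr$fractions[["AR-V9"]],
        ar_cn_true = tr$ar_cn,
        hotspot = if (is.null(tr$hotspot)) NA_character_ else names(tr$hotspot),
        hotspot_vaf = if (is.null(tr$hotspot)) NA_real_ else unname(tr$hotspot),
        gsr_type = if (is.null(tr$gsr)) NA_character_ else tr$gsr$type,
        gsr_vaf = if (is.null(tr$gsr)) NA_real_ else tr$gsr$vaf)
    }
  }
  truth <- bind_rows(truth_rows)
  expression <- if (length(expr_rows) > 0) bind_rows(expr_rows) else NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in samples) {
      sd <- file.path(dir, s$sample)
      dir.create(sd, showWarnings = FALSE)
      if (!is.null(s$rna)) write_fastq(s$rna$reads, file.path(sd, "rna.fastq"))
      if (!is.null(s$dna)) write_fastq(s$dna$reads, file.path(sd, "dna.fastq"))
    }
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
    if (!is.null(expression))
      readr::write_tsv(expression, file.path(dir, "expression.tsv"))
  }
  list(samples = samples, expression = expression, truth = truth, spec = spec)
}
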