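#' Build junction signature sequences
#'
#' A signature is the concatenation of the 3' flank of the upstream exon and
#' the 5' flank of the downstream exon of one splice junction (default 130 bp
#' per side, truncated to the exon length when an exon is shorter). The
#' exon-exon boundary sits at `junction_offset` bases into the signature.
#'
#' @param panel A [panel_config].
#' @param flank Flank length per side in bp.
#' @return Tibble with one row per catalog junction: `variant_name`,
#'   `upstream`, `downstream`, `sequence`, `junction_offset`, `width`.
#' @export
build_signatures <- function(panel, flank = 130) {
  ex <- panel$exons
  jn <- panel$junctions
  up_seq <- ex$sequence[match(jn$upstream, ex$exon_id)]
  down_seq <- ex$sequence[match(jn$downstream, ex$exon_id)]
  up_take <- pmin(flank, nchar(up_seq))
  down_take <- pmin(flank, nchar(down_seq))
  sig <- paste0(
    substring(up_seq, nchar(up_seq) - up_take + 1, nchar(up_seq)),
    substring(down_seq, 1, down_take))
  out <- tibble(
    variant_name = jn$variant_name,
    upstream = jn$upstream, downstream = jn$downstream,
    sequence = sig, junction_offset = as.integer(up_take),
    width = nchar(sig))
  dup <- duplicated(out$sequence) | duplicated(out$sequence, fromLast = TRUE)
  if (any(dup)) {
    d <- out[dup, ]
    panel_error(sprintf(
      "identical signature sequences for junctions: %s",
      paste(sprintf("%s(%s->%s)", d$variant_name, d$upstream, d$downstream),
            collapse = ", ")))
  }
  out
}

junction_key <- function(up, down) paste(up, down, sep = "->")

#' Assign reads to junction signatures
#'
#' Ungapped matching with a mismatch budget: a read is assigned to a junction
#' when it aligns fully inside exactly one signature (either strand) with at
#' most `max_mismatches` substitutions, covering at least `min_overhang`
#' bases on each side of the exon-exon boundary. Alignments are ranked by
#' mismatch count; reads whose best alignment is tied across two or more
#' distinct signatures are left unassigned.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `sequence` column.
#' @param signatures Output of [build_signatures()].
#' @param min_overhang Minimum bases required on each side of the boundary.
#' @param max_mismatches Mismatch budget per alignment.
#' @return Character vector: junction key `"up->down"` per read, or `NA` for
#'   unassigned reads (no valid alignment, or an ambiguous tie).
#' @export
assign_read <- function(reads, signatures, min_overhang = 10,
                        max_mismatches = 3) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (length(seqs) > 0 && any(nchar(seqs) < 2 * min_overhang))
    abort("reads must be at least 2 * min_overhang long",
          class = "arv_param_error")
  hit <- cpp_assign_reads(seqs, signatures$sequence,
                          as.integer(signatures$junction_offset),
                          as.integer(min_overhang), as.integer(max_mismatches))
  key <- junction_key(signatures$upstream, signatures$downstream)
  out <- rep(NA_character_, length(hit))
  out[hit > 0] <- key[hit[hit > 0]]
  out
}

#' Count reads per junction
#'
#' @inheritParams assign_read
#' @return A `junction_counts` tibble: one row per catalog junction with its
#'   read `count`; attributes `n_reads`, `n_unassigned` and `n_ambiguous`
#'   record totals (ambiguous multi-signature ties are a subset of the
#'   unassigned reads).
#' @export
count_junctions <- function(reads, signatures, min_overhang = 10,
                            max_mismatches = 3) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  hit <- if (length(seqs) == 0) integer(0) else
    cpp_assign_reads(seqs, signatures$sequence,
                     as.integer(signatures$junction_offset),
                     as.integer(min_overhang), as.integer(max_mismatches))
  counts <- tabulate(hit[hit > 0], nbins = nrow(signatures))
  out <- signatures |>
    select("variant_name", "upstream", "downstream") |>
    mutate(count = as.integer(counts))
  attr(out, "n_reads") <- length(seqs)
  attr(out, "n_unassigned") <- sum(hit <= 0)
  attr(out, "n_ambiguous") <- sum(hit == -1)
  class(out) <- c("junction_counts", class(out))
  out
}

#' Exact binomial (Clopper-Pearson) 95% lower bound
#'
#' Lower endpoint of the two-sided exact 95% confidence interval on a
#' proportion `x / n`.
#'
#' @param x Successes. @param n Trials.
#' @return Numeric vector of lower bounds (0 when `x == 0`).
#' @export
ci95_lower <- function(x, n) {
  ifelse(x <= 0, 0, stats::qbeta(0.025, x, n - x + 1))
}

#' Quantify splice-variant fractions
#'
#' For each junction `u -> d`, the fraction is its read count divided by the
#' total count over all catalog junctions sharing the upstream exon `u`,
#' with an exact Clopper-Pearson 95% lower bound. Junction groups with a
#' zero denominator are reported as not quantifiable (`NA`).
#'
#' @param counts A `junction_counts` tibble from [count_junctions()].
#' @param panel A [panel_config] (same catalog the counts were computed on).
#' @return A `variant_fractions` tibble: `variant_name`, `upstream`,
#'   `downstream`, `numerator`, `denominator`, `fraction`, `ci95_lower`.
#' @export
quantify_fractions <- function(counts, panel) {
  out <- counts |>
    group_by(.data$upstream) |>
    mutate(numerator = .data$count,
           denominator = sum(.data$count)) |>
    ungroup() |>
    mutate(
      fraction = ifelse(.data$denominator > 0,
                        .data$numerator / .data$denominator, NA_real_),
      ci95_lower = ifelse(.data$denominator > 0,
                          ci95_lower(.data$numerator, .data$denominator),
                          NA_real_)) |>
    select("variant_name", "upstream", "downstream", "numerator",
           "denominator", "fraction", "ci95_lower")
  class(out) <- c("variant_fractions", class(out))
  out
}

#' Combined splice-variant fraction
#'
#' Sum of the point-estimate fractions of the named variants (each computed
#' against its own upstream-exon denominator).
#'
#' @param fractions A `variant_fractions` tibble.
#' @param variants Variant names to combine.
#' @return A single number, or `NA` if any component is not quantifiable.
#' @export
total_arv_fraction <- function(fractions,
                               variants = c("AR-V3", "AR-V7", "AR-V9")) {
  f <- fractions |> filter(.data$variant_name %in% variants)
  if (nrow(f) < length(variants) || any(is.na(f$fraction))) return(NA_real_)
  sum(f$fraction)
}

#' Export signatures as FASTA
#'
#' @param signatures Output of [build_signatures()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_signatures_fasta <- function(signatures, path) {
  lines <- as.vector(rbind(
    sprintf(">%s|%s", signatures$variant_name,
            junction_key(signatures$upstream, signatures$downstream)),
    signatures$sequence))
  writeLines(lines, path)
  invisible(path)
}
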