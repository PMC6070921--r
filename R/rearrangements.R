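#' Split-align reads against the panel reference
#'
#' Exhaustive ungapped two-segment alignment: finds the split `read[0:s]` /
#' `read[s:]` such that both segments map (either strand) with at most
#' `max_mismatches_per_segment` mismatches and at least `min_segment` bases,
#' maximising total matched length; under junction micro-homology the
#' leftmost maximal split is reported. Reads explained by a contiguous
#' alignment (with twice the per-segment mismatch budget, or with a gap of
#' at most `max_normal_gap`) return no split.
#'
#' @param reads Character vector of read sequences (or tibble with
#'   `sequence`).
#' @param panel A [panel_config] (its locus is the reference).
#' @param min_segment Minimum mapped bases per segment.
#' @param max_mismatches_per_segment Mismatch budget per segment.
#' @param max_normal_gap Reference gap still considered contiguous.
#' @return Tibble of `SplitAlignment`s (one row per read that split):
#'   `read_index`, `split_pos`, `breakpoint_a`, `breakpoint_b`, `strand_a`,
#'   `strand_b`, `matched`.
#' @export
split_align <- function(reads, panel, min_segment = 25,
                        max_mismatches_per_segment = 2, max_normal_gap = 5) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (any(nchar(seqs) < 2 * min_segment))
    param_error("reads must be at least 2 * min_segment long")
  out <- list()
  for (i in seq_along(seqs)) {
    res <- cpp_split_align(seqs[i], panel$locus_sequence,
                           as.integer(min_segment),
                           as.integer(max_mismatches_per_segment),
                           as.integer(max_normal_gap),
                           as.integer(2 * max_mismatches_per_segment))
    if (isTRUE(res$found)) {
      # canonical orientation: a split (s1, s2, a, b) read on the opposite
      # sequencing strand appears as (!s2, !s1, b, a); fold (-,-) onto (+,+)
      # and order mixed-strand (inversion) breakpoints ascending
      bpa <- res$breakpoint_a; bpb <- res$breakpoint_b
      sa <- res$strand_a; sb <- res$strand_b
      if (sa == "-" && sb == "-") {
        tmp <- bpa; bpa <- bpb; bpb <- tmp
        sa <- "+"; sb <- "+"
      } else if (sa != sb && bpa > bpb) {
        tmp <- bpa; bpa <- bpb; bpb <- tmp
      }
      out[[length(out) + 1]] <- tibble(
        read_index = i, split_pos = res$split_pos,
        breakpoint_a = bpa, breakpoint_b = bpb,
        strand_a = sa, strand_b = sb,
        matched = res$matched)
    }
  }
  bind_rows(out)
}

#' Classify a rearrangement from segment orientations and breakpoint order
#'
#' Same gene region and strand with a forward skip is a deletion; a backward
#' link is a tandem duplication; opposite strands are an inversion; segments
#' in different gene regions are a translocation.
#'
#' @param strand_a,strand_b Segment strands (`"+"`/`"-"`).
#' @param breakpoint_a,breakpoint_b Breakpoint coordinates.
#' @param same_locus Logical: both breakpoints in the same gene region.
#' @return Character vector of event types.
#' @export
classify_event <- function(strand_a, strand_b, breakpoint_a, breakpoint_b,
                           same_locus = TRUE) {
  ifelse(!same_locus, "translocation",
         ifelse(strand_a != strand_b, "inversion",
                ifelse(breakpoint_b > breakpoint_a, "deletion",
                       "duplication")))
}

#' Cluster split alignments into breakpoint events
#'
#' Split alignments agreeing in segment orientations and in both breakpoints
#' within `tolerance` are merged; the event breakpoints are the medians of
#' the members' breakpoints and the split-read support is the cluster size.
#'
#' @param splits Tibble from [split_align()].
#' @param panel A [panel_config] (for gene-region lookup and typing).
#' @param tolerance Maximum breakpoint distance within a cluster, bp.
#' @return Tibble of `BreakpointEvent`s sorted by support (descending):
#'   `breakpoint_a`, `breakpoint_b`, `strand_a`, `strand_b`, `type`,
#'   `n_split_support`.
#' @export
cluster_events <- function(splits, panel, tolerance = 10) {
  if (tolerance < 0) param_error("tolerance must be >= 0")
  if (nrow(splits) == 0)
    return(tibble(breakpoint_a = integer(), breakpoint_b = integer(),
                  strand_a = character(), strand_b = character(),
                  type = character(), n_split_support = integer()))
  splits <- splits |> arrange(.data$strand_a, .data$strand_b,
                              .data$breakpoint_a, .data$breakpoint_b)
  cluster <- integer(nrow(splits))
  cid <- 0L
  anchor_a <- anchor_b <- NA_integer_
  key <- paste(splits$strand_a, splits$strand_b)
  prev_key <- ""
  for (i in seq_len(nrow(splits))) {
    new <- key[i] != prev_key ||
      abs(splits$breakpoint_a[i] - anchor_a) > tolerance ||
      abs(splits$breakpoint_b[i] - anchor_b) > tolerance
    if (new) {
      cid <- cid + 1L
      anchor_a <- splits$breakpoint_a[i]
      anchor_b <- splits$breakpoint_b[i]
      prev_key <- key[i]
    }
    cluster[i] <- cid
  }
  events <- splits |>
    mutate(cluster = cluster) |>
    group_by(.data$cluster, .data$strand_a, .data$strand_b) |>
    summarise(breakpoint_a = as.integer(round(stats::median(.data$breakpoint_a))),
              breakpoint_b = as.integer(round(stats::median(.data$breakpoint_b))),
              n_split_support = dplyr::n(), .groups = "drop") |>
    select(-"cluster")
  region_a <- region_of(panel, events$breakpoint_a)
  region_b <- region_of(panel, events$breakpoint_b)
  events |>
    mutate(region_a = region_a, region_b = region_b,
           type = classify_event(.data$strand_a, .data$strand_b,
                                 .data$breakpoint_a, .data$breakpoint_b,
                                 region_a == region_b)) |>
    arrange(desc(.data$n_split_support))
}

#' Estimate the variant allele fraction of a breakpoint event
#'
#' VAF = split support / (split support + contiguous reads spanning
#' `breakpoint_a` by at least `min_segment` bases on each side).
#'
#' @param events Event tibble from [cluster_events()].
#' @param reads DNA read tibble (contiguous reads are those with
#'   `aligned = TRUE` or verified by the caller).
#' @param min_segment Minimum bases on each side of the breakpoint.
#' @return `events` with `n_reference_spanning` and `vaf` columns (`NA` when
#'   the denominator is zero).
#' @export
event_vaf <- function(events, reads, min_segment = 25) {
  if (nrow(events) == 0)
    return(events |> mutate(n_reference_spanning = integer(), vaf = numeric()))
  spanning <- vapply(events$breakpoint_a, function(bp)
    sum(reads$start <= bp - min_segment & reads$end >= bp + min_segment),
    numeric(1))
  events |>
    mutate(n_reference_spanning = as.integer(spanning),
           vaf = ifelse(.data$n_split_support + spanning > 0,
                        .data$n_split_support /
                          (.data$n_split_support + spanning), NA_real_))
}

#' Call structural rearrangements from a DNA read set
#'
#' Breakfast-style split-read calling: reads are first verified against
#' their recorded alignment; reads that do not map contiguously are
#' split-aligned exhaustively against the panel locus, the resulting split
#' alignments are clustered into events, typed, filtered to events with at
#' least one breakpoint in the AR gene region and at least `min_support`
#' supporting split reads, and assigned a variant allele fraction.
#'
#' @param reads DNA read tibble from [simulate_dna_reads()] (columns
#'   `sequence`, `start`, `strand`).
#' @param panel A [panel_config].
#' @param min_segment,max_mismatches_per_segment,max_normal_gap See
#'   [split_align()].
#' @param tolerance Breakpoint clustering tolerance, bp.
#' @param min_support Minimum split-read support (default 10).
#' @param require_ar Keep only events with a breakpoint in the AR region.
#' @return Event tibble with support and VAF, sorted by support.
#' @export
call_rearrangements <- function(reads, panel, min_segment = 25,
                                max_mismatches_per_segment = 2,
                                max_normal_gap = 5, tolerance = 10,
                                min_support = 10, require_ar = TRUE) {
  mm <- cpp_contig_mismatch(reads$sequence, as.integer(reads$start),
                            reads$strand, panel$locus_sequence,
                            as.integer(2 * max_mismatches_per_segment))
  contiguous <- mm <= 2 * max_mismatches_per_segment
  candidates <- reads[!contiguous, ]
  splits <- split_align(candidates, panel, min_segment,
                        max_mismatches_per_segment, max_normal_gap)
  events <- cluster_events(splits, panel, tolerance)
  if (require_ar && nrow(events) > 0) {
    span <- ar_span(panel)
    in_ar <- function(p) p >= span[1] & p < span[2]
    events <- events |>
      filter(in_ar(.data$breakpoint_a) | in_ar(.data$breakpoint_b))
  }
  events <- events |> filter(.data$n_split_support >= min_support)
  event_vaf(events, reads[contiguous, ], min_segment)
}

#' Write events as BEDPE
#'
#' @param events Event tibble from [call_rearrangements()].
#' @param panel A [panel_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_events_bedpe <- function(events, panel, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\t%.4f",
    panel$locus_name, events$breakpoint_a, events$breakpoint_a + 1L,
    panel$locus_name, events$breakpoint_b, events$breakpoint_b + 1L,
    events$type, events$n_split_support, events$strand_a, events$strand_b,
    ifelse(is.na(events$vaf), -1, events$vaf))
  writeLines(c(paste("#chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                     "end_b", "type", "split_support", "strand_a", "strand_b",
                     "vaf", sep = "\t"), lines), path)
  invisible(path)
}
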