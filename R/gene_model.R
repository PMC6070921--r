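#' @useDynLib arvprofiler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# 0-based half-open substring of a locus sequence
subseq0 <- function(seq, start, end) substring(seq, start + 1L, end)

#' Reverse-complement nucleotide sequences
#'
#' @param seqs Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) cpp_revcomp(as.character(seqs))

panel_error <- function(msg) abort(msg, class = "arv_panel_error")

#' Construct a panel configuration
#'
#' A panel ties together the mock reference sequence, the exon catalog of the
#' AR-like gene (canonical exons `E1..E8` plus cryptic exons `CE*`), the named
#' splice-junction catalog, DNA capture targets, control-gene targets used for
#' coverage normalisation, the expression gene list (five AR-regulated genes
#' plus three housekeeping genes) and the hotspot mutation table. All
#' coordinates are 0-based half-open on the plus strand of the locus.
#'
#' @param locus_sequence Single reference sequence (character scalar).
#' @param exons Tibble with columns `exon_id`, `start`, `end` and optionally
#'   `sequence` (extracted from `locus_sequence` when absent).
#' @param junctions Tibble with columns `variant_name`, `upstream`,
#'   `downstream` (exon ids).
#' @param dna_targets,control_targets Tibbles with `region`, `start`, `end`.
#' @param rna_genes Tibble with `gene`, `role` (`ar_regulated` or
#'   `housekeeping`), `start`, `end`.
#' @param hotspots Tibble with `name`, `position`, `ref`, `alt`.
#' @param locus_name Name of the reference sequence.
#' @param strand Strand the gene is annotated on; the pipeline operates in
#'   transcript orientation, so this is carried as metadata only.
#' @param ploidy Named list with `ar` and `control` copy numbers of an
#'   unaltered genome (defaults: X-linked AR in a male, autosomal controls).
#' @return A `panel_config` object (validated).
#' @export
panel_config <- function(locus_sequence, exons, junctions, dna_targets,
                         control_targets, rna_genes, hotspots,
                         locus_name = "mock_locus", strand = "+",
                         ploidy = list(ar = 1, control = 2)) {
  exons <- as_tibble(exons)
  if (!"sequence" %in% names(exons)) exons$sequence <- NA_character_
  exons <- exons |>
    mutate(
      start = as.integer(.data$start), end = as.integer(.data$end),
      sequence = ifelse(is.na(.data$sequence),
                        subseq0(locus_sequence, .data$start, .data$end),
                        .data$sequence))
  panel <- structure(
    list(
      locus_name = locus_name,
      locus_sequence = locus_sequence,
      strand = strand,
      exons = exons,
      junctions = as_tibble(junctions),
      dna_targets = as_tibble(dna_targets) |>
        mutate(start = as.integer(.data$start), end = as.integer(.data$end)),
      control_targets = as_tibble(control_targets) |>
        mutate(start = as.integer(.data$start), end = as.integer(.data$end)),
      rna_genes = as_tibble(rna_genes),
      hotspots = as_tibble(hotspots) |>
        mutate(position = as.integer(.data$position)),
      ploidy = ploidy
    ),
    class = "panel_config"
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  ex <- panel$exons
  if (nrow(ex) == 0) panel_error("panel must define at least one exon")
  if (any(ex$end <= ex$start)) panel_error("exon intervals must have length > 0")
  if (any(nchar(ex$sequence) != ex$end - ex$start))
    panel_error("exon sequence length must equal interval length")
  if (any(ex$end > nchar(panel$locus_sequence)))
    panel_error("exon interval outside locus sequence")
  if (anyDuplicated(ex$exon_id)) panel_error("duplicate exon ids")
  o <- order(ex$start)
  if (any(ex$start[o][-1] < ex$end[o][-nrow(ex)]))
    panel_error("exon intervals overlap")
  jn <- panel$junctions
  missing <- setdiff(c(jn$upstream, jn$downstream), ex$exon_id)
  if (length(missing) > 0) {
    bad <- jn |> filter(.data$upstream %in% missing | .data$downstream %in% missing)
    panel_error(sprintf(
      "junction %s (%s -> %s) references unknown exon(s): %s",
      bad$variant_name[1], bad$upstream[1], bad$downstream[1],
      paste(unique(missing), collapse = ", ")))
  }
  if (anyDuplicated(paste(jn$upstream, jn$downstream)))
    panel_error("duplicate (upstream, downstream) junction pair in catalog")
  up_start <- ex$start[match(jn$upstream, ex$exon_id)]
  down_start <- ex$start[match(jn$downstream, ex$exon_id)]
  if (any(up_start >= down_start))
    panel_error("junction upstream exon must precede downstream exon")
  # dna and control targets disjoint
  tg <- bind_rows(panel$dna_targets |> mutate(.kind = "dna"),
                  panel$control_targets |> mutate(.kind = "control"))
  if (nrow(tg) > 1) {
    tg <- tg[order(tg$start), ]
    if (any(tg$start[-1] < tg$end[-nrow(tg)] &
            tg$.kind[-1] != tg$.kind[-nrow(tg)]))
      panel_error("dna_targets and control_targets must be disjoint")
  }
  hs <- panel$hotspots
  if (nrow(hs) > 0) {
    at <- substring(panel$locus_sequence, hs$position + 1, hs$position + 1)
    bad <- which(at != hs$ref)
    if (length(bad) > 0)
      panel_error(sprintf(
        "hotspot %s: ref base '%s' does not match locus base '%s' at %d",
        hs$name[bad[1]], hs$ref[bad[1]], at[bad[1]], hs$position[bad[1]]))
  }
  invisible(panel)
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config> locus '%s' (%d bp, %s strand)\n",
              x$locus_name, nchar(x$locus_sequence), x$strand))
  cat(sprintf("  %d exons, %d junctions (%d variants), %d hotspots\n",
              nrow(x$exons), nrow(x$junctions),
              length(unique(x$junctions$variant_name)), nrow(x$hotspots)))
  cat(sprintf("  %d DNA target(s), %d control target(s), %d expression genes\n",
              nrow(x$dna_targets), nrow(x$control_targets), nrow(x$rna_genes)))
  invisible(x)
}

#' Load a panel configuration from a YAML file
#'
#' The file holds the locus sequence (inline), the exon table, the junction
#' catalog, BED-style target intervals, the expression gene list and the
#' hotspot table. All invariants are checked on load; exon sequences are
#' extracted from the locus when not given explicitly.
#'
#' @param path Path to a YAML panel file.
#' @return A validated [panel_config] object.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) panel_error(sprintf("panel file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  need <- c("locus_sequence", "exons", "junctions", "dna_targets",
            "control_targets", "rna_genes", "hotspots")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    panel_error(paste("panel file missing fields:", paste(miss, collapse = ", ")))
  to_tbl <- function(x) bind_rows(lapply(x, as_tibble))
  panel_config(
    locus_sequence = cfg$locus_sequence,
    exons = to_tbl(cfg$exons) |> rename(exon_id = "id"),
    junctions = to_tbl(cfg$junctions) |> rename(variant_name = "variant"),
    dna_targets = to_tbl(cfg$dna_targets),
    control_targets = to_tbl(cfg$control_targets),
    rna_genes = to_tbl(cfg$rna_genes),
    hotspots = if (length(cfg$hotspots) > 0) to_tbl(cfg$hotspots) else
      tibble(name = character(), position = integer(),
             ref = character(), alt = character()),
    locus_name = cfg$locus_name %||% "mock_locus",
    strand = cfg$strand %||% "+",
    ploidy = cfg$ploidy %||% list(ar = 1, control = 2)
  )
}

#' Write a panel configuration to a YAML file
#'
#' Round-trips with [load_panel()]: reloading yields a field-by-field
#' identical model.
#'
#' @param panel A [panel_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  rows <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  cfg <- list(
    locus_name = panel$locus_name,
    strand = panel$strand,
    ploidy = panel$ploidy,
    locus_sequence = panel$locus_sequence,
    exons = rows(panel$exons |> select("exon_id", "start", "end") |>
                   rename(id = "exon_id")),
    junctions = rows(panel$junctions |> rename(variant = "variant_name")),
    dna_targets = rows(panel$dna_targets),
    control_targets = rows(panel$control_targets),
    rna_genes = rows(panel$rna_genes),
    hotspots = rows(panel$hotspots)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Group the junction catalog by upstream exon
#'
#' Splice-variant fractions are defined within the set of junctions sharing
#' an upstream exon; this grouping partitions the catalog.
#'
#' @param panel A [panel_config].
#' @return Named list of junction tibbles, one element per upstream exon id.
#' @export
junctions_by_upstream <- function(panel) {
  jn <- panel$junctions
  split(jn, jn$upstream)
}

# gene region ("AR", a control gene name, or "intergenic") of a coordinate
region_of <- function(panel, pos) {
  out <- rep("intergenic", length(pos))
  ar <- panel$dna_targets
  ctl <- panel$control_targets
  for (i in seq_len(nrow(ar)))
    out[pos >= ar$start[i] & pos < ar$end[i]] <- ar$region[i]
  for (i in seq_len(nrow(ctl)))
    out[pos >= ctl$start[i] & pos < ctl$end[i]] <- ctl$region[i]
  out
}

ar_span <- function(panel) {
  c(min(panel$dna_targets$start), max(panel$dna_targets$end))
}

#' Export panel targets as BED
#'
#' Writes DNA and control capture targets in BED format (0-based half-open,
#' matching the panel's internal convention).
#'
#' @param panel A [panel_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_targets_bed <- function(panel, path) {
  tg <- bind_rows(panel$dna_targets, panel$control_targets)
  lines <- sprintf("%s\t%d\t%d\t%s", panel$locus_name, tg$start, tg$end, tg$region)
  writeLines(lines, path)
  invisible(path)
}

#' Export the locus reference as FASTA
#'
#' @param panel A [panel_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_locus_fasta <- function(panel, path) {
  seq <- panel$locus_sequence
  chunks <- substring(seq, seq(1, nchar(seq), 70),
                      pmin(seq(1, nchar(seq), 70) + 69, nchar(seq)))
  writeLines(c(paste0(">", panel$locus_name), chunks), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
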