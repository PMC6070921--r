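# Deterministic pseudo-random nucleotide sequence (LCG; independent of R's RNG
# so panel construction never perturbs simulation seeds).
lcg_sequence <- function(n, seed = 20180417) {
  x <- as.double(seed %% 2147483647)
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * x + 12345) %% 2147483648
    out[i] <- (x %/% 65536) %% 4
  }
  paste(c("A", "C", "G", "T")[out + 1L], collapse = "")
}

#' Build the mock AR panel
#'
#' Constructs a synthetic plus-strand locus emulating the structure of a
#' targeted AR panel: eight canonical exons (`E1`..`E8`) separated by introns,
#' five cryptic exons (`CE1`..`CE5`) placed in the intron downstream of `E3`,
#' a control-gene region downstream of the AR-like gene (stand-ins for the
#' panel's non-AR genes, used for copy-number normalisation), expression
#' intervals for the five AR-regulated and three housekeeping genes, and
#' three hotspot positions named after the classical AR ligand-binding-domain
#' mutations (L702H in exon 4; H875Y and T878A in exon 8).
#'
#' The junction catalog encodes one defensible exon composition per splice
#' variant (a stand-in, since true signature sequences are assay-specific):
#' `AR-V7 = E3->CE3`, `AR-V9 = E3->CE5`, `AR-V3 = E2->CE4`, `AR-V4 = E3->CE1`,
#' `AR-V5 = E3->CE2`, `AR-V6 = E2->CE2`, plus the seven canonical `AR-FL`
#' junctions `E1->E2` .. `E7->E8`.
#'
#' @param seed Seed of the deterministic locus sequence generator.
#' @return A validated [panel_config].
#' @export
mock_ar_panel <- function(seed = 20180417) {
  exon_len <- c(E1 = 280L, E2 = 200L, E3 = 180L, E4 = 220L, E5 = 160L,
                E6 = 150L, E7 = 190L, E8 = 320L)
  ce_len <- c(CE1 = 150L, CE2 = 160L, CE3 = 170L, CE4 = 150L, CE5 = 180L)
  intron <- 400L
  ce_gap <- 130L

  pos <- 600L  # left pad (room for capture fragments overhanging the target)
  ex <- list()
  place <- function(id, len) {
    row <- tibble(exon_id = id, start = pos, end = pos + len)
    pos <<- pos + len
    row
  }
  ex$E1 <- place("E1", exon_len[["E1"]]); pos <- pos + intron
  ex$E2 <- place("E2", exon_len[["E2"]]); pos <- pos + intron
  ex$E3 <- place("E3", exon_len[["E3"]])
  for (ce in names(ce_len)) {
    pos <- pos + ce_gap
    ex[[ce]] <- place(ce, ce_len[[ce]])
  }
  pos <- pos + ce_gap
  ex$E4 <- place("E4", exon_len[["E4"]]); pos <- pos + intron
  ex$E5 <- place("E5", exon_len[["E5"]]); pos <- pos + intron
  ex$E6 <- place("E6", exon_len[["E6"]]); pos <- pos + intron
  ex$E7 <- place("E7", exon_len[["E7"]]); pos <- pos + intron
  ex$E8 <- place("E8", exon_len[["E8"]])
  exons <- bind_rows(ex)

  ar_start <- min(exons$start) - 150L
  ar_end <- max(exons$end) + 150L
  dna_targets <- tibble(region = "AR", start = ar_start, end = ar_end)

  pos <- ar_end + 500L
  ctl <- list()
  for (spec in list(c("FOXA1L", 2400L), c("SPOPL1", 1600L), c("SPOPL2", 1200L))) {
    len <- as.integer(spec[2])
    ctl[[spec[1]]] <- tibble(region = spec[1], start = pos, end = pos + len)
    pos <- pos + len + 250L
  }
  control_targets <- bind_rows(ctl)

  pos <- pos + 300L
  genes <- c("KLK3", "FKBP5", "TMPRSS2", "ACPP", "SLC45A3",
             "TBP", "STARD7", "DDX1")
  roles <- c(rep("ar_regulated", 5), rep("housekeeping", 3))
  rg <- list()
  for (i in seq_along(genes)) {
    rg[[i]] <- tibble(gene = genes[i], role = roles[i],
                      start = pos, end = pos + 400L)
    pos <- pos + 550L
  }
  rna_genes <- bind_rows(rg)

  locus_len <- pos + 200L
  locus <- lcg_sequence(locus_len, seed = seed)

  next_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  hs_pos <- c(L702H = exons$start[exons$exon_id == "E4"] + 63L,
              H875Y = exons$start[exons$exon_id == "E8"] + 96L,
              T878A = exons$start[exons$exon_id == "E8"] + 105L)
  refs <- substring(locus, hs_pos + 1L, hs_pos + 1L)
  hotspots <- tibble(
    name = names(hs_pos), position = unname(hs_pos),
    ref = refs, alt = vapply(refs, next_base, character(1), USE.NAMES = FALSE))

  junctions <- bind_rows(
    tibble(variant_name = "AR-FL",
           upstream = paste0("E", 1:7), downstream = paste0("E", 2:8)),
    tibble(variant_name = c("AR-V7", "AR-V9", "AR-V3", "AR-V4", "AR-V5", "AR-V6"),
           upstream = c("E3", "E3", "E2", "E3", "E3", "E2"),
           downstream = c("CE3", "CE5", "CE4", "CE1", "CE2", "CE2"))
  )

  panel_config(
    locus_sequence = locus, exons = exons, junctions = junctions,
    dna_targets = dna_targets, control_targets = control_targets,
    rna_genes = rna_genes, hotspots = hotspots,
    locus_name = "mock_ar_locus", strand = "+",
    ploidy = list(ar = 1, control = 2))
}

canonical_exons <- function(panel) {
  ex <- panel$exons |> filter(!grepl("^CE", .data$exon_id)) |> arrange(.data$start)
  ex$exon_id
}

#' Assemble a transcript from the exon catalog
#'
#' `AR-FL` is the concatenation of all canonical exons in genomic order; a
#' splice variant keeps the canonical exons up to and including its upstream
#' exon and appends its cryptic exon.
#'
#' @param panel A [panel_config].
#' @param variant_name `"AR-FL"` or a variant name present in the catalog.
#' @return List with `sequence` (transcript string) and `junctions`, a tibble
#'   of exon-exon boundaries (`upstream`, `downstream`, `pos` = transcript
#'   coordinate of the boundary).
#' @export
transcript_sequence <- function(panel, variant_name) {
  ex <- panel$exons
  canon <- canonical_exons(panel)
  if (variant_name == "AR-FL") {
    ids <- canon
  } else {
    jn <- panel$junctions |> filter(.data$variant_name == !!variant_name)
    if (nrow(jn) == 0)
      panel_error(sprintf("variant '%s' not in junction catalog", variant_name))
    up <- jn$upstream[1]
    ids <- c(canon[seq_len(match(up, canon))], jn$downstream[1])
  }
  seqs <- ex$sequence[match(ids, ex$exon_id)]
  lens <- nchar(seqs)
  bounds <- cumsum(lens)
  list(
    sequence = paste(seqs, collapse = ""),
    junctions = tibble(upstream = ids[-length(ids)], downstream = ids[-1],
                       pos = bounds[-length(bounds)])
  )
}
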