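#' Pile up base counts over target intervals
#'
#' Per-position counts of A/C/G/T among contiguously aligned reads, plus
#' total covering depth. Positions are 0-based locus coordinates.
#'
#' @param reads DNA read tibble (`sequence`, `start`, `strand`; rows with
#'   `aligned = FALSE` are excluded).
#' @param panel A [panel_config].
#' @param targets Target intervals (default: the panel's DNA targets).
#' @return Tibble: `position`, `depth`, `A`, `C`, `G`, `T`.
#' @export
pileup <- function(reads, panel, targets = panel$dna_targets) {
  if ("aligned" %in% names(reads)) reads <- reads |> filter(.data$aligned)
  out <- list()
  for (i in seq_len(nrow(targets))) {
    lo <- targets$start[i]; hi <- targets$end[i]
    keep <- reads$end > lo & reads$start < hi
    m <- cpp_pileup(reads$sequence[keep], as.integer(reads$start[keep]),
                    reads$strand[keep], as.integer(lo), as.integer(hi))
    out[[i]] <- tibble(position = seq.int(lo, hi - 1L),
                       depth = m[5, ], A = m[1, ], C = m[2, ],
                       G = m[3, ], T = m[4, ])
  }
  bind_rows(out)
}

#' Call substitution variants from a pileup
#'
#' Emits positions where the most frequent non-reference allele passes the
#' depth, allele-fraction and alternate-read thresholds; calls matching a
#' panel hotspot (position and alternate base) carry the hotspot name.
#'
#' @param pu Pileup tibble from [pileup()].
#' @param panel A [panel_config] (reference bases and hotspot table).
#' @param min_depth Minimum covering depth.
#' @param min_vaf Minimum variant allele fraction.
#' @param min_alt_reads Minimum alternate-allele reads.
#' @return Tibble of calls: `position`, `ref`, `alt`, `alt_count`, `depth`,
#'   `vaf`, `hotspot`.
#' @export
call_variants <- function(pu, panel, min_depth = 50, min_vaf = 0.05,
                          min_alt_reads = 5) {
  if (nrow(pu) == 0)
    return(tibble(position = integer(), ref = character(), alt = character(),
                  alt_count = integer(), depth = integer(), vaf = numeric(),
                  hotspot = character()))
  bases <- c("A", "C", "G", "T")
  ref <- substring(panel$locus_sequence, pu$position + 1L, pu$position + 1L)
  cnt <- as.matrix(pu[, bases])
  ref_col <- match(ref, bases)
  idx <- cbind(seq_len(nrow(cnt)), ref_col)
  alt_cnt <- cnt
  alt_cnt[idx[!is.na(ref_col), , drop = FALSE]] <- -1L
  best <- max.col(alt_cnt, ties.method = "first")
  alt_count <- alt_cnt[cbind(seq_len(nrow(cnt)), best)]
  vaf <- ifelse(pu$depth > 0, alt_count / pu$depth, 0)
  keep <- pu$depth >= min_depth & alt_count >= min_alt_reads & vaf >= min_vaf
  out <- tibble(position = pu$position[keep], ref = ref[keep],
                alt = bases[best[keep]],
                alt_count = as.integer(alt_count[keep]),
                depth = as.integer(pu$depth[keep]), vaf = vaf[keep])
  hs <- panel$hotspots
  m <- match(paste(out$position, out$alt), paste(hs$position, hs$alt))
  out$hotspot <- hs$name[m]
  out
}

#' Call variants from a DNA read set
#'
#' Pileup over the panel's DNA targets followed by [call_variants()].
#'
#' @inheritParams pileup
#' @inheritParams call_variants
#' @return Variant call tibble.
#' @export
call_sample_variants <- function(reads, panel, min_depth = 50,
                                 min_vaf = 0.05, min_alt_reads = 5) {
  call_variants(pileup(reads, panel), panel, min_depth, min_vaf,
                min_alt_reads)
}

#' Write variant calls as a minimal VCF
#'
#' Positions are converted to 1-based on export.
#'
#' @param calls Call tibble from [call_variants()].
#' @param panel A [panel_config].
#' @param path Output path.
#' @param sample Sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, panel, path, sample = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", panel$locus_name,
            nchar(panel$locus_sequence)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=HOTSPOT,Number=1,Type=String,Description=\"Hotspot name\">",
    sprintf("##sample=%s", sample),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  info <- sprintf("DP=%d;AF=%.4f%s", calls$depth, calls$vaf,
                  ifelse(is.na(calls$hotspot), "",
                         paste0(";HOTSPOT=", calls$hotspot)))
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                   panel$locus_name, calls$position + 1L,
                   ifelse(is.na(calls$hotspot), ".", calls$hotspot),
                   calls$ref, calls$alt, info)
  writeLines(c(header, lines), path)
  invisible(path)
}
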