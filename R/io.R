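#' Write reads as FASTQ
#'
#' Constant base quality (Q40); read ids come from the `read_id` column.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    abort("malformed FASTQ: line count not a multiple of 4",
          class = "arv_io_error")
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  tibble(read_id = ids, sequence = lines[seq(2, length(lines), by = 4)])
}

#' Export windowed coverage as TSV
#'
#' @param windows Window tibble from [window_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_windows_tsv <- function(windows, path) {
  readr::write_tsv(windows, path)
  invisible(path)
}

#' Export variant fractions as TSV
#'
#' @param fractions A `variant_fractions` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_fractions_tsv <- function(fractions, path) {
  readr::write_tsv(fractions, path)
  invisible(path)
}
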