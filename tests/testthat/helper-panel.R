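# shared fixtures, built once per test run

the_panel <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- mock_ar_panel()
    p
  }
})

the_signatures <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- build_signatures(the_panel())
    s
  }
})

# tiny two-exon panel: one junction, exon lengths controllable
tiny_panel <- function(up_len = 200, down_len = 200, seed = 99) {
  locus <- arvprofiler:::lcg_sequence(up_len + down_len + 1200, seed = seed)
  panel_config(
    locus_sequence = locus,
    exons = tibble::tibble(exon_id = c("E1", "E2"),
                           start = c(200, 200 + up_len + 300),
                           end = c(200 + up_len, 200 + up_len + 300 + down_len)),
    junctions = tibble::tibble(variant_name = "AR-FL",
                               upstream = "E1", downstream = "E2"),
    dna_targets = tibble::tibble(region = "AR", start = 150,
                                 end = 200 + up_len + 300 + down_len + 50),
    control_targets = tibble::tibble(region = "CTL",
                                     start = 200 + up_len + 300 + down_len + 200,
                                     end = 200 + up_len + 300 + down_len + 700),
    rna_genes = tibble::tibble(gene = c("G1", "H1", "H2", "H3"),
                               role = c("ar_regulated", rep("housekeeping", 3)),
                               start = 0, end = 10),
    hotspots = tibble::tibble(name = character(), position = integer(),
                              ref = character(), alt = character()))
}

# deterministic uniform read extraction from a sequence (no errors)
reads_from <- function(seq, starts, len) {
  substring(seq, starts + 1, starts + len)
}

fixture_yaml <- function() {
  system.file("extdata", "mock_ar_panel.yaml", package = "arvprofiler")
}
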