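test_that("reads drawn from the reference do not split", {
  p <- the_panel()
  starts <- seq(1000, 5000, by = 500)
  reads <- reads_from(p$locus_sequence, starts, 150)
  expect_equal(nrow(split_align(reads, p)), 0)
})

test_that("a constructed deletion-junction read reports exact breakpoints", {
  p <- the_panel()
  a <- 3100L; b <- 4600L
  read <- paste0(substring(p$locus_sequence, a - 75 + 1, a),
                 substring(p$locus_sequence, b + 1, b + 75))
  sp <- split_align(read, p)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$breakpoint_a, a)
  expect_equal(sp$breakpoint_b, b)
  expect_equal(sp$strand_a, "+")
  expect_equal(sp$strand_b, "+")
  # the reverse-complemented read canonicalises to the same breakpoints
  sp_rc <- split_align(revcomp(read), p)
  expect_equal(sp_rc$breakpoint_a, a)
  expect_equal(sp_rc$breakpoint_b, b)
  expect_equal(sp_rc$strand_a, "+")
})

test_that("event classification covers all orientation cases", {
  expect_equal(classify_event("+", "+", 100, 600, TRUE), "deletion")
  expect_equal(classify_event("+", "+", 600, 100, TRUE), "duplication")
  expect_equal(classify_event("+", "-", 100, 600, TRUE), "inversion")
  expect_equal(classify_event("-", "+", 100, 600, TRUE), "inversion")
  expect_equal(classify_event("+", "+", 100, 600, FALSE), "translocation")
})

test_that("identical splits merge into one event; distant ones stay apart", {
  p <- the_panel()
  one <- tibble::tibble(read_index = 1:12, split_pos = 75,
                        breakpoint_a = 3100L, breakpoint_b = 4600L,
                        strand_a = "+", strand_b = "+", matched = 150)
  ev <- cluster_events(one, p, tolerance = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_split_support, 12L)
  expect_equal(ev$type, "deletion")
  two <- dplyr::bind_rows(one, one |>
                            dplyr::mutate(breakpoint_a = 3600L,
                                          breakpoint_b = 5100L))
  ev2 <- cluster_events(two, p, tolerance = 10)
  expect_equal(nrow(ev2), 2)
  # small jitter within tolerance still merges
  jit <- one
  jit$breakpoint_a <- jit$breakpoint_a + rep(c(-3L, 0L, 3L), 4)
  expect_equal(nrow(cluster_events(jit, p, tolerance = 10)), 1)
})

test_that("vaf is split support over split plus reference-spanning reads", {
  p <- the_panel()
  ev <- tibble::tibble(breakpoint_a = 3100L, breakpoint_b = 4600L,
                       strand_a = "+", strand_b = "+", type = "deletion",
                       n_split_support = 10L)
  spanning <- tibble::tibble(start = rep(3000L, 90), end = rep(3200L, 90))
  out <- event_vaf(ev, spanning, min_segment = 25)
  expect_equal(out$vaf, 0.10)
  # no reference-spanning reads at all: a fully clonal event, vaf 1
  out0 <- event_vaf(ev, spanning[0, ], min_segment = 25)
  expect_equal(out0$vaf, 1.0)
  # spanning reads must overlap by min_segment on both sides to count
  shallow <- tibble::tibble(start = rep(3090L, 50), end = rep(3240L, 50))
  out1 <- event_vaf(ev, shallow, min_segment = 25)
  expect_equal(out1$vaf, 1.0)
})

test_that("simulated inversion junction reads are recovered within 5 bp", {
  p <- the_panel()
  ex <- p$exons
  a <- ex$start[ex$exon_id == "E4"] + 60L
  b <- a + 1400L
  ev <- tibble::tibble(breakpoint_a = a, breakpoint_b = b,
                       type = "inversion", vaf = 1.0)
  d <- simulate_dna_reads(p, dna_truth(gsr_events = ev, ar_copy_number = 2,
                                       depth = 400, error_rate = 0.002,
                                       seed = 61))
  jr <- d$reads[!d$reads$aligned &
                  d$reads$start <= a - 25 & d$reads$end >= a + 25, ]
  expect_gte(nrow(jr), 100)
  sp <- split_align(jr$sequence[1:100], p)
  expect_gte(nrow(sp), 95)
  expect_true(all(abs(sp$breakpoint_a - a) <= 5))
  expect_true(all(abs(sp$breakpoint_b - b) <= 5))
  expect_true(all(sp$strand_a != sp$strand_b))
})

test_that("a low-vaf event passes the support filter exactly once", {
  p <- the_panel()
  ex <- p$exons
  ev <- tibble::tibble(breakpoint_a = ex$start[ex$exon_id == "E2"] + 90L,
                       breakpoint_b = ex$start[ex$exon_id == "E2"] + 790L,
                       type = "deletion", vaf = 0.05)
  d <- simulate_dna_reads(p, dna_truth(gsr_events = ev, ar_copy_number = 2,
                                       depth = 2000, seed = 71))
  events <- call_rearrangements(d$reads, p, min_support = 10)
  expect_equal(nrow(events), 1)
  expect_equal(events$type, "deletion")
  expect_gte(events$n_split_support, 10)
})

test_that("detected support never decreases with simulated vaf", {
  p <- the_panel()
  ex <- p$exons
  a <- ex$start[ex$exon_id == "E3"] + 50L
  b <- a + 1800L
  support <- vapply(c(0.02, 0.05, 0.1, 0.5), function(v) {
    ev <- tibble::tibble(breakpoint_a = a, breakpoint_b = b,
                         type = "deletion", vaf = v)
    d <- simulate_dna_reads(p, dna_truth(gsr_events = ev, ar_copy_number = 2,
                                         depth = 1200,
                                         seed = round(1000 * v)))
    evs <- call_rearrangements(d$reads, p, min_support = 1)
    if (nrow(evs) == 0) 0L else max(evs$n_split_support)
  }, integer(1))
  expect_true(all(diff(support) >= 0))
})

test_that("translocations into the control region keep their AR breakpoint", {
  p <- the_panel()
  ex <- p$exons
  ctl <- p$control_targets
  ev <- tibble::tibble(breakpoint_a = ex$start[ex$exon_id == "E5"] + 30L,
                       breakpoint_b = ctl$start[2] + 300L,
                       type = "translocation", vaf = 0.3)
  d <- simulate_dna_reads(p, dna_truth(gsr_events = ev, ar_copy_number = 2,
                                       depth = 600, seed = 81))
  events <- call_rearrangements(d$reads, p, min_support = 10)
  expect_equal(nrow(events), 1)
  expect_equal(events$type, "translocation")
  expect_lte(abs(events$breakpoint_a - ev$breakpoint_a), 5)
  expect_lte(abs(events$breakpoint_b - ev$breakpoint_b), 5)
})

test_that("BEDPE export writes one line per event plus header", {
  p <- the_panel()
  ev <- tibble::tibble(breakpoint_a = 3100L, breakpoint_b = 4600L,
                       strand_a = "+", strand_b = "+", type = "deletion",
                       n_split_support = 15L, n_reference_spanning = 100L,
                       vaf = 0.13)
  path <- withr::local_tempfile(fileext = ".bedpe")
  export_events_bedpe(ev, p, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2)
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(f[2]), 3100L)
  expect_equal(f[7], "deletion")
})
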