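test_that("single-isoform and pure-FL limits behave exactly", {
  p <- the_panel()
  s <- the_signatures()
  # every junction-spanning read of a pure AR-V7 sample matches its signature
  r <- simulate_rna_reads(p, c("AR-V7" = 1.0), depth = 100, error_rate = 0,
                          seed = 5)
  expect_true(all(r$reads$isoform == "AR-V7"))
  cnt <- count_junctions(r$reads, s)
  v7 <- cnt$count[cnt$variant_name == "AR-V7"]
  others <- cnt$count[!cnt$variant_name %in% c("AR-V7", "AR-FL") |
                        cnt$upstream == "E3" & cnt$downstream == "E4"]
  expect_gt(v7, 0)
  expect_equal(cnt$count[cnt$upstream == "E3" & cnt$downstream == "E4"], 0L)
  expect_true(all(cnt$count[!cnt$variant_name %in% c("AR-FL", "AR-V7")] == 0L))
  # pure AR-FL: no read matches any variant signature
  r0 <- simulate_rna_reads(p, numeric(0), depth = 100, error_rate = 0,
                           seed = 6)
  cnt0 <- count_junctions(r0$reads, s)
  expect_true(all(cnt0$count[cnt0$variant_name != "AR-FL"] == 0L))
  expect_gt(sum(cnt0$count), 0)
})

test_that("realized variant share stays inside exact binomial bounds", {
  p <- the_panel()
  r <- simulate_rna_reads(p, c("AR-V7" = 0.10), depth = 2000, seed = 17)
  sp <- r$truth$junction_spanning
  v7 <- sp$n_spanning[sp$isoform == "AR-V7" & sp$downstream == "CE3"]
  fl <- sp$n_spanning[sp$isoform == "AR-FL" & sp$upstream == "E3"]
  n <- v7 + fl
  # exact central 99% interval for Binomial(n, 0.10)
  expect_gte(v7, qbinom(0.005, n, 0.10))
  expect_lte(v7, qbinom(0.995, n, 0.10))
})

test_that("fraction mass above 1 within an upstream group is rejected", {
  p <- the_panel()
  expect_error(
    simulate_rna_reads(p, c("AR-V7" = 0.6, "AR-V9" = 0.5), depth = 10),
    class = "arv_param_error")
  expect_error(
    simulate_rna_reads(p, c("NOT-A-VARIANT" = 0.1), depth = 10),
    class = "arv_param_error")
})

test_that("read simulation is deterministic and conserves read counts", {
  p <- the_panel()
  a <- simulate_rna_reads(p, c("AR-V7" = 0.05), depth = 300, seed = 11)
  b <- simulate_rna_reads(p, c("AR-V7" = 0.05), depth = 300, seed = 11)
  expect_identical(a$reads, b$reads)
  c <- simulate_rna_reads(p, c("AR-V7" = 0.05), depth = 300, seed = 12)
  expect_false(identical(a$reads$sequence, c$reads$sequence))
  # conservation: total reads == sum of per-isoform truth counts
  expect_equal(nrow(a$reads), sum(a$truth$isoforms$n_reads))

  da <- simulate_dna_reads(p, dna_truth(depth = 50, seed = 3))
  db <- simulate_dna_reads(p, dna_truth(depth = 50, seed = 3))
  expect_identical(da$reads, db$reads)
})

test_that("neutral DNA coverage ratio is about one and scales linearly", {
  p <- the_panel()
  d <- simulate_dna_reads(p, dna_truth(ar_copy_number = 2, depth = 150,
                                       seed = 21))
  ar_w <- window_counts(d$reads, p$dna_targets)
  ctl_w <- window_counts(d$reads, p$control_targets)
  ratio <- mean(ar_w$raw_count) / mean(ctl_w$raw_count)
  expect_lt(abs(ratio - 1), 0.1)
  # coverage linearity over five copy-number levels
  levels <- c(1, 2, 4, 8, 16)
  per_copy <- vapply(levels, function(cn) {
    d <- simulate_dna_reads(p, dna_truth(ar_copy_number = cn, depth = 150,
                                         seed = 100 + cn))
    mean(window_counts(d$reads, p$dna_targets)$raw_count) / cn
  }, numeric(1))
  expect_true(all(abs(per_copy / mean(per_copy) - 1) < 0.05))
})

test_that("a vaf-1 deletion leaves no intact reads across the breakpoint", {
  p <- the_panel()
  ex <- p$exons
  ev <- tibble::tibble(breakpoint_a = ex$start[ex$exon_id == "E5"] + 40L,
                       breakpoint_b = ex$start[ex$exon_id == "E7"] + 10L,
                       type = "deletion", vaf = 1.0)
  d <- simulate_dna_reads(p, dna_truth(gsr_events = ev, depth = 500,
                                       seed = 31))
  crossing <- d$reads$start < ev$breakpoint_a & d$reads$end > ev$breakpoint_a
  expect_true(all(!d$reads$aligned[crossing]))
  expect_gt(sum(crossing), 0)
  expect_equal(d$truth$events$n_junction_reads, sum(crossing))
})

test_that("hotspot alternate alleles follow the binomial at the stated vaf", {
  p <- the_panel()
  d <- simulate_dna_reads(p, dna_truth(hotspot_vafs = c(T878A = 0.25),
                                       depth = 400, seed = 41))
  hs <- d$truth$hotspots
  expect_gte(hs$n_alt, qbinom(0.005, hs$n_covering, 0.25))
  expect_lte(hs$n_alt, qbinom(0.995, hs$n_covering, 0.25))
})

test_that("breakpoints outside the locus are rejected", {
  p <- the_panel()
  ev <- tibble::tibble(breakpoint_a = 10L, breakpoint_b = 5000L,
                       type = "deletion", vaf = 0.5)
  expect_error(simulate_dna_reads(p, dna_truth(gsr_events = ev)),
               class = "arv_param_error")
})

test_that("generate_cohort is reproducible and honours group distributions", {
  p <- the_panel()
  spec <- cohort_spec(list(
    cohort_group("g1", 3, arv_fraction_range = c(0, 0.02),
                 rna_depth_range = c(100, 200), dna_depth = 40),
    cohort_group("CRPC", 3, arv_fraction_range = c(0.02, 0.12),
                 rna_depth_range = c(100, 200), dna_depth = 40)),
    seed = 7)
  coh <- generate_cohort(p, spec, assays = c("rna", "expression"))
  expect_length(coh$samples, 6)
  expect_equal(nrow(coh$truth), 6)
  # same spec + seed -> identical truth; also identical read sets
  coh2 <- generate_cohort(p, spec, assays = c("rna", "expression"))
  expect_identical(coh$truth, coh2$truth)
  expect_identical(coh$samples[[1]]$rna$reads, coh2$samples[[1]]$rna$reads)
  # stated uniform support respected
  crpc <- coh$truth[coh$truth$group == "CRPC", ]
  for (col in c("arv3_true", "arv7_true", "arv9_true")) {
    expect_true(all(crpc[[col]] >= 0.02 & crpc[[col]] <= 0.12))
  }
  # cohort directory layout + truth TSV
  dir <- withr::local_tempdir()
  generate_cohort(p, spec, dir = dir, assays = "rna")
  expect_length(list.dirs(dir, recursive = FALSE), 6)
  tt <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tt), 6)
  # FASTQ round trip
  fq <- read_fastq(file.path(dir, "g1_01", "rna.fastq"))
  expect_equal(fq$sequence, coh$samples[["g1_01"]]$rna$reads$sequence)
})
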