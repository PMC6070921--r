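test_that("signatures are 130+130 flanks, truncated by short exons", {
  p <- the_panel()
  s <- the_signatures()
  # all mock exons are >= 130 bp: full-length signatures
  expect_true(all(s$width == 260))
  expect_true(all(s$junction_offset == 130))
  # every signature substring-matches its exon concatenation at the boundary
  ex <- p$exons
  for (i in seq_len(nrow(s))) {
    up <- ex$sequence[ex$exon_id == s$upstream[i]]
    down <- ex$sequence[ex$exon_id == s$downstream[i]]
    expect_identical(
      s$sequence[i],
      paste0(substring(up, nchar(up) - 129, nchar(up)),
             substring(down, 1, 130)))
  }
  # short upstream exon truncates the upstream flank
  tp <- tiny_panel(up_len = 40)
  ts <- build_signatures(tp)
  expect_equal(ts$width, 40 + 130)
  expect_equal(ts$junction_offset, 40)
})

test_that("duplicate signature sequences raise an error naming the junctions", {
  p0 <- tiny_panel(up_len = 200, down_len = 200)
  # second downstream exon with an identical 5' flank
  locus <- p0$locus_sequence
  e2 <- p0$exons[p0$exons$exon_id == "E2", ]
  dup_start <- e2$end + 100
  locus2 <- paste0(substring(locus, 1, dup_start),
                   substring(locus, e2$start + 1, e2$end),
                   substring(locus, dup_start + (e2$end - e2$start) + 1))
  exons <- dplyr::bind_rows(
    p0$exons[, c("exon_id", "start", "end")],
    tibble::tibble(exon_id = "CE1", start = dup_start,
                   end = dup_start + (e2$end - e2$start)))
  junctions <- tibble::tibble(variant_name = c("AR-FL", "AR-V7"),
                              upstream = "E1", downstream = c("E2", "CE1"))
  pp <- panel_config(locus_sequence = locus2, exons = exons,
                     junctions = junctions, dna_targets = p0$dna_targets,
                     control_targets = p0$control_targets,
                     rna_genes = p0$rna_genes, hotspots = p0$hotspots)
  expect_error(build_signatures(pp), regexp = "AR-V7",
               class = "arv_panel_error")
})

test_that("assign_read follows the overhang, mismatch and tie rules", {
  p <- the_panel()
  s <- the_signatures()
  v7 <- s[s$variant_name == "AR-V7", ]
  # exact central 150 bp (75 per side) -> that junction
  centre <- substring(v7$sequence, 56, 205)
  expect_equal(assign_read(centre, s), "E3->CE3")
  # reverse complement assigns identically
  expect_equal(assign_read(revcomp(centre), s), "E3->CE3")
  # read lying entirely within one exon -> unassigned
  e3 <- p$exons$sequence[p$exons$exon_id == "E3"]
  expect_true(is.na(assign_read(substring(e3, 11, 160), s)))
  # two substitutions within budget still assign
  mutated <- centre
  substr(mutated, 20, 20) <- if (substring(mutated, 20, 20) == "A") "C" else "A"
  substr(mutated, 90, 90) <- if (substring(mutated, 90, 90) == "G") "T" else "G"
  expect_equal(assign_read(mutated, s, min_overhang = 10,
                           max_mismatches = 3), "E3->CE3")
  # four substitutions exceed the default budget
  worse <- mutated
  substr(worse, 120, 120) <- if (substring(worse, 120, 120) == "A") "C" else "A"
  substr(worse, 140, 140) <- if (substring(worse, 140, 140) == "A") "C" else "A"
  expect_true(is.na(assign_read(worse, s, max_mismatches = 3)))
  # insufficient overhang: 55 + 5 bases around the boundary of a short read
  short <- substring(v7$sequence, 76, 135)  # 60 bp: 55 upstream, 5 downstream
  expect_true(is.na(assign_read(short, s, min_overhang = 10)))
  expect_equal(assign_read(short, s, min_overhang = 5), "E3->CE3")
})

test_that("ambiguous ties across signatures are discarded", {
  # two downstream exons sharing their first 30 bases force a tie for reads
  # with a short downstream overhang
  base <- tiny_panel(up_len = 200, down_len = 200)
  locus <- base$locus_sequence
  e2 <- base$exons[base$exons$exon_id == "E2", ]
  shared <- substring(locus, e2$start + 1, e2$start + 30)
  ce_start <- e2$end + 100
  locus2 <- paste0(substring(locus, 1, ce_start), shared,
                   arvprofiler:::lcg_sequence(170, seed = 4242),
                   substring(locus, ce_start + 201))
  exons <- dplyr::bind_rows(
    base$exons[, c("exon_id", "start", "end")],
    tibble::tibble(exon_id = "CE1", start = ce_start, end = ce_start + 200))
  pp <- panel_config(locus_sequence = locus2, exons = exons,
                     junctions = tibble::tibble(
                       variant_name = c("AR-FL", "AR-V1"),
                       upstream = "E1", downstream = c("E2", "CE1")),
                     dna_targets = base$dna_targets,
                     control_targets = base$control_targets,
                     rna_genes = base$rna_genes, hotspots = base$hotspots)
  ss <- build_signatures(pp)
  fl <- ss[ss$variant_name == "AR-FL", ]
  # 120 upstream + 25 downstream bases: downstream part identical in both
  amb <- substring(fl$sequence, 11, 155)
  expect_true(is.na(assign_read(amb, ss, min_overhang = 10)))
  # 40 downstream bases disambiguate
  clear <- substring(fl$sequence, 26, 170)
  expect_equal(assign_read(clear, ss), "E1->E2")
})

test_that("count_junctions equals the brute-force Hamming oracle", {
  p <- the_panel()
  s <- the_signatures()
  r <- simulate_rna_reads(p, c("AR-V7" = 0.08, "AR-V3" = 0.04), depth = 400,
                          seed = 77)
  impl <- arvprofiler:::cpp_assign_reads(
    r$reads$sequence, s$sequence, s$junction_offset, 10L, 3L)
  oracle <- arvprofiler:::cpp_assign_reads_oracle(
    r$reads$sequence, s$sequence, s$junction_offset, 10L, 3L)
  expect_identical(impl, oracle)
  # counts derive from the per-read assignments
  cnt <- count_junctions(r$reads, s)
  expect_equal(cnt$count, as.integer(tabulate(oracle[oracle > 0], nrow(s))))
  expect_equal(attr(cnt, "n_reads"), nrow(r$reads))
  expect_equal(attr(cnt, "n_unassigned"), sum(oracle <= 0))
})

test_that("empty and degenerate read sets give all-zero counts", {
  s <- the_signatures()
  cnt <- count_junctions(character(0), s)
  expect_true(all(cnt$count == 0L))
  expect_equal(attr(cnt, "n_reads"), 0)
  one <- substring(s$sequence[1], 56, 205)
  cnt1 <- count_junctions(rep(one, 100), s)
  expect_equal(cnt1$count[1], 100L)
  expect_true(all(cnt1$count[-1] == 0L))
})

test_that("fractions follow the shared-upstream-denominator formula", {
  p <- the_panel()
  s <- the_signatures()
  counts <- s |> dplyr::select("variant_name", "upstream", "downstream")
  counts$count <- 0L
  counts$count[counts$upstream == "E3" & counts$downstream == "E4"] <- 90L
  counts$count[counts$variant_name == "AR-V7"] <- 10L
  fr <- quantify_fractions(counts, p)
  v7 <- fr[fr$variant_name == "AR-V7", ]
  expect_equal(v7$numerator, 10L)
  expect_equal(v7$denominator, 100L)
  expect_equal(v7$fraction, 0.10)
  # zero numerator -> fraction 0 with lower bound 0
  v9 <- fr[fr$variant_name == "AR-V9", ]
  expect_equal(v9$fraction, 0)
  expect_equal(v9$ci95_lower, 0)
  # empty groups are not quantifiable
  e1 <- fr[fr$upstream == "E1", ]
  expect_true(is.na(e1$fraction))
  # quantifiable groups sum to one
  sums <- fr |>
    dplyr::filter(denominator > 0) |>
    dplyr::group_by(upstream) |>
    dplyr::summarise(s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("the exact lower bound matches a bisection oracle on pbinom", {
  # oracle: smallest p with Pr(Bin(n, p) >= x) >= 0.025
  cp_oracle <- function(x, n) {
    if (x == 0) return(0)
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (1 - pbinom(x - 1, n, mid) >= 0.025) hi <- mid else lo <- mid
    }
    hi
  }
  cases <- list(c(10, 100), c(1, 10), c(3, 30), c(250, 1000), c(5, 5))
  for (cs in cases) {
    expect_equal(ci95_lower(cs[1], cs[2]), cp_oracle(cs[1], cs[2]),
                 tolerance = 1e-9)
  }
  expect_equal(round(ci95_lower(10, 100), 3), 0.049)
  # lower bound below the point estimate, converging as n grows
  ns <- c(100, 1000, 10000)
  gaps <- vapply(ns, function(n) 0.3 - ci95_lower(0.3 * n, n), numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) < 0))
})

test_that("total variant fraction sums point estimates, NA when unquantifiable", {
  p <- the_panel()
  s <- the_signatures()
  counts <- s |> dplyr::select("variant_name", "upstream", "downstream")
  counts$count <- 1000L
  counts$count[counts$variant_name == "AR-V3"] <- 20L  # /3020 group E2
  fr <- quantify_fractions(counts, p)
  expect_equal(total_arv_fraction(fr),
               sum(fr$fraction[fr$variant_name %in%
                                 c("AR-V3", "AR-V7", "AR-V9")]))
  counts0 <- counts
  counts0$count <- 0L
  fr0 <- quantify_fractions(counts0, p)
  expect_true(is.na(total_arv_fraction(fr0)))
})

test_that("signature FASTA export round-trips", {
  s <- the_signatures()
  path <- withr::local_tempfile(fileext = ".fa")
  export_signatures_fasta(s, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2 * nrow(s))
  expect_identical(lines[seq(2, length(lines), 2)], s$sequence)
})
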