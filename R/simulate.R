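# Run code with a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-sample seed from a master seed
#'
#' Stable string hash of the sample id folded into the master seed, kept
#' below 2^31 so it is a valid R integer seed.
#'
#' @param master Master integer seed.
#' @param sample_id Sample identifier string.
#' @return Integer seed.
#' @export
derive_seed <- function(master, sample_id) {
  h <- 0
  for (c in utf8ToInt(as.character(sample_id))) h <- (h * 31 + c) %% 2147483647
  as.integer((h + as.double(master) * 7919) %% 2147483647)
}

param_error <- function(msg) abort(msg, class = "arv_param_error")

# Vectorised substitution-only error model: k_i ~ Binomial(len_i, rate) errors
# per read, positions uniform, substituted base drawn from the other three.
mutate_bases <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs)
  k <- stats::rbinom(length(seqs), len, error_rate)
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(max(k, 0))) {
    idx <- which(k >= j)
    if (length(idx) == 0) break
    pos <- floor(stats::runif(length(idx)) * len[idx]) + 1L
    cur <- substr(seqs[idx], pos, pos)
    off <- sample.int(3, length(idx), replace = TRUE)
    new <- bases[((match(cur, bases) - 1L + off) %% 4L) + 1L]
    substr(seqs[idx], pos, pos) <- new
  }
  seqs
}

#' Simulate targeted RNA reads from an isoform mixture
#'
#' Reads are drawn from transcript sequences assembled from the exon catalog.
#' `fractions` gives each splice variant's share of the junction reads within
#' its upstream-exon group; the remainder of each group is full-length
#' transcript. `depth` is the expected number of junction-spanning reads at a
#' junction carried only by the full-length transcript; shared junctions
#' receive proportionally more. Read starts are uniform over each transcript,
#' strands random, substitution errors independent per base.
#'
#' @param panel A [panel_config].
#' @param fractions Named numeric vector, e.g. `c("AR-V7" = 0.1)`. Empty
#'   means pure full-length transcript.
#' @param depth Expected junction-spanning reads (full-length baseline).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability (< 0.1).
#' @param seed Integer seed; identical inputs give identical read sets.
#' @return List with `reads` (tibble: `read_id`, `isoform`, `start`, `strand`,
#'   `sequence`) and `truth` (realised per-isoform read counts and exact
#'   junction-spanning counts).
#' @export
simulate_rna_reads <- function(panel, fractions = numeric(0), depth = 1000,
                               read_length = 150, error_rate = 0.002,
                               seed = 1) {
  if (error_rate < 0 || error_rate >= 0.1)
    param_error("error_rate must be in [0, 0.1)")
  if (depth <= 0) param_error("depth must be positive")
  fractions <- fractions[fractions > 0]
  variants <- names(fractions)
  catalog_variants <- setdiff(unique(panel$junctions$variant_name), "AR-FL")
  unknown <- setdiff(variants, catalog_variants)
  if (length(unknown) > 0)
    param_error(paste("variants not in junction catalog:",
                      paste(unknown, collapse = ", ")))
  # fraction mass per upstream-exon group must leave room for AR-FL
  jn <- panel$junctions
  up_of <- jn$upstream[match(variants, jn$variant_name)]
  group_mass <- tapply(as.numeric(fractions), up_of, sum)
  if (length(group_mass) > 0 && any(group_mass > 1))
    param_error("variant fractions within an upstream-exon group exceed 1")

  isoforms <- c("AR-FL", variants)
  if (length(group_mass) > 0 && max(group_mass) >= 1) {
    # a saturated upstream-exon group leaves no room for the full-length
    # transcript (single-isoform limit): drop AR-FL entirely
    theta <- c(`AR-FL` = 0)
    for (v in variants) theta[v] <- fractions[[v]]
  } else {
    theta <- c(`AR-FL` = 1)
    for (v in variants) {
      s_u <- group_mass[[up_of[match(v, variants)]]]
      theta[v] <- fractions[[v]] / (1 - s_u)
    }
  }

  with_seed(seed, {
    all_reads <- list()
    truth_iso <- list()
    truth_jn <- list()
    for (iso in isoforms) {
      tx <- transcript_sequence(panel, iso)
      L <- nchar(tx$sequence)
      if (L < read_length)
        param_error(sprintf("transcript %s shorter than read length", iso))
      n_exp <- depth * theta[[iso]] * (L - read_length + 1) / (read_length - 1)
      n <- stats::rpois(1, n_exp)
      start <- if (n > 0) sample.int(L - read_length + 1, n, replace = TRUE) - 1L
               else integer(0)
      strand <- if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character(0)
      seqs <- if (n > 0) substring(tx$sequence, start + 1L,
                                   start + read_length) else character(0)
      seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
      all_reads[[iso]] <- tibble(
        read_id = sprintf("rna|%s|%d", iso, seq_len(n)),
        isoform = iso, start = start, strand = strand, sequence = seqs)
      truth_iso[[iso]] <- tibble(isoform = iso, abundance = theta[[iso]],
                                 n_reads = n)
      spans <- vapply(tx$junctions$pos, function(p)
        sum(start > p - read_length & start < p), integer(1))
      truth_jn[[iso]] <- tx$junctions |>
        mutate(isoform = iso, n_spanning = spans) |>
        select("isoform", "upstream", "downstream", "n_spanning")
    }
    reads <- bind_rows(all_reads)
    reads$sequence <- mutate_bases(reads$sequence, error_rate)
    list(reads = reads,
         truth = list(isoforms = bind_rows(truth_iso),
                      junction_spanning = bind_rows(truth_jn),
                      fractions = fractions, depth = depth,
                      read_length = read_length, error_rate = error_rate,
                      seed = seed))
  })
}

#' Specify the DNA-level truth of one simulated sample
#'
#' @param ar_copy_number True AR copies (1 = unaltered male X).
#' @param control_copy_number Copies of the autosomal control genes.
#' @param gsr_events Tibble of engineered rearrangements (`breakpoint_a`,
#'   `breakpoint_b`, `type` in deletion/duplication/inversion/translocation,
#'   `vaf`), or `NULL`.
#' @param hotspot_vafs Named vector of hotspot variant allele fractions.
#' @param depth Mean coverage of the control targets (diploid-equivalent);
#'   a region with `c` copies is covered at `depth * c / control_copy_number`.
#' @param read_length,fragment_mean,fragment_sd,error_rate Read model.
#' @param seed Integer seed.
#' @return A `dna_truth` list.
#' @export
dna_truth <- function(ar_copy_number = 1, control_copy_number = 2,
                      gsr_events = NULL, hotspot_vafs = NULL, depth = 200,
                      read_length = 150, fragment_mean = 180,
                      fragment_sd = 30, error_rate = 0.002, seed = 1) {
  if (ar_copy_number <= 0 || control_copy_number <= 0)
    param_error("copy numbers must be positive")
  if (!is.null(gsr_events)) {
    gsr_events <- as_tibble(gsr_events)
    if (any(gsr_events$vaf < 0 | gsr_events$vaf > 1))
      param_error("event vaf must be in [0, 1]")
    ok <- gsr_events$type %in% c("deletion", "duplication", "inversion",
                                 "translocation")
    if (!all(ok)) param_error("unknown rearrangement type")
  }
  if (!is.null(hotspot_vafs) &&
      any(hotspot_vafs < 0 | hotspot_vafs > 1))
    param_error("hotspot vaf must be in [0, 1]")
  structure(list(ar_copy_number = ar_copy_number,
                 control_copy_number = control_copy_number,
                 gsr_events = gsr_events, hotspot_vafs = hotspot_vafs,
                 depth = depth, read_length = read_length,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 error_rate = error_rate, seed = seed),
            class = "dna_truth")
}

#' Simulate targeted paired-end DNA reads
#'
#' Fragments are laid over the capture targets at a rate proportional to the
#' region's copy number, with truncated-normal lengths and FR read pairs.
#' For each engineered rearrangement, the stated fraction of fragments
#' overlapping `breakpoint_a` derives from the rearranged allele: reads
#' crossing the breakpoint carry the junction of the two loci with the
#' orientation implied by the event type. Hotspot alternate alleles are
#' emitted at their stated fraction among covering reads.
#'
#' @param panel A [panel_config].
#' @param truth A [dna_truth()].
#' @return List with `reads` (tibble: `read_id`, `mate`, `start`, `end`,
#'   `strand`, `aligned`, `event`, `sequence`; `start`/`end` are the
#'   reference-aligned interval, `aligned = FALSE` marks breakpoint-junction
#'   reads) and `truth` (realised junction-read and allele counts).
#' @export
simulate_dna_reads <- function(panel, truth = dna_truth()) {
  locus <- panel$locus_sequence
  locus_len <- nchar(locus)
  R <- truth$read_length
  ev <- truth$gsr_events
  if (!is.null(ev)) {
    if (any(ev$breakpoint_a < R | ev$breakpoint_a > locus_len - R |
            ev$breakpoint_b < R | ev$breakpoint_b > locus_len - R))
      param_error("breakpoints must lie at least one read length inside the locus")
  }
  regions <- bind_rows(
    panel$dna_targets |> mutate(copies = truth$ar_copy_number),
    panel$control_targets |> mutate(copies = truth$control_copy_number))

  with_seed(truth$seed, {
    # capture-style placement: any fragment overlapping the target by >= 1 bp
    # is retained, so read-start density is uniform across target interiors
    frags <- list()
    for (i in seq_len(nrow(regions))) {
      len <- regions$end[i] - regions$start[i]
      cov <- truth$depth * regions$copies[i] / truth$control_copy_number
      n <- stats::rpois(1, cov * (len + truth$fragment_mean) / (2 * R))
      if (n == 0) next
      fl <- pmax(R, round(stats::rnorm(n, truth$fragment_mean,
                                       truth$fragment_sd)))
      fs <- regions$start[i] - fl + 1L +
        floor(stats::runif(n) * (len + fl - 1))
      fs <- pmax(0L, pmin(as.integer(fs), locus_len - fl))
      frags[[i]] <- tibble(region = regions$region[i], fs = as.integer(fs),
                           fe = as.integer(fs + fl))
    }
    frags <- bind_rows(frags)
    if (nrow(frags) == 0)
      return(list(reads = tibble(read_id = character(), mate = integer(),
                                 start = integer(), end = integer(),
                                 strand = character(), aligned = logical(),
                                 event = integer(), sequence = character()),
                  truth = list(n_fragments = 0L, fragments_per_region = NULL,
                               events = NULL, hotspots = NULL,
                               params = truth)))
    nf <- nrow(frags)
    frags$frag_id <- seq_len(nf)

    # mark rearranged fragments per event
    frags$event <- NA_integer_
    realized_events <- NULL
    if (!is.null(ev) && nrow(ev) > 0) {
      for (e in seq_len(nrow(ev))) {
        ov <- which(frags$fs < ev$breakpoint_a[e] & frags$fe > ev$breakpoint_a[e] &
                    is.na(frags$event))
        hit <- ov[stats::runif(length(ov)) < ev$vaf[e]]
        frags$event[hit] <- e
      }
    }

    reads <- bind_rows(
      frags |> mutate(mate = 1L, start = .data$fs, strand = "+"),
      frags |> mutate(mate = 2L, start = .data$fe - R, strand = "-")) |>
      mutate(end = .data$start + R) |>
      arrange(.data$frag_id, .data$mate)
    # reference-oriented sequence
    seqs <- substring(locus, reads$start + 1L, reads$end)
    aligned <- rep(TRUE, nrow(reads))

    # rewrite junction-crossing reads of rearranged fragments
    if (!is.null(ev) && nrow(ev) > 0) {
      for (e in seq_len(nrow(ev))) {
        bpa <- ev$breakpoint_a[e]; bpb <- ev$breakpoint_b[e]
        idx <- which(!is.na(reads$event) & reads$event == e &
                     reads$start < bpa & reads$end > bpa)
        if (length(idx) == 0) next
        pre_len <- bpa - reads$start[idx]
        need <- R - pre_len
        prefix <- substring(locus, reads$start[idx] + 1L, bpa)
        suffix <- if (ev$type[e] == "inversion") {
          revcomp(substring(locus, bpb - need + 1L, bpb))
        } else {
          substring(locus, bpb + 1L, bpb + need)
        }
        seqs[idx] <- paste0(prefix, suffix)
        aligned[idx] <- FALSE
      }
      realized_events <- ev |>
        mutate(n_junction_reads = vapply(seq_len(nrow(ev)), function(e)
          sum(!is.na(reads$event) & reads$event == e &
              reads$start < ev$breakpoint_a[e] &
              reads$end > ev$breakpoint_a[e]), integer(1)))
    }
    reads$event[aligned] <- NA_integer_

    # hotspot alternate alleles among contiguous covering reads
    realized_hotspots <- NULL
    hv <- truth$hotspot_vafs
    if (!is.null(hv) && length(hv) > 0) {
      hs <- panel$hotspots |> filter(.data$name %in% names(hv))
      bad <- setdiff(names(hv), hs$name)
      if (length(bad) > 0)
        param_error(paste("unknown hotspot:", paste(bad, collapse = ", ")))
      rh <- list()
      for (i in seq_len(nrow(hs))) {
        pos <- hs$position[i]
        cov_idx <- which(aligned & reads$start <= pos & reads$end > pos)
        sel <- cov_idx[stats::runif(length(cov_idx)) < hv[[hs$name[i]]]]
        at <- pos - reads$start[sel] + 1L
        substr(seqs[sel], at, at) <- hs$alt[i]
        rh[[i]] <- tibble(name = hs$name[i], vaf = hv[[hs$name[i]]],
                          n_covering = length(cov_idx), n_alt = length(sel))
      }
      realized_hotspots <- bind_rows(rh)
    }

    seqs[reads$strand == "-"] <- revcomp(seqs[reads$strand == "-"])
    seqs <- mutate_bases(seqs, truth$error_rate)
    reads$sequence <- seqs
    reads$aligned <- aligned
    reads$read_id <- sprintf("dna|%d/%d", reads$frag_id, reads$mate)
    reads <- reads |>
      select("read_id", "mate", "start", "end", "strand", "aligned",
             "event", "sequence")
    list(reads = reads,
         truth = list(n_fragments = nf,
                      fragments_per_region = frags |> count(.data$region),
                      events = realized_events,
                      hotspots = realized_hotspots,
                      params = truth))
  })
}
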