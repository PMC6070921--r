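#' Count read starts in overlapping windows
#'
#' Tiles each target with fixed-width windows at the given step (windows that
#' would extend past the target end are dropped) and counts the reads whose
#' alignment start falls inside each window.
#'
#' @param reads Tibble with a `start` column (alignment starts), or a numeric
#'   vector of starts.
#' @param targets Tibble with `region`, `start`, `end`.
#' @param window Window width in bp.
#' @param step Step between window starts in bp; must not exceed `window`
#'   (windows are required to overlap or abut).
#' @return Tibble of `CoverageWindow`s: `region`, `win_start`, `win_end`,
#'   `raw_count`.
#' @export
window_counts <- function(reads, targets, window = 400, step = 200) {
  if (step > window)
    param_error("step must not exceed window (windows would not overlap)")
  if (nrow(targets) == 0) param_error("targets must be non-empty")
  starts <- if (is.data.frame(reads)) reads$start else as.numeric(reads)
  out <- list()
  for (i in seq_len(nrow(targets))) {
    lo <- targets$start[i]; hi <- targets$end[i]
    if (hi - lo < window) next
    ws <- seq(lo, hi - window, by = step)
    cnt <- vapply(ws, function(w) sum(starts >= w & starts < w + window),
                  numeric(1))
    out[[i]] <- tibble(region = targets$region[i], win_start = as.integer(ws),
                       win_end = as.integer(ws + window),
                       raw_count = as.integer(cnt))
  }
  bind_rows(out)
}

cn_label <- function(cn) {
  ifelse(cn > 2, "amplification", ifelse(cn > 1, "gain", "neutral"))
}

#' Estimate copy number from AR and control window counts
#'
#' Window counts are scaled by the sample's total on-target reads, each AR
#' window is divided by the median scaled control-window count, and the
#' median of these AR ratios — rescaled by the control ploidy so that an
#' unaltered male X-linked gene reports 1 — is the copy-number estimate.
#' Labels follow the gain (> 1 copy) and amplification (> 2 copies) rules.
#'
#' @param ar_windows,control_windows Window tibbles from [window_counts()].
#' @param control_ploidy Copy number of the control genes in an unaltered
#'   genome (2 for autosomes).
#' @return One-row tibble: `cn_estimate`, `label`, `n_ar_windows`,
#'   `n_control_windows`.
#' @export
normalize_and_estimate <- function(ar_windows, control_windows,
                                   control_ploidy = 2) {
  if (nrow(ar_windows) == 0 || nrow(control_windows) == 0)
    param_error("need at least one AR window and one control window")
  total <- sum(ar_windows$raw_count) + sum(control_windows$raw_count)
  if (total == 0 || stats::median(control_windows$raw_count) == 0)
    abort("control coverage is zero; cannot estimate copy number",
          class = "arv_estimation_error")
  ar_scaled <- ar_windows$raw_count / total
  ctl_scaled <- control_windows$raw_count / total
  ratios <- ar_scaled / stats::median(ctl_scaled)
  cn <- stats::median(ratios) * control_ploidy
  tibble(cn_estimate = cn, label = cn_label(cn),
         n_ar_windows = nrow(ar_windows),
         n_control_windows = nrow(control_windows))
}

#' Call AR copy number from a DNA read set
#'
#' Convenience wrapper: windowed counts over the AR and control targets,
#' then [normalize_and_estimate()].
#'
#' @param reads DNA read tibble (uses contiguously aligned reads only).
#' @param panel A [panel_config].
#' @param window,step Window tiling parameters.
#' @return One-row tibble as from [normalize_and_estimate()], with the
#'   window table attached as attribute `windows`.
#' @export
call_copy_number <- function(reads, panel, window = 400, step = 200) {
  if ("aligned" %in% names(reads)) reads <- reads |> filter(.data$aligned)
  ar_w <- window_counts(reads, panel$dna_targets, window, step)
  ctl_w <- window_counts(reads, panel$control_targets, window, step)
  out <- normalize_and_estimate(ar_w, ctl_w,
                                control_ploidy = panel$ploidy$control)
  attr(out, "windows") <- bind_rows(ar_w |> mutate(set = "AR"),
                                    ctl_w |> mutate(set = "control"))
  out
}
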