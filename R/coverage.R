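#' Normalise a depth track by its chromosome-wide total
#'
#' Divides the depth at every position by the summed depth over all positions
#' of the chromosome in that sample, so tracks from libraries sequenced to
#' different depths become comparable: the result is a per-position fraction
#' summing to 1 (within 1e-9) and is invariant to rescaling the raw depths.
#'
#' @param track Depth tibble (`chrom`, `pos`, `depth`) from
#'   [read_depth_track()].
#' @return A tibble with columns `chrom`, `pos`, `value` (fractions).
#' @export
normalize_track <- function(track) {
  if (nrow(track) == 0L || sum(track$depth) <= 0) {
    abort_validation("cannot normalize a track with zero total depth")
  }
  tibble(chrom = track$chrom, pos = track$pos,
         value = track$depth / sum(track$depth))
}

#' Build a control-pool median reference track
#'
#' Per-position median of normalised control tracks, at positions present in
#' every control. Positions where the median is 0 are flagged (`masked`): no
#' meaningful ratio can be formed there without a pseudocount. Controls
#' should come from samples with a wild-type copy of the analysed chromosome,
#' processed with the same capture chemistry as the case.
#'
#' @param controls List of normalised tracks ([normalize_track()] output).
#' @param min_controls Minimum pool size (default 3).
#' @return A tibble with columns `chrom`, `pos`, `value`, `masked`.
#' @export
build_reference <- function(controls, min_controls = 3) {
  if (length(controls) < min_controls) {
    abort_validation(sprintf("need at least %d control tracks, got %d",
                             min_controls, length(controls)))
  }
  shared <- Reduce(intersect, map(controls, "pos"))
  if (length(shared) == 0L) abort_validation("controls share no positions")
  shared <- sort(shared)
  vals <- vapply(controls, function(tr) tr$value[match(shared, tr$pos)],
                 numeric(length(shared)))
  med <- apply(as.matrix(vals), 1, median)
  tibble(chrom = controls[[1]]$chrom[1], pos = shared,
         value = med, masked = med == 0)
}

#' Per-position log2 ratio of case over reference coverage
#'
#' `log2((case + pseudocount) / (reference + pseudocount))` at positions
#' present in both tracks. With the default `pseudocount = 0`, positions
#' where either track is 0 are masked (`log2_ratio = NA`) rather than mapped
#' to infinities; a positive pseudocount keeps every shared position but
#' shrinks large ratios, so it should stay well below the typical normalised
#' per-position value.
#'
#' @param case Normalised case track.
#' @param reference Reference track from [build_reference()] (or any
#'   normalised track).
#' @param pseudocount Non-negative value added to both numerator and
#'   denominator (default 0).
#' @return A `ratio_track` tibble with columns `chrom`, `pos`, `log2_ratio`,
#'   `masked`.
#' @export
log2_ratio_track <- function(case, reference, pseudocount = 0) {
  if (pseudocount < 0) abort_validation("pseudocount must be >= 0")
  shared <- intersect(case$pos, reference$pos)
  if (length(shared) == 0L) {
    abort_validation("case and reference share no positions")
  }
  shared <- sort(shared)
  cv <- case$value[match(shared, case$pos)]
  rv <- reference$value[match(shared, reference$pos)]
  if (pseudocount == 0) {
    masked <- rv == 0 | cv == 0
    ratio <- ifelse(masked, NA_real_, log2(cv / rv))
  } else {
    masked <- rep(FALSE, length(shared))
    ratio <- log2((cv + pseudocount) / (rv + pseudocount))
  }
  structure(
    tibble(chrom = case$chrom[1], pos = shared, log2_ratio = ratio, masked = masked),
    class = c("ratio_track", class(tibble()))
  )
}

#' Call focal copy-number events from a log2 ratio track
#'
#' Restricts the ratio track to targeted positions, median-smooths it, and
#' reports maximal runs of consistent-sign positions whose smoothed absolute
#' ratio reaches `threshold`. Runs of the same sign separated by at most
#' `merge_gap` targeted positions are merged; runs covering fewer than
#' `min_positions` positions are discarded. Call boundaries always lie on
#' observed targeted positions and calls never extend outside targets.
#'
#' Smoothing operates over the ordered targeted positions (index space), the
#' natural neighbourhood for sparse exome coverage. The default threshold of
#' 0.4 sits between 0 and log2(1.5) ~ 0.585, the expectation for a
#' heterozygous duplication in a fully clonal sample.
#'
#' @param ratio A `ratio_track` from [log2_ratio_track()].
#' @param targets Target tibble (`target_id`, `chrom`, `start`, `end`;
#'   0-based half-open), e.g. from [read_targets()].
#' @param threshold Minimum absolute smoothed log2 ratio (default 0.4).
#' @param min_positions Minimum targeted positions per call (default 100).
#' @param merge_gap Maximum below-threshold gap, in targeted positions,
#'   bridged between same-sign runs (default 50).
#' @param smooth_window Running-median window, odd (default 51); shrunk when
#'   fewer positions are available.
#' @return A tibble of calls: `chrom`, `start`, `end` (0-based half-open,
#'   spanning observed positions), `direction` (`gain`/`loss`), `mean_log2`
#'   (unsmoothed mean over the call), `n_positions`, `targets_hit`
#'   (list-column of target ids).
#' @export
call_focal_events <- function(ratio, targets, threshold = 0.4,
                              min_positions = 100, merge_gap = 50,
                              smooth_window = 51) {
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  direction = character(), mean_log2 = double(),
                  n_positions = integer(), targets_hit = list())
  keep <- !ratio$masked & !is.na(ratio$log2_ratio)
  rt <- ratio[keep, ]
  if (nrow(rt) == 0L) return(empty)
  tg <- targets[targets$chrom == rt$chrom[1], ]
  if (nrow(tg) == 0L) return(empty)
  target_of <- position_target(rt$pos, tg)
  rt <- rt[!is.na(target_of), ]
  target_of <- target_of[!is.na(target_of)]
  if (nrow(rt) == 0L) return(empty)

  k <- min(smooth_window, nrow(rt))
  if (k %% 2L == 0L) k <- k - 1L
  smoothed <- if (k >= 3) as.numeric(stats::runmed(rt$log2_ratio, k)) else rt$log2_ratio

  state <- ifelse(smoothed >= threshold, 1L, ifelse(smoothed <= -threshold, -1L, 0L))
  runs <- run_bounds(state)
  runs <- runs[runs$value != 0L, ]
  if (nrow(runs) == 0L) return(empty)

  # merge same-sign runs separated by few targeted positions
  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      gap <- runs$from[i] - merged$to[last] - 1L
      if (runs$value[i] == merged$value[last] && gap <= merge_gap) {
        merged$to[last] <- runs$to[i]
      } else {
        merged <- bind_rows(merged, runs[i, ])
      }
    }
  }
  merged <- merged[(merged$to - merged$from + 1L) >= min_positions, ]
  if (nrow(merged) == 0L) return(empty)

  bind_rows(map(seq_len(nrow(merged)), function(i) {
    idx <- merged$from[i]:merged$to[i]
    tibble(chrom = rt$chrom[1],
           start = min(rt$pos[idx]) - 1,
           end = max(rt$pos[idx]),
           direction = if (merged$value[i] > 0) "gain" else "loss",
           mean_log2 = mean(rt$log2_ratio[idx]),
           n_positions = length(idx),
           targets_hit = list(unique(target_of[idx])))
  }))
}

position_target <- function(pos, targets) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(targets))) {
    inside <- pos > targets$start[i] & pos <= targets$end[i]  # pos is 1-based
    out[inside] <- targets$target_id[i]
  }
  out
}

run_bounds <- function(x) {
  r <- rle(x)
  to <- cumsum(r$lengths)
  tibble(value = r$values, from = to - r$lengths + 1L, to = to)
}
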