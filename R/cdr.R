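#' Build a per-base lesion support profile by sweep line
#'
#' Formalises the visual stacking of lesion bars along a chromosome: for one
#' lesion kind, counts at every base how many distinct samples carry a
#' segment covering it. Overlapping same-kind segments within one sample are
#' merged first, so each sample contributes at most one to the count at any
#' base. The profile is piecewise constant between segment breakpoints and is
#' computed by an event-point sweep, never by per-base counting (the per-base
#' count is the test oracle, not the implementation).
#'
#' @param segments Segment tibble on a single chromosome.
#' @param kind Lesion kind to profile (`"DEL"`, `"GAIN"` or `"UPD"`).
#' @return A `support_profile` tibble with columns `chrom`, `start`, `end`,
#'   `support` covering the span of the segments (including internal
#'   zero-support gaps). The per-sample merged segments are attached as
#'   attribute `merged_segments` for membership queries.
#' @export
build_support_profile <- function(segments, kind = "DEL") {
  validate_segments(segments)
  if (!kind %in% LESION_KINDS) {
    abort_validation(paste0("kind must be one of: ", paste(LESION_KINDS, collapse = ", ")))
  }
  seg <- segments[segments$kind == kind, ]
  if (length(unique(segments$chrom)) > 1L) {
    abort_validation("segments span multiple chromosomes; profile one chromosome at a time")
  }
  empty <- structure(
    tibble(chrom = character(), start = integer(), end = integer(), support = integer()),
    class = c("support_profile", class(tibble())),
    merged_segments = tibble(sample_id = character(), chrom = character(),
                             start = integer(), end = integer())
  )
  if (nrow(seg) == 0L) return(empty)

  merged <- merge_per_sample(seg)
  bp <- sort(unique(c(merged$start, merged$end)))
  iv_start <- bp[-length(bp)]
  iv_end <- bp[-1]
  # +1 at segment starts, -1 at ends; cumulative sum over breakpoints
  delta <- vapply(bp[-length(bp)], function(b) {
    sum(merged$start == b) - sum(merged$end == b)
  }, integer(1))
  support <- cumsum(delta)
  structure(
    tibble(chrom = seg$chrom[1], start = iv_start, end = iv_end, support = support),
    class = c("support_profile", class(tibble())),
    merged_segments = merged
  )
}

merge_per_sample <- function(seg) {
  # union of same-sample segments; touching intervals merge (identical cover)
  out <- seg |>
    arrange(.data$sample_id, .data$start, .data$end) |>
    group_by(.data$sample_id, .data$chrom) |>
    group_modify(function(d, key) {
      s <- d$start; e <- d$end
      ks <- s[1]; ke <- e[1]; res_s <- integer(0); res_e <- integer(0)
      for (i in seq_along(s)[-1]) {
        if (s[i] <= ke) ke <- max(ke, e[i])
        else { res_s <- c(res_s, ks); res_e <- c(res_e, ke); ks <- s[i]; ke <- e[i] }
      }
      tibble(start = c(res_s, ks), end = c(res_e, ke))
    }) |>
    ungroup()
  out[, c("sample_id", "chrom", "start", "end")]
}

#' Find common aberrant regions (CDRs) from a support profile
#'
#' A CDR is a maximal interval of locally maximal support: a run of
#' breakpoint intervals sharing the same covering sample set, whose support
#' is at least `min_support` and strictly greater than the support of both
#' flanking intervals (zero beyond the profiled span). Extending either
#' boundary of a reported CDR therefore reduces its support. This is the
#' "minimal common region" reading of stacked lesion plots: each cluster of
#' overlapping lesions contributes the core interval shared by most samples.
#'
#' @param profile A `support_profile` from [build_support_profile()].
#' @param min_support Minimum number of distinct supporting samples
#'   (default 2).
#' @return A tibble with columns `chrom`, `start`, `end`, `support`,
#'   `member_samples` (list-column of sample ids covering the whole CDR) and
#'   `genes` (list-column, empty until [annotate_cdr_genes()]).
#' @export
find_cdrs <- function(profile, min_support = 2) {
  if (min_support < 1) abort_validation("min_support must be >= 1")
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  support = integer(), member_samples = list(), genes = list())
  if (nrow(profile) == 0L) return(empty)
  merged <- attr(profile, "merged_segments")

  members <- map(seq_len(nrow(profile)), function(i) {
    hit <- merged$start <= profile$start[i] & merged$end >= profile$end[i]
    sort(unique(merged$sample_id[hit]))
  })

  # collapse adjacent intervals with identical covering sets
  key <- map_chr(members, paste, collapse = "\r")
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)] |
                    profile$start[-1] != profile$end[-nrow(profile)]))
  plateaus <- tibble(
    chrom = profile$chrom[!duplicated(run)],
    start = unname(vapply(split(profile$start, run), min, double(1))),
    end = unname(vapply(split(profile$end, run), max, double(1))),
    support = profile$support[!duplicated(run)],
    member_samples = members[!duplicated(run)]
  )

  n <- nrow(plateaus)
  left <- c(0, plateaus$support[-n])
  right <- c(plateaus$support[-1], 0)
  # non-adjacent plateaus (gaps in the profile) neighbour support 0
  if (n > 1) {
    gap_l <- c(FALSE, plateaus$start[-1] != plateaus$end[-n])
    gap_r <- c(plateaus$end[-n] != plateaus$start[-1], FALSE)
    left[gap_l] <- 0
    right[gap_r] <- 0
  }
  is_cdr <- plateaus$support >= min_support &
    plateaus$support > left & plateaus$support > right
  out <- plateaus[is_cdr, ]
  out$genes <- rep(list(character(0)), nrow(out))
  out
}

#' Annotate CDRs with overlapping genes
#'
#' Fills the `genes` list-column with the ids of every gene model overlapping
#' the CDR by at least one base, in genomic order.
#'
#' @param cdrs CDR tibble from [find_cdrs()].
#' @param gene_models Gene model tibble ([read_gene_models()]).
#' @return The CDR tibble with populated `genes`.
#' @export
annotate_cdr_genes <- function(cdrs, gene_models) {
  if (nrow(cdrs) == 0L) return(cdrs)
  cdrs$genes <- map(seq_len(nrow(cdrs)), function(i) {
    hit <- gene_models$chrom == cdrs$chrom[i] &
      gene_models$start < cdrs$end[i] & gene_models$end > cdrs$start[i]
    g <- gene_models[hit, ]
    g$gene_id[order(g$start)]
  })
  cdrs
}
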