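#' Cohort template for a large myeloid-malignancy study
#'
#' The per-diagnosis sample counts and chromosome-lesion carrier counts used
#' as the default cohort layout for the synthetic generator: 813 samples
#' across MPN (PV/ET/PMF and their myelofibrotic, accelerated and leukemic
#' transformations), MDS, de novo AML and CML, 52 of them carrying at least
#' one lesion on the analysed chromosome (6.4\%).
#'
#' @return A tibble with columns `disease_entity`, `diagnosis`, `n_samples`,
#'   `n_with_lesion`.
#' @export
myeloid_cohort_template <- function() {
  tribble(
    ~disease_entity, ~diagnosis,      ~n_samples, ~n_with_lesion,
    "MPN",           "PV",            177L,       3L,
    "MPN",           "post-PV MF",    48L,        3L,
    "MPN",           "post-PV AML",   19L,        3L,
    "MPN",           "ET",            91L,        2L,
    "MPN",           "post-ET MF",    18L,        1L,
    "MPN",           "post-ET AML",   9L,         1L,
    "MPN",           "PMF",           85L,        5L,
    "MPN",           "post-PMF AP",   7L,         0L,
    "MPN",           "post-PMF AML",  16L,        6L,
    "MDS",           "MDS",           61L,        3L,
    "MDS",           "post-MDS AML",  40L,        5L,
    "de novo AML",   "de novo AML",   180L,       19L,
    "CML",           "CML",           62L,        1L
  )
}

#' Simulate a cohort with planted chromosome lesions
#'
#' Generates a sample sheet and a lesion segment table matching a cohort
#' specification: for each diagnosis row, exactly `n_with_lesion` randomly
#' chosen samples receive one to three lesion segments, with kinds drawn
#' from `kind_mix` and coordinates drawn on a toy chromosome. The planted
#' truth is returned alongside the tables; identical seed and configuration
#' give identical output.
#'
#' @param cohort_spec Tibble with `diagnosis`, `n_samples`, `n_with_lesion`
#'   (default [myeloid_cohort_template()]).
#' @param seed Integer seed.
#' @param chrom,chrom_length Toy chromosome name and length (default
#'   `chr11`, 135 Mb, the scale of human chromosome 11).
#' @param kind_mix Named proportions over DEL/GAIN/UPD; the default follows
#'   the observed lesion-type mix of a large chromosome-11 survey
#'   (30:11:17).
#' @param n_segments_prob Probabilities of a lesion-bearing sample carrying
#'   1, 2 or 3 segments.
#' @param out_dir Optional directory: when given, writes `samples.tsv`,
#'   `segments.tsv` and `truth.json` there.
#' @return A list with `samples`, `segments` (tibbles) and `truth` (list).
#' @export
simulate_cohort <- function(cohort_spec = myeloid_cohort_template(), seed,
                            chrom = "chr11", chrom_length = 135e6,
                            kind_mix = c(DEL = 30, GAIN = 11, UPD = 17) / 58,
                            n_segments_prob = c(0.7, 0.2, 0.1),
                            out_dir = NULL) {
  if (any(cohort_spec$n_with_lesion > cohort_spec$n_samples)) {
    abort_validation("n_with_lesion cannot exceed n_samples")
  }
  if (abs(sum(kind_mix) - 1) > 1e-9) abort_validation("kind_mix must sum to 1")
  phase_map <- mpn_phase_map()

  result <- withr::with_seed(seed, {
    samples <- cohort_spec |>
      mutate(.row = row_number()) |>
      group_by(.data$.row) |>
      reframe(diagnosis = rep(.data$diagnosis, .data$n_samples)) |>
      mutate(sample_id = sprintf("S%04d", row_number()),
             patient_id = sprintf("P%04d", row_number())) |>
      select("sample_id", "patient_id", "diagnosis")
    samples <- apply_phase_map(samples, phase_map)

    seg_rows <- list()
    truth_lesions <- list()
    for (i in seq_len(nrow(cohort_spec))) {
      dx <- cohort_spec$diagnosis[i]
      ids <- samples$sample_id[samples$diagnosis == dx]
      carriers <- sort(sample(ids, cohort_spec$n_with_lesion[i]))
      for (sid in carriers) {
        k <- sample(1:3, 1, prob = n_segments_prob)
        for (j in seq_len(k)) {
          len <- round(10^runif(1, log10(5e5), log10(chrom_length / 2)))
          start <- sample.int(chrom_length - len, 1) - 1L
          seg_rows[[length(seg_rows) + 1L]] <- tibble(
            sample_id = sid, chrom = chrom, start = start,
            end = start + len,
            kind = sample(names(kind_mix), 1, prob = kind_mix))
        }
      }
    }
    segments <- bind_rows(seg_rows)
    if (nrow(segments) == 0L) {
      segments <- tibble(sample_id = character(), chrom = character(),
                         start = integer(), end = integer(), kind = character())
    } else {
      segments <- distinct(segments) |> arrange(.data$sample_id, .data$start)
    }
    list(samples = samples, segments = segments)
  })

  truth <- list(seed = seed, chrom = chrom, chrom_length = chrom_length,
                cohort_spec = as.list(cohort_spec),
                n_samples = sum(cohort_spec$n_samples),
                n_with_lesion = sum(cohort_spec$n_with_lesion),
                planted_segments = as.list(result$segments))
  out <- list(samples = result$samples, segments = result$segments, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(out$samples, file.path(out_dir, "samples.tsv"))
    write_segments(out$segments, file.path(out_dir, "segments.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate capture targets on a toy chromosome
#'
#' Non-overlapping target intervals of varying length placed with random
#' gaps, emulating exon capture design.
#'
#' @param n_targets Number of targets.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @param target_length Range of target lengths (drawn uniformly).
#' @param gap_length Range of inter-target gaps.
#' @param origin Start coordinate of the first target (0-based).
#' @return Target tibble (`target_id`, `chrom`, `start`, `end`).
#' @export
simulate_targets <- function(n_targets = 40, seed = 1, chrom = "chr11",
                             target_length = c(120, 400),
                             gap_length = c(2e3, 2e4), origin = 1e5) {
  withr::with_seed(seed, {
    lens <- round(runif(n_targets, target_length[1], target_length[2]))
    gaps <- round(runif(n_targets, gap_length[1], gap_length[2]))
    starts <- origin + cumsum(c(0, head(lens + gaps, -1)))
    tibble(target_id = sprintf("target_%03d", seq_len(n_targets)),
           chrom = chrom, start = starts, end = starts + lens)
  })
}

#' Simulate case and control exome depth tracks with spiked focal events
#'
#' Per-position depths over targeted bases are drawn as
#' `Poisson(depth * target_weight * copy_ratio)`, where each target carries a
#' Gamma-distributed capture weight (mean 1) shared by all samples of the
#' batch, `copy_ratio` is 1 everywhere for controls and inside `spikes` for
#' the case takes the planted ratio (1.5 for a heterozygous duplication,
#' 0.5 for a hemizygous deletion). The global seed fans out to fixed
#' sub-streams (weights; case; each control), so adding controls never
#' perturbs the case draw.
#'
#' @param targets Target tibble ([simulate_targets()] or [read_targets()]).
#' @param seed Integer seed.
#' @param depth Mean sequencing depth at an average target.
#' @param n_controls Number of control tracks (default 8).
#' @param spikes Optional tibble `chrom`, `start`, `end`, `copy_ratio`
#'   (0-based half-open); must lie within targets.
#' @param weight_shape Shape of the Gamma capture-weight distribution
#'   (rate equal, so the mean is 1; default 20, cv ~ 0.22).
#' @return A list with `case` (depth tibble), `controls` (list of depth
#'   tibbles) and `truth` (spikes, depth, per-target weights).
#' @export
simulate_depth_tracks <- function(targets, seed, depth = 100, n_controls = 8,
                                  spikes = NULL, weight_shape = 20) {
  if (depth <= 0) abort_validation("depth must be positive")
  pos <- unlist(map(seq_len(nrow(targets)),
                    function(i) (targets$start[i] + 1L):targets$end[i]))
  w_target <- rep(seq_len(nrow(targets)), targets$end - targets$start)
  copy_ratio <- rep(1, length(pos))
  if (!is.null(spikes) && nrow(spikes) > 0) {
    for (i in seq_len(nrow(spikes))) {
      inside <- pos > spikes$start[i] & pos <= spikes$end[i]
      if (!any(inside)) abort_validation("spike interval overlaps no targeted base")
      covered <- sum(inside)
      if (covered < spikes$end[i] - spikes$start[i]) {
        abort_validation("spike interval extends outside the targets")
      }
      copy_ratio[inside] <- spikes$copy_ratio[i]
    }
  }
  weights <- withr::with_seed(seed, rgamma(nrow(targets), shape = weight_shape,
                                           rate = weight_shape))
  rate <- depth * weights[w_target]
  chrom <- targets$chrom[1]
  draw <- function(s, ratio) {
    withr::with_seed(s, tibble(chrom = chrom, pos = pos,
                               depth = rpois(length(pos), rate * ratio)))
  }
  case <- draw(seed + 1L, copy_ratio)
  controls <- map(seq_len(n_controls), function(i) draw(seed + 1L + i, 1))
  truth <- list(seed = seed, depth = depth,
                spikes = if (is.null(spikes)) list() else as.list(spikes),
                target_weights = weights)
  list(case = case, controls = controls, truth = truth)
}

#' Simulate variant observations from planted dosage mechanisms
#'
#' For each row of `clone_spec` (a mechanism with its clonality, depth and
#' number of variants), draws alternate read counts from
#' `Binomial(depth, vaf_eff)` where `vaf_eff` is the mechanism's
#' [expected_vaf()] shrunk by the sequencing error rate. The overlapping
#' lesion kind implied by each mechanism is recorded so the observations can
#' be classified blind and compared to the planted truth.
#'
#' @param clone_spec Tibble with columns `mechanism`, `clonality`, `depth`,
#'   `n`.
#' @param seed Integer seed.
#' @param error_rate Sequencing error floor (default 0.01).
#' @return A list with `variants` (tibble including `overlapping_kind` and
#'   the planted `true_mechanism`) and `truth`.
#' @export
simulate_clone_observations <- function(clone_spec, seed, error_rate = 0.01) {
  kinds <- c(heterozygous = "none", UPD_homozygous = "UPD",
             gain_amplified_mutant = "GAIN", gain_retained_wildtype = "GAIN",
             hemizygous_deleted_locus = "DEL")
  models <- bind_rows(map(names(kinds), function(m) {
    mm <- mechanism_models(kinds[[m]])
    mm[mm$mechanism == m, ]
  }))
  bad <- setdiff(clone_spec$mechanism, models$mechanism)
  if (length(bad) > 0) {
    abort_validation(paste0("unknown mechanism: ", paste(bad, collapse = ", ")))
  }
  variants <- withr::with_seed(seed, {
    bind_rows(map(seq_len(nrow(clone_spec)), function(i) {
      m <- models[models$mechanism == clone_spec$mechanism[i], ]
      p <- expected_vaf(m$copy_number, m$mutant_copies, clone_spec$clonality[i])
      p_eff <- min(max(p, error_rate), 1 - error_rate)
      alt_n <- rbinom(clone_spec$n[i], clone_spec$depth[i], p_eff)
      tibble(sample_id = sprintf("clone_%d", i),
             chrom = "chr11",
             pos = seq_len(clone_spec$n[i]),
             ref = "C", alt = "T",
             ref_reads = clone_spec$depth[i] - alt_n,
             alt_reads = alt_n,
             overlapping_kind = kinds[[clone_spec$mechanism[i]]],
             true_mechanism = clone_spec$mechanism[i],
             true_clonality = clone_spec$clonality[i])
    }))
  })
  list(variants = variants,
       truth = list(seed = seed, clone_spec = as.list(clone_spec),
                    error_rate = error_rate))
}

#' Simulate a colony genotyping table with a planted phase
#'
#' Draws colony counts from the multinomial implied by the planted
#' configuration: `trans` splits colonies between the two single-mutant
#' classes, `cis` between double-mutant and wild-type, `single` between one
#' single-mutant class and wild-type.
#'
#' @param phase One of `trans`, `cis`, `single`.
#' @param n_colonies Total colonies genotyped.
#' @param seed Integer seed.
#' @return A list with `colonies` (one-row tibble `a_only`, `b_only`,
#'   `both`, `neither`) and `truth`.
#' @export
simulate_colony_table <- function(phase = c("trans", "cis", "single"),
                                  n_colonies = 40, seed = 1) {
  phase <- match.arg(phase)
  probs <- switch(phase,
    trans = c(a_only = 0.5, b_only = 0.5, both = 0, neither = 0),
    cis = c(a_only = 0, b_only = 0, both = 0.5, neither = 0.5),
    single = c(a_only = 0.5, b_only = 0, both = 0, neither = 0.5))
  counts <- withr::with_seed(seed, as.vector(rmultinom(1, n_colonies, probs)))
  colonies <- as_tibble(as.list(setNames(counts, names(probs))))
  list(colonies = colonies, truth = list(phase = phase, seed = seed,
                                         n_colonies = n_colonies))
}

#' Simulate deletions sharing a planted common core
#'
#' Each sample receives one deletion containing the requested core interval,
#' extended on both sides by independent exponential-ish flanks. The realised
#' minimal common region (the intersection of all deletions) is recorded in
#' the truth so recovery can be checked exactly.
#'
#' @param n_samples Number of samples (default 20).
#' @param core Planted core interval `c(start, end)` (0-based half-open;
#'   default a 50 kb core).
#' @param seed Integer seed.
#' @param chrom,chrom_length Toy chromosome (default 10 Mb: large enough for
#'   CDR geometry, small enough for per-base oracles).
#' @param max_flank Upper bound on each flank extension (default 2 Mb).
#' @return A list with `segments`, `samples` and `truth` (including
#'   `realized_core`).
#' @export
simulate_cdr_segments <- function(n_samples = 20, core = c(5e6, 5.05e6), seed = 7,
                                  chrom = "chr11", chrom_length = 10e6,
                                  max_flank = 2e6) {
  if (core[1] >= core[2] || core[1] < 0 || core[2] > chrom_length) {
    abort_validation("core must be a non-empty interval within the chromosome")
  }
  segments <- withr::with_seed(seed, {
    left <- pmin(round(rexp(n_samples, rate = 4 / max_flank)), max_flank)
    right <- pmin(round(rexp(n_samples, rate = 4 / max_flank)), max_flank)
    tibble(sample_id = sprintf("S%03d", seq_len(n_samples)),
           chrom = chrom,
           start = pmax(0, core[1] - left),
           end = pmin(chrom_length, core[2] + right),
           kind = "DEL")
  })
  samples <- tibble(sample_id = segments$sample_id,
                    patient_id = sub("^S", "P", segments$sample_id),
                    diagnosis = "de novo AML")
  truth <- list(seed = seed, requested_core = core,
                realized_core = c(max(segments$start), min(segments$end)))
  list(segments = segments, samples = samples, truth = truth)
}
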