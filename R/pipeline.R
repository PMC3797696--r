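#' Run the full chromosome-centered lesion analysis
#'
#' Wires the modules end to end: cohort summary, patient-level
#' deduplication, aberration tally, per-chromosome support profiles and
#' CDRs, lesion-phenotype association(s), and optionally the focal
#' coverage caller and the dosage classifier. Results are written as TSV
#' files with JSON mirrors plus a run manifest; reruns on identical inputs
#' produce byte-identical result files (timestamps live only in the
#' manifest).
#'
#' @param segments Segment tibble or path to a segments TSV.
#' @param samples Sample sheet tibble or path.
#' @param out_dir Output directory (created if needed).
#' @param gene_models Optional gene model tibble for CDR annotation.
#' @param associations Named list of association specs, each a list with
#'   `group_a`, `group_b` and optionally `predicate` and `unit`. Defaults to
#'   the chronic-MPN vs post-MPN-AML contrast when those diagnoses are
#'   present.
#' @param cdr_kind Lesion kind profiled for CDRs (default `"DEL"`).
#' @param min_support Minimum CDR support (default 2).
#' @param exclude_complex Sample ids excluded from the tally.
#' @param reciprocal_overlap Dedup threshold (default 0.9).
#' @param unit Counting unit for summary and associations.
#' @param case_track,control_tracks,targets Optional raw depth tibbles (case,
#'   list of controls) and target tibble: when all are given the focal
#'   caller runs with `caller_args`.
#' @param caller_args Named list of overrides for [call_focal_events()].
#' @param variants Optional variant tibble with `overlapping_kind` for the
#'   dosage classifier.
#' @param dosage_args Named list of overrides for [classify_mechanism()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_full_analysis <- function(segments, samples, out_dir,
                              gene_models = NULL,
                              associations = NULL,
                              cdr_kind = "DEL", min_support = 2,
                              exclude_complex = character(),
                              reciprocal_overlap = 0.9,
                              unit = "sample",
                              case_track = NULL, control_tracks = NULL,
                              targets = NULL, caller_args = list(),
                              variants = NULL, dosage_args = list()) {
  input_digests <- list()
  if (is.character(segments)) {
    input_digests$segments <- unname(tools::md5sum(segments))
    segments <- read_segments(segments)
  }
  if (is.character(samples)) {
    input_digests$samples <- unname(tools::md5sum(samples))
    samples <- read_sample_sheet(samples)
  }
  validate_segments(segments)
  missing <- setdiff(segments$sample_id, samples$sample_id)
  if (length(missing) > 0L) {
    abort_validation(paste0("segment sample_id not in sample sheet: ",
                            paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- Sys.time()
  counts <- list()

  summary <- summarize_cohort(segments, samples, unit = unit)
  write_report(as_tibble(summary), file.path(out_dir, "cohort_summary"))
  counts$cohort_summary <- nrow(summary)

  deduped <- dedupe_recurrent(segments, samples,
                              reciprocal_overlap = reciprocal_overlap)
  write_report(deduped, file.path(out_dir, "segments_deduplicated"))
  counts$segments_deduplicated <- nrow(deduped)

  tally <- tally_aberrations(deduped, samples, exclude = exclude_complex)
  write_report(tally, file.path(out_dir, "aberration_tally"))

  cdr_list <- map(split_chrom(deduped[deduped$kind == cdr_kind, ]), function(seg) {
    prof <- build_support_profile(seg, kind = cdr_kind)
    cdrs <- find_cdrs(prof, min_support = min_support)
    if (!is.null(gene_models)) cdrs <- annotate_cdr_genes(cdrs, gene_models)
    cdrs
  })
  cdrs <- if (length(cdr_list) > 0) bind_rows(cdr_list) else
    find_cdrs(build_support_profile(deduped[0, ], kind = cdr_kind), min_support)
  cdr_flat <- cdrs |>
    mutate(member_samples = map_chr(.data$member_samples, paste, collapse = ","),
           genes = map_chr(.data$genes, paste, collapse = ","))
  write_report(cdr_flat, file.path(out_dir, "cdrs"))
  counts$cdrs <- nrow(cdrs)

  if (is.null(associations)) {
    associations <- list()
    if (any(samples$diagnosis %in% post_mpn_aml_diagnoses()) &&
        any(samples$diagnosis %in% chronic_mpn_diagnoses())) {
      associations$post_mpn_aml_vs_chronic <- list(
        group_a = post_mpn_aml_diagnoses(),
        group_b = chronic_mpn_diagnoses())
    }
  }
  assoc_results <- imap(associations, function(spec, name) {
    res <- associate_lesions(segments, samples,
                             group_a = spec$group_a, group_b = spec$group_b,
                             predicate = spec$predicate %||% lesion_any(),
                             unit = spec$unit %||% unit)
    c(as.list(tidy(res)),
      list(group_a = spec$group_a, group_b = spec$group_b, unit = res$unit))
  })
  jsonlite::write_json(assoc_results, file.path(out_dir, "associations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts$associations <- length(assoc_results)

  focal_calls <- NULL
  if (!is.null(case_track) && !is.null(control_tracks) && !is.null(targets)) {
    ref <- build_reference(map(control_tracks, normalize_track))
    ratio <- log2_ratio_track(normalize_track(case_track), ref)
    readr::write_tsv(as_tibble(ratio), file.path(out_dir, "log2_ratio.tsv"))
    focal_calls <- do.call(call_focal_events,
                           c(list(ratio = ratio, targets = targets), caller_args))
    write_report(
      mutate(focal_calls, targets_hit = map_chr(.data$targets_hit, paste, collapse = ",")),
      file.path(out_dir, "focal_calls"))
    counts$focal_calls <- nrow(focal_calls)
  }

  dosage_calls <- NULL
  if (!is.null(variants)) {
    dosage_calls <- do.call(classify_mechanism,
                            c(list(variants = variants), dosage_args))
    write_report(select(dosage_calls, -"log_likelihoods"),
                 file.path(out_dir, "dosage_calls"))
    counts$dosage_calls <- nrow(dosage_calls)
  }

  manifest <- list(
    tool = "chromscan",
    version = as.character(utils::packageVersion("chromscan")),
    config = list(cdr_kind = cdr_kind, min_support = min_support,
                  exclude_complex = exclude_complex,
                  reciprocal_overlap = reciprocal_overlap, unit = unit,
                  caller_args = caller_args, dosage_args = dosage_args),
    input_digests = input_digests,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    record_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(summary = summary, deduped = deduped, tally = tally,
                 cdrs = cdrs, associations = assoc_results,
                 focal_calls = focal_calls, dosage_calls = dosage_calls,
                 manifest = manifest))
}

split_chrom <- function(segments) {
  if (nrow(segments) == 0L) return(list())
  split(segments, segments$chrom)
}

# TSV plus a JSON mirror of the same records
write_report <- function(df, stem) {
  readr::write_tsv(df, paste0(stem, ".tsv"))
  jsonlite::write_json(df, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(stem)
}
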