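#' Read a somatic aberration segment table
#'
#' Reads a five-column tab-separated table of somatic lesion segments
#' (`sample_id`, `chrom`, `start`, `end`, `kind`). Coordinates on disk are
#' 0-based half-open, matching BED conventions, and are kept as such in
#' memory. A header line is optional and detected by a non-integer third
#' field. Lesion kinds must be one of `DEL`, `GAIN`, `UPD`.
#'
#' Malformed rows are rejected (never coerced) with an error naming the
#' offending line of the file.
#'
#' @param path Path to the segments TSV.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `kind`, one row per segment.
#' @seealso [write_segments()], [read_sample_sheet()]
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("segments file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), kind = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- !is_integer_token(fields[[1]][3] %||% NA_character_)
  offset <- if (has_header) 1L else 0L
  rows <- fields[(offset + 1L):length(fields)]
  if (has_header && length(fields) == 1L) rows <- list()

  parse_row <- function(f, i) {
    line_no <- i + offset
    if (length(f) != 5L) {
      abort_parse(sprintf("line %d: expected 5 tab-separated fields, got %d",
                          line_no, length(f)))
    }
    if (!is_integer_token(f[3]) || !is_integer_token(f[4])) {
      abort_parse(sprintf("line %d: start/end must be integers ('%s', '%s')",
                          line_no, f[3], f[4]))
    }
    if (!f[5] %in% LESION_KINDS) {
      abort_parse(sprintf("line %d: unknown lesion kind '%s' (allowed: %s)",
                          line_no, f[5], paste(LESION_KINDS, collapse = ", ")))
    }
    start <- as.integer(f[3]); end <- as.integer(f[4])
    if (is.na(start) || is.na(end) || start < 0L || start >= end) {
      abort_validation(sprintf(
        "line %d: invalid interval [%s, %s) - need 0 <= start < end",
        line_no, f[3], f[4]))
    }
    list(sample_id = f[1], chrom = f[2], start = start, end = end, kind = f[5])
  }
  parsed <- imap(rows, parse_row)
  segments <- bind_rows(parsed)
  dup <- duplicated(segments)
  if (any(dup)) {
    abort_validation(sprintf(
      "line %d: duplicate segment row (sample, chrom, start, end, kind must be unique)",
      which(dup)[1] + offset))
  }
  segments
}

#' Write a segment table to disk
#'
#' Inverse of [read_segments()]: writes the five-column TSV with a header.
#' Round-tripping through [write_segments()] and [read_segments()] preserves
#' every field exactly.
#'
#' @param segments Segment tibble as returned by [read_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  readr::write_tsv(segments[, c("sample_id", "chrom", "start", "end", "kind")], path)
  invisible(path)
}

validate_segments <- function(segments) {
  needed <- c("sample_id", "chrom", "start", "end", "kind")
  if (!all(needed %in% names(segments))) {
    abort_validation(paste0("segments must have columns: ",
                            paste(needed, collapse = ", ")))
  }
  if (nrow(segments) == 0L) return(invisible(segments))
  bad_kind <- !segments$kind %in% LESION_KINDS
  if (any(bad_kind)) {
    abort_validation(sprintf("unknown lesion kind '%s' (allowed: %s)",
                             segments$kind[bad_kind][1],
                             paste(LESION_KINDS, collapse = ", ")))
  }
  bad <- segments$start < 0 | segments$start >= segments$end
  if (any(bad)) {
    abort_validation(sprintf("invalid interval [%s, %s): need 0 <= start < end",
                             segments$start[bad][1], segments$end[bad][1]))
  }
  invisible(segments)
}

#' Read a cohort sample sheet
#'
#' Reads a tab-separated sample sheet with columns `sample_id`, `patient_id`
#' and `diagnosis` (header optional; detected by a first field equal to
#' `"sample_id"`). A disease-phase column is derived from the diagnosis via a
#' declared mapping table, so the grouping used by the association tests is
#' data, not code.
#'
#' @param path Path to the sample sheet TSV.
#' @param phase_map Mapping tibble with columns `diagnosis` and `phase`;
#'   defaults to [mpn_phase_map()]. Diagnoses absent from the map get phase
#'   `NA` with a warning.
#' @return A tibble with columns `sample_id`, `patient_id`, `diagnosis`,
#'   `phase`.
#' @export
read_sample_sheet <- function(path, phase_map = mpn_phase_map()) {
  if (!file.exists(path)) abort_validation(paste0("sample sheet not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(sample_id = character(), patient_id = character(),
                  diagnosis = character(), phase = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- identical(fields[[1]][1], "sample_id")
  offset <- if (has_header) 1L else 0L
  rows <- fields[seq.int(offset + 1L, length.out = length(fields) - offset)]
  parsed <- imap(rows, function(f, i) {
    if (length(f) < 3L) {
      abort_parse(sprintf("line %d: expected at least 3 tab-separated fields, got %d",
                          i + offset, length(f)))
    }
    list(sample_id = f[1], patient_id = f[2], diagnosis = f[3])
  })
  samples <- bind_rows(parsed)
  if (anyDuplicated(samples$sample_id)) {
    abort_validation(sprintf("duplicate sample_id '%s' in sample sheet",
                             samples$sample_id[duplicated(samples$sample_id)][1]))
  }
  apply_phase_map(samples, phase_map)
}

apply_phase_map <- function(samples, phase_map) {
  samples$phase <- phase_map$phase[match(samples$diagnosis, phase_map$diagnosis)]
  unmapped <- unique(samples$diagnosis[is.na(samples$phase)])
  if (length(unmapped) > 0L) {
    warn(paste0("diagnoses without a phase mapping: ",
                paste(unmapped, collapse = ", ")))
  }
  samples
}

#' Default diagnosis-to-phase mapping for myeloid cohorts
#'
#' Declares how specific diagnoses map onto the three disease phases used for
#' grouping: `chronic`, `progressed_non_AML` (myelofibrotic or accelerated
#' phase, blast count below the AML threshold) and `AML`. Patients with
#' post-MPN myelofibrosis or in accelerated phase have not transformed to
#' leukemia and are treated as chronic-phase in the leukemic-transformation
#' contrast; see [chronic_mpn_diagnoses()].
#'
#' @return A tibble with columns `diagnosis`, `phase`, `disease_entity`.
#' @export
mpn_phase_map <- function() {
  tribble(
    ~diagnosis,                  ~phase,               ~disease_entity,
    "PV",                        "chronic",            "MPN",
    "post-PV MF",                "progressed_non_AML", "MPN",
    "post-PV AML",               "AML",                "MPN",
    "ET",                        "chronic",            "MPN",
    "post-ET MF",                "progressed_non_AML", "MPN",
    "post-ET AML",               "AML",                "MPN",
    "PMF",                       "chronic",            "MPN",
    "post-PMF AP",               "progressed_non_AML", "MPN",
    "post-PMF AML",              "AML",                "MPN",
    "MDS",                       "chronic",            "MDS",
    "post-MDS AML",              "AML",                "MDS",
    "de novo AML",               "AML",                "de novo AML",
    "CML",                       "chronic",            "CML"
  )
}

#' Diagnosis sets for the MPN leukemic-transformation contrast
#'
#' `post_mpn_aml_diagnoses()` returns the secondary-AML arm (AML after PV, ET
#' or PMF); `chronic_mpn_diagnoses()` returns the chronic-phase arm, in which
#' myelofibrotic and accelerated-phase samples are counted as chronic because
#' they have not transformed to leukemia.
#'
#' @return Character vector of diagnosis labels.
#' @export
post_mpn_aml_diagnoses <- function() {
  c("post-PV AML", "post-ET AML", "post-PMF AML")
}

#' @rdname post_mpn_aml_diagnoses
#' @export
chronic_mpn_diagnoses <- function() {
  c("PV", "post-PV MF", "ET", "post-ET MF", "PMF", "post-PMF AP")
}

#' Read a per-base depth track
#'
#' Reads three-column per-base depth text (`chrom`, 1-based `pos`, `depth`) as
#' produced by `samtools depth`, one chromosome per file. The representation
#' is sparse: positions absent from the file stay absent, they are never
#' zero-filled. Positions must be strictly increasing and depths
#' non-negative.
#'
#' @param path Path to the depth file (no header).
#' @return A tibble with columns `chrom`, `pos`, `depth`.
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("depth file not found: ", path))
  track <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "depth"),
    col_types = readr::cols(chrom = readr::col_character(),
                            pos = readr::col_double(),
                            depth = readr::col_double()),
    progress = FALSE
  )
  if (nrow(track) == 0L) {
    return(tibble(chrom = character(), pos = double(), depth = double()))
  }
  if (anyNA(track$pos) || anyNA(track$depth)) {
    bad <- which(is.na(track$pos) | is.na(track$depth))[1]
    abort_parse(sprintf("line %d: non-numeric position or depth", bad))
  }
  if (length(unique(track$chrom)) > 1L) {
    bad <- which(track$chrom != track$chrom[1])[1]
    abort_validation(sprintf(
      "line %d: multiple chromosomes in one depth file ('%s' after '%s')",
      bad, track$chrom[bad], track$chrom[1]))
  }
  if (any(track$depth < 0)) {
    bad <- which(track$depth < 0)[1]
    abort_validation(sprintf("line %d: negative depth %s", bad, track$depth[bad]))
  }
  if (any(diff(track$pos) <= 0)) {
    bad <- which(diff(track$pos) <= 0)[1] + 1L
    abort_validation(sprintf("line %d: positions not strictly increasing", bad))
  }
  track
}

#' Write a per-base depth track
#'
#' @param track Depth tibble (`chrom`, `pos`, `depth`).
#' @param path Output path; three columns, tab-separated, no header.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "pos", "depth")], path, col_names = FALSE)
  invisible(path)
}

#' Read gene/CDS models from BED
#'
#' Reads gene models either from BED12 (blocks interpreted as CDS exons) or
#' from BED6 plus a companion BED of CDS sub-intervals whose name column
#' carries the gene id. Coordinates are kept 0-based half-open. CDS blocks
#' within one gene must not overlap; a total CDS length that is not a
#' multiple of 3 triggers a warning (such models cannot be used for
#' residue-level annotation).
#'
#' @param path BED6 or BED12 file of gene spans.
#' @param cds_path Optional companion BED of CDS blocks (required when `path`
#'   is BED6 and residue-level annotation is wanted).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, and a `cds_blocks` list-column of tibbles (`start`, `end`).
#' @export
read_gene_models <- function(path, cds_path = NULL) {
  if (!file.exists(path)) abort_validation(paste0("gene BED not found: ", path))
  gr <- rtracklayer::import(path, format = "bed")
  genes <- tibble(
    gene_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (anyDuplicated(genes$gene_id)) {
    abort_validation("duplicate gene ids in gene BED")
  }
  if (!is.null(gr$blocks)) {
    # BED12: blocks are 1-based, relative to the feature start
    genes$cds_blocks <- map2(gr$blocks, genes$start, function(bl, s0) {
      tibble(start = s0 + GenomicRanges::start(bl) - 1L,
             end = s0 + GenomicRanges::end(bl))
    })
  } else if (!is.null(cds_path)) {
    cds <- rtracklayer::import(cds_path, format = "bed")
    cds_tbl <- tibble(
      gene_id = as.character(cds$name),
      start = GenomicRanges::start(cds) - 1L,
      end = GenomicRanges::end(cds)
    )
    genes$cds_blocks <- map(genes$gene_id, function(g) {
      blk <- cds_tbl[cds_tbl$gene_id == g, c("start", "end")]
      arrange(blk, .data$start)
    })
  } else {
    genes$cds_blocks <- map(genes$start, ~ tibble(start = integer(), end = integer()))
  }
  for (i in seq_len(nrow(genes))) {
    bl <- genes$cds_blocks[[i]]
    if (nrow(bl) > 1L && any(bl$start[-1] < bl$end[-nrow(bl)])) {
      abort_validation(sprintf("gene '%s': overlapping CDS blocks", genes$gene_id[i]))
    }
    len <- sum(bl$end - bl$start)
    if (len > 0L && len %% 3L != 0L) {
      warn(sprintf("gene '%s': CDS length %d is not a multiple of 3",
                   genes$gene_id[i], len))
    }
  }
  genes
}

#' Read targeted intervals from BED
#'
#' @param path BED3+ file of capture targets, 0-based half-open.
#' @return A tibble with columns `target_id`, `chrom`, `start`, `end`.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("targets BED not found: ", path))
  gr <- rtracklayer::import(path, format = "bed")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name)) as.character(gr$name) else
    sprintf("target_%03d", seq_along(gr))
  tibble(target_id = ids,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' Read a minimal variant table
#'
#' Reads a seven-column TSV of variant observations: `sample_id`, `chrom`,
#' 1-based `pos`, `ref`, `alt`, `ref_reads`, `alt_reads`. A header is
#' optional, detected by a non-integer third field. Full VCF semantics
#' (multi-allelic records, genotype fields) are deliberately out of scope.
#'
#' @param path Path to the variant TSV.
#' @return A tibble with the seven columns above plus `vaf`
#'   (`alt_reads / (ref_reads + alt_reads)`).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("variant file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- tibble(sample_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(),
                  ref_reads = integer(), alt_reads = integer(), vaf = double())
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- !is_integer_token(fields[[1]][3] %||% NA_character_)
  offset <- if (has_header) 1L else 0L
  rows <- fields[seq.int(offset + 1L, length.out = length(fields) - offset)]
  if (length(rows) == 0L) return(empty)
  parsed <- imap(rows, function(f, i) {
    line_no <- i + offset
    if (length(f) != 7L) {
      abort_parse(sprintf("line %d: expected 7 tab-separated fields, got %d",
                          line_no, length(f)))
    }
    if (!is_integer_token(f[3]) || !is_integer_token(f[6]) || !is_integer_token(f[7])) {
      abort_parse(sprintf("line %d: pos/ref_reads/alt_reads must be integers", line_no))
    }
    if (f[4] == f[5]) {
      abort_validation(sprintf("line %d: ref and alt alleles are identical ('%s')",
                               line_no, f[4]))
    }
    rr <- as.integer(f[6]); ar <- as.integer(f[7])
    if (as.integer(f[3]) < 1L || rr < 0L || ar < 0L) {
      abort_validation(sprintf("line %d: pos must be >= 1 and read counts >= 0", line_no))
    }
    list(sample_id = f[1], chrom = f[2], pos = as.integer(f[3]),
         ref = f[4], alt = f[5], ref_reads = rr, alt_reads = ar)
  })
  variants <- bind_rows(parsed)
  variants$vaf <- ifelse(variants$ref_reads + variants$alt_reads > 0,
                         variants$alt_reads / (variants$ref_reads + variants$alt_reads),
                         NA_real_)
  variants
}

is_integer_token <- function(x) {
  !is.na(x) && grepl("^[0-9]+$", x)
}
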