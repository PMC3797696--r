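#' Map a CDS nucleotide position to its codon index
#'
#' Both coordinates are 1-based: nucleotides 1-3 form codon 1 (the initiator
#' methionine), so codon = `ceiling(pos / 3)`. CDS position 388 lies in codon
#' 130.
#'
#' @param cds_pos 1-based CDS nucleotide position(s).
#' @param cds_length Optional CDS length; positions beyond it error.
#' @return Integer codon index, same length as `cds_pos`.
#' @export
cds_pos_to_codon <- function(cds_pos, cds_length = NULL) {
  if (any(cds_pos < 1) || any(cds_pos != round(cds_pos))) {
    abort_validation("cds_pos must be a positive integer")
  }
  if (!is.null(cds_length) && any(cds_pos > cds_length)) {
    abort_validation(sprintf("cds_pos %s beyond CDS length %d",
                             cds_pos[cds_pos > cds_length][1], cds_length))
  }
  as.integer(ceiling(cds_pos / 3))
}

translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds)) abort_validation("CDS must contain only A, C, G, T")
  # no.init.codon: plain codon-table semantics (no initiator-Met special case)
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "error"))
}

#' Annotate a tandem duplication within a coding sequence
#'
#' A tandem duplication copies `dup_length_nt` nucleotides starting at
#' 1-based CDS position `dup_start` and inserts the copy immediately after
#' the original. The annotation distinguishes three outcomes:
#'
#' * frameshift - length not a multiple of 3 (`in_frame = FALSE`,
#'   `n_residues = 0`);
#' * codon-aligned in-frame duplication - `dup_start` on a codon boundary:
#'   a whole run of residues is duplicated, reported as `residue_first` to
#'   `residue_last` (e.g. a 513 nt duplication starting at residue 528
#'   duplicates residues 528-698, 171 residues);
#' * codon-internal in-frame duplication - length a multiple of 3 but the
#'   start inside a codon: the shifted junction creates novel codons, so the
#'   event is reported as an insertion (`inserted_residues` after residue
#'   `inserted_after`), determined by translating the mutated CDS and
#'   locating the longest common prefix with the reference protein (ties
#'   resolve to the most C-terminal placement, matching HGVS practice).
#'
#' @param cds_sequence Reference coding sequence (A/C/G/T, length a multiple
#'   of 3).
#' @param dup_start 1-based CDS position of the first duplicated nucleotide.
#' @param dup_length_nt Number of duplicated nucleotides.
#' @return One-row tibble: `in_frame`, `dup_length_nt`, `n_residues`,
#'   `residue_first`, `residue_last`, `inserted_after`, `inserted_residues`,
#'   `mutant_cds`.
#' @export
annotate_tandem_duplication <- function(cds_sequence, dup_start, dup_length_nt) {
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3L != 0L) abort_validation("CDS length must be a multiple of 3")
  if (dup_start < 1 || dup_length_nt < 1 || dup_start + dup_length_nt - 1 > n) {
    abort_validation("duplicated interval must lie within the CDS")
  }
  dup_unit <- substr(cds_sequence, dup_start, dup_start + dup_length_nt - 1)
  mutant <- paste0(substr(cds_sequence, 1, dup_start + dup_length_nt - 1),
                   dup_unit,
                   substr(cds_sequence, dup_start + dup_length_nt, n))
  in_frame <- dup_length_nt %% 3L == 0L
  out <- tibble(in_frame = in_frame,
                dup_length_nt = as.integer(dup_length_nt),
                n_residues = 0L,
                residue_first = NA_integer_, residue_last = NA_integer_,
                inserted_after = NA_integer_, inserted_residues = NA_character_,
                mutant_cds = mutant)
  if (!in_frame) return(out)

  out$n_residues <- as.integer(dup_length_nt / 3L)
  if ((dup_start - 1L) %% 3L == 0L) {
    # codon-aligned: whole residues duplicated
    out$residue_first <- as.integer((dup_start + 2L) %/% 3L)
    out$residue_last <- out$residue_first + out$n_residues - 1L
  } else {
    # codon-internal: report as an insertion via full translation
    ref_prot <- translate_cds(cds_sequence)
    mut_prot <- translate_cds(mutant)
    p <- common_prefix_length(ref_prot, mut_prot)
    # most C-terminal placement: slide right while the insertion repeats
    ins <- substr(mut_prot, p + 1L, p + out$n_residues)
    if (substr(mut_prot, p + out$n_residues + 1L, nchar(mut_prot)) !=
        substr(ref_prot, p + 1L, nchar(ref_prot))) {
      abort_runtime("internal error: duplication does not resolve to a clean insertion")
    }
    out$inserted_after <- as.integer(p)
    out$inserted_residues <- ins
  }
  out
}

common_prefix_length <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- min(length(av), length(bv))
  same <- av[seq_len(m)] == bv[seq_len(m)]
  if (all(same)) m else which(!same)[1] - 1L
}

#' Annotate a single-nucleotide variant at protein level
#'
#' Substitutes `alt` at 1-based CDS position `cds_pos`, translates the
#' affected codon with the standard genetic code and returns the protein
#' change in `<ref><codon><alt>` form (e.g. `G130S` for c.388G>A in a CDS
#' with glycine at codon 130). Synonymous changes report identical letters.
#'
#' @param cds_sequence Reference coding sequence.
#' @param cds_pos 1-based CDS position of the variant.
#' @param alt Alternate nucleotide (must differ from the reference base).
#' @return Protein-change string.
#' @export
annotate_snv <- function(cds_sequence, cds_pos, alt) {
  cds_sequence <- toupper(cds_sequence)
  alt <- toupper(alt)
  n <- nchar(cds_sequence)
  if (cds_pos < 1 || cds_pos > n) abort_validation("cds_pos outside the CDS")
  if (!alt %in% c("A", "C", "G", "T")) abort_validation("alt must be one of A, C, G, T")
  ref_base <- substr(cds_sequence, cds_pos, cds_pos)
  if (ref_base == alt) {
    abort_validation(sprintf("alt equals the reference base '%s' at CDS position %d",
                             ref_base, cds_pos))
  }
  codon_i <- cds_pos_to_codon(cds_pos, n)
  codon_start <- (codon_i - 1L) * 3L + 1L
  ref_codon <- substr(cds_sequence, codon_start, codon_start + 2L)
  mut_codon <- ref_codon
  substr(mut_codon, (cds_pos - 1L) %% 3L + 1L, (cds_pos - 1L) %% 3L + 1L) <- alt
  paste0(translate_cds(ref_codon), codon_i, translate_cds(mut_codon))
}
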