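#' Expected variant allele fraction under a clonal copy-number model
#'
#' For a locus with `copy_number` total copies of which `mutant_copies` carry
#' the variant in the aberrant clone, diluted by normal diploid wild-type
#' cells to clone fraction `clonality` (c), the expected fraction of variant
#' reads is
#' `mutant_copies * c / (copy_number * c + 2 * (1 - c))`.
#' A fully clonal UPD homozygote (2, 2, 1) gives 1; a gain duplicating the
#' mutant allele (3, 2, 1) gives 2/3; a heterozygous variant in half the
#' cells (2, 1, 0.5) gives 0.25.
#'
#' @param copy_number Total copies at the locus in the aberrant clone
#'   (>= 1).
#' @param mutant_copies Copies carrying the variant (0 to `copy_number`).
#' @param clonality Fraction of cells in the aberrant clone, in `[0, 1]`.
#' @return Expected VAF (vectorised with recycling).
#' @export
expected_vaf <- function(copy_number, mutant_copies, clonality) {
  if (any(copy_number < 1) || any(copy_number != round(copy_number))) {
    abort_validation("copy_number must be a positive integer")
  }
  if (any(mutant_copies < 0) || any(mutant_copies > copy_number)) {
    abort_validation("need 0 <= mutant_copies <= copy_number")
  }
  if (any(clonality < 0) || any(clonality > 1)) {
    abort_validation("clonality must be in [0, 1]")
  }
  denom <- copy_number * clonality + 2 * (1 - clonality)
  ifelse(denom == 0, 0, mutant_copies * clonality / denom)
}

# Mechanisms compatible with an overlapping lesion kind. Under a GAIN the
# locus has three copies, so allele fractions come in thirds and no 1/2
# "heterozygous" state exists; under UPD or DEL a lesion-independent
# heterozygous variant remains a competing explanation.
mechanism_models <- function(overlapping_kind) {
  switch(overlapping_kind,
    none = tibble(mechanism = "heterozygous", copy_number = 2L, mutant_copies = 1L),
    UPD = tibble(mechanism = c("UPD_homozygous", "heterozygous"),
                 copy_number = c(2L, 2L), mutant_copies = c(2L, 1L)),
    GAIN = tibble(mechanism = c("gain_amplified_mutant", "gain_retained_wildtype"),
                  copy_number = c(3L, 3L), mutant_copies = c(2L, 1L)),
    DEL = tibble(mechanism = c("hemizygous_deleted_locus", "heterozygous"),
                 copy_number = c(1L, 2L), mutant_copies = c(1L, 1L)),
    abort_validation(paste0("overlapping_kind must be one of: none, ",
                            paste(LESION_KINDS, collapse = ", ")))
  )
}

#' Classify the genetic mechanism acting on mutant alleles
#'
#' For each variant observation, enumerates the dosage mechanisms compatible
#' with the lesion kind overlapping the locus (`none`, `DEL`, `GAIN` or
#' `UPD`), scores each by the binomial log-likelihood of the observed
#' alternate read count under its [expected_vaf()], and reports the
#' maximum-likelihood mechanism. When the winning log-likelihood exceeds the
#' runner-up by less than `decision_margin` natural-log units the call is
#' declared `ambiguous`. If clonality is unknown, it is profiled over a grid
#' and each mechanism takes its best clonality.
#'
#' Model VAFs are shrunk into `[error_rate, 1 - error_rate]` so that a fully
#' clonal homozygote keeps finite likelihood in the presence of occasional
#' reference-supporting reads (sequencing error).
#'
#' @param variants Variant tibble ([read_variants()]); must have
#'   `alt_reads` and `ref_reads`. An `overlapping_kind` column is used when
#'   present and the argument is `NULL`.
#' @param overlapping_kind Lesion kind overlapping each variant: scalar or
#'   vector over rows, values in `none`, `DEL`, `GAIN`, `UPD`.
#' @param clonality Known clone fraction (scalar or per-variant), or `NULL`
#'   to profile over `clonality_grid`.
#' @param min_depth Minimum total read depth (default 20); lower errors.
#' @param decision_margin Log-likelihood margin below which the call is
#'   `ambiguous` (default 2, about an e^2-fold likelihood ratio).
#' @param error_rate Sequencing error floor on model VAFs (default 0.01).
#' @param clonality_grid Grid for profile likelihood (default 0.05 to 1 by
#'   0.05).
#' @return The variant tibble plus columns `mechanism` (winner or
#'   `ambiguous`), `best_mechanism`, `expected_vaf`, `clonality_hat`,
#'   `margin` and a `log_likelihoods` list-column of named vectors.
#' @export
classify_mechanism <- function(variants, overlapping_kind = NULL, clonality = NULL,
                               min_depth = 20, decision_margin = 2,
                               error_rate = 0.01,
                               clonality_grid = seq(0.05, 1, by = 0.05)) {
  if (is.null(overlapping_kind)) {
    if (!"overlapping_kind" %in% names(variants)) {
      abort_validation("supply overlapping_kind as argument or column")
    }
    overlapping_kind <- variants$overlapping_kind
  }
  n <- nrow(variants)
  overlapping_kind <- rep_len(overlapping_kind, n)
  clon <- if (is.null(clonality)) rep(NA_real_, n) else rep_len(clonality, n)
  depth <- variants$ref_reads + variants$alt_reads
  if (any(depth < min_depth)) {
    abort_validation(sprintf("read depth %d below min_depth %d",
                             min(depth), min_depth))
  }

  calls <- map(seq_len(n), function(i) {
    models <- mechanism_models(overlapping_kind[i])
    grid <- if (is.na(clon[i])) clonality_grid else clon[i]
    scored <- map(seq_len(nrow(models)), function(m) {
      p <- expected_vaf(models$copy_number[m], models$mutant_copies[m], grid)
      p_eff <- pmin(pmax(p, error_rate), 1 - error_rate)
      ll <- dbinom(variants$alt_reads[i], depth[i], p_eff, log = TRUE)
      best <- which.max(ll)
      list(ll = ll[best], clonality = grid[best], vaf = p[best])
    })
    ll <- map_dbl(scored, "ll")
    names(ll) <- models$mechanism
    top <- which.max(ll)
    margin <- if (length(ll) > 1) ll[top] - max(ll[-top]) else Inf
    tibble(best_mechanism = models$mechanism[top],
           mechanism = if (margin < decision_margin) "ambiguous" else models$mechanism[top],
           expected_vaf = scored[[top]]$vaf,
           clonality_hat = scored[[top]]$clonality,
           margin = unname(margin),
           log_likelihoods = list(ll))
  })
  bind_cols(variants, bind_rows(calls))
}

#' Classify cis/trans configuration of two variants from colony genotypes
#'
#' Subcloning a PCR product spanning two variants into bacterial colonies
#' separates the two parental alleles; the joint genotype counts over
#' colonies then reveal the phase. Variants on different alleles (trans,
#' compound heterozygosity) yield only single-mutant colonies; variants on
#' the same allele (cis) yield double-mutant and wild-type colonies; a
#' single real variant yields one single-mutant class. Mixed patterns, or
#' wild-type colonies alongside both single-mutant classes, are
#' inconclusive.
#'
#' @param colonies Named list, vector or one-row tibble with counts
#'   `a_only`, `b_only`, `both`, `neither`.
#' @param min_colonies Minimum total colonies for a call (default 10);
#'   below, the result is `inconclusive` and flagged.
#' @return One-row tibble: `call` (one of `trans_compound_heterozygous`,
#'   `cis_same_allele`, `single_variant`, `inconclusive`), `n_colonies`,
#'   `flagged_low_count`.
#' @export
classify_phase <- function(colonies, min_colonies = 10) {
  cl <- as.list(colonies)
  needed <- c("a_only", "b_only", "both", "neither")
  if (!all(needed %in% names(cl))) {
    abort_validation(paste0("colonies must have counts: ",
                            paste(needed, collapse = ", ")))
  }
  cnt <- vapply(cl[needed], function(x) as.numeric(x[1]), numeric(1))
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    abort_validation("colony counts must be non-negative integers")
  }
  total <- sum(cnt)
  if (total < min_colonies) {
    return(tibble(call = "inconclusive", n_colonies = total,
                  flagged_low_count = TRUE))
  }
  a <- cnt[["a_only"]]; b <- cnt[["b_only"]]
  both <- cnt[["both"]]; neither <- cnt[["neither"]]
  call <- if (a > 0 && b > 0 && both == 0 && neither == 0) {
    "trans_compound_heterozygous"
  } else if (both > 0 && a == 0 && b == 0) {
    "cis_same_allele"
  } else if (both == 0 && xor(a > 0, b > 0)) {
    "single_variant"
  } else {
    "inconclusive"
  }
  tibble(call = call, n_colonies = total, flagged_low_count = FALSE)
}
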