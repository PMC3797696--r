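# Shared fixture builders and independent oracles.

random_segments <- function(n, n_samples = 10, chrom = "chr11",
                            max_pos = 10000, max_len = 500, seed = 1,
                            kinds = c("DEL", "GAIN", "UPD")) {
  withr::with_seed(seed, {
    start <- sample.int(max_pos - 1L, n, replace = TRUE) - 1L
    len <- sample.int(max_len, n, replace = TRUE)
    tibble::tibble(
      sample_id = sprintf("S%03d", sample.int(n_samples, n, replace = TRUE)),
      chrom = chrom,
      start = start,
      end = pmin(start + len, as.integer(max_pos)),
      kind = sample(kinds, n, replace = TRUE)
    ) |> dplyr::distinct()
  })
}

samples_for <- function(segments, diagnosis = "de novo AML") {
  ids <- sort(unique(segments$sample_id))
  tibble::tibble(sample_id = ids, patient_id = sub("^S", "P", ids),
                 diagnosis = diagnosis)
}

# random coding sequence: ATG start, no stop codons
random_cds <- function(n_codons, seed = 1) {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  withr::with_seed(seed,
    paste0("ATG", paste(sample(codons, n_codons - 1, replace = TRUE), collapse = "")))
}

translate_str <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE))
}

# Independent two-sided exact-test oracle: enumerate every table with the
# observed margins and sum point probabilities (direct choose() arithmetic)
# not exceeding the observed one.
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; n1 <- a + b; c1 <- a + c
  ks <- max(0, n1 + c1 - N):min(n1, c1)
  probs <- choose(c1, ks) * choose(N - c1, n1 - ks) / choose(N, n1)
  sum(probs[probs <= probs[ks == a] * (1 + 1e-7)])
}

# Per-base brute-force support count (the sweep-line oracle)
support_oracle <- function(segments, kind, at) {
  seg <- segments[segments$kind == kind, ]
  vapply(at, function(p) {
    length(unique(seg$sample_id[seg$start <= p & seg$end > p]))
  }, integer(1))
}

# support of a profile at single bases, 0 outside
profile_at <- function(profile, at) {
  vapply(at, function(p) {
    hit <- profile$start <= p & profile$end > p
    if (any(hit)) profile$support[hit][1] else 0L
  }, integer(1))
}

write_bed12 <- function(path, rows) {
  # rows: list of list(chrom, start, end, name, strand, blocks = matrix start0/end)
  lines <- vapply(rows, function(r) {
    bl <- r$blocks
    sizes <- paste(bl[, 2] - bl[, 1], collapse = ",")
    offsets <- paste(bl[, 1] - r$start, collapse = ",")
    paste(r$chrom, r$start, r$end, r$name, 0, r$strand, r$start, r$end, "0",
          nrow(bl), sizes, offsets, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}
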