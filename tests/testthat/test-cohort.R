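two_sample_patient <- function() {
  samples <- tibble::tibble(
    sample_id = c("S1a", "S1b", "S2"),
    patient_id = c("P1", "P1", "P2"),
    diagnosis = c("PMF", "post-PMF AML", "de novo AML"))
  samples
}

test_that("recurrent lesions collapse within a patient but never across patients", {
  samples <- two_sample_patient()
  # identical UPD seen in both samples of patient P1
  seg <- tibble::tibble(
    sample_id = c("S1a", "S1b"), chrom = "chr11",
    start = 60e6, end = 134e6, kind = "UPD")
  out <- dedupe_recurrent(seg, samples)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sample_id, "S1a")  # earliest sample's coordinates kept

  # same coordinates in different patients: both retained
  seg$sample_id <- c("S1a", "S2")
  expect_equal(nrow(dedupe_recurrent(seg, samples)), 2L)

  # kind mismatch at the same locus: both retained
  seg <- tibble::tibble(sample_id = c("S1a", "S1b"), chrom = "chr11",
                        start = 1e6, end = 2e6, kind = c("DEL", "UPD"))
  expect_equal(nrow(dedupe_recurrent(seg, samples)), 2L)

  # below the reciprocal-overlap threshold: both retained
  seg <- tibble::tibble(sample_id = c("S1a", "S1b"), chrom = "chr11",
                        start = c(0, 5e6), end = c(10e6, 15e6), kind = "DEL")
  expect_equal(nrow(dedupe_recurrent(seg, samples, reciprocal_overlap = 0.9)), 2L)
  expect_equal(nrow(dedupe_recurrent(seg, samples, reciprocal_overlap = 0.5)), 1L)

  seg$sample_id[1] <- "unknown"
  expect_error(dedupe_recurrent(seg, samples), "unknown",
               class = "chromscan_validation_error")
})

test_that("cohort summary counts units and reports consistent percentages", {
  samples <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                            patient_id = sprintf("P%02d", 1:10),
                            diagnosis = rep(c("PV", "ET"), each = 5))
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          start = integer(), end = integer(), kind = character())
  s <- summarize_cohort(empty, samples)
  expect_equal(s$n_with_lesion, c(0, 0, 0))
  expect_equal(s$frequency_pct[s$diagnosis == "total"], 0)

  seg <- tibble::tibble(sample_id = samples$sample_id, chrom = "chr11",
                        start = 0L, end = 100L, kind = "DEL")
  s <- summarize_cohort(seg, samples)
  expect_equal(s$frequency_pct[s$diagnosis == "total"], 100)

  # permutation invariance
  s2 <- summarize_cohort(seg[sample(nrow(seg)), ], samples[sample(nrow(samples)), ])
  expect_equal(sort(s2$n), sort(s$n))
  expect_equal(glance(s2)$n_with_lesion, glance(s)$n_with_lesion)

  # reported percentage always equals the ratio of the reported integers
  tot <- s2[s2$diagnosis == "total", ]
  expect_equal(tot$frequency_pct, round(100 * tot$n_with_lesion / tot$n, 1))
})

test_that("patient-level counting credits a twice-sampled patient once", {
  samples <- two_sample_patient()
  seg <- tibble::tibble(sample_id = c("S1a", "S1b"), chrom = "chr11",
                        start = 0L, end = 100L, kind = "UPD")
  by_sample <- glance(summarize_cohort(seg, samples, unit = "sample"))
  by_patient <- glance(summarize_cohort(seg, samples, unit = "patient"))
  expect_equal(by_sample$n, 3)
  expect_equal(by_sample$n_with_lesion, 2)
  expect_equal(by_patient$n, 2)
  expect_equal(by_patient$n_with_lesion, 1)
})

test_that("association testing builds the group-by-lesion table and errors on bad groups", {
  samples <- tibble::tibble(sample_id = sprintf("S%02d", 1:20),
                            patient_id = sprintf("P%02d", 1:20),
                            diagnosis = rep(c("post-PMF AML", "PMF"), each = 10))
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          start = integer(), end = integer(), kind = character())
  res <- associate_lesions(empty, samples, "post-PMF AML", "PMF")
  expect_equal(res$p_two_sided, 1)

  expect_error(associate_lesions(empty, samples, "PMF", "PMF"),
               "disjoint", class = "chromscan_validation_error")
  expect_error(associate_lesions(empty, samples, "post-PV AML", "PMF"),
               "no members", class = "chromscan_validation_error")

  seg <- tibble::tibble(sample_id = c("S01", "S02", "S03", "S11"),
                        chrom = "chr11", start = 0L, end = 100L,
                        kind = c("DEL", "UPD", "GAIN", "DEL"))
  res <- associate_lesions(seg, samples, "post-PMF AML", "PMF")
  expect_equal(unname(res$table[1, ]), c(3, 7))
  expect_equal(unname(res$table[2, ]), c(1, 9))

  # predicates restrict which segments count
  res_del <- associate_lesions(seg, samples, "post-PMF AML", "PMF",
                               predicate = lesion_kind("DEL"))
  expect_equal(unname(res_del$table[, 1]), c(1, 1))
  res_reg <- associate_lesions(seg, samples, "post-PMF AML", "PMF",
                               predicate = lesion_overlaps("chr11", 200, 300))
  expect_equal(sum(res_reg$table[, 1]), 0)
})

test_that("a planted regional enrichment is detected in nearly all replicates", {
  # group A carries lesions over the region at 50%, group B at 5%
  region <- c(1e6, 2e6)
  n_detect <- 0
  for (seed in 0:199) {
    detected <- withr::with_seed(seed, {
      nA <- 40; nB <- 200
      samples <- tibble::tibble(
        sample_id = sprintf("S%03d", 1:(nA + nB)),
        patient_id = sprintf("P%03d", 1:(nA + nB)),
        diagnosis = rep(c("post-PMF AML", "PMF"), c(nA, nB)))
      carrier <- c(runif(nA) < 0.5, runif(nB) < 0.05)
      seg <- tibble::tibble(sample_id = samples$sample_id[carrier],
                            chrom = "chr11", start = region[1], end = region[2],
                            kind = "DEL")
      res <- associate_lesions(seg, samples, "post-PMF AML", "PMF",
                               predicate = lesion_overlaps("chr11", region[1], region[2]))
      res$p_two_sided < 0.05
    })
    n_detect <- n_detect + detected
  }
  expect_gte(n_detect, 190)  # >= 95% of 200 replicates
})

test_that("aberration tallies count kinds after exclusions", {
  seg <- random_segments(300, n_samples = 30, seed = 3)
  samples <- samples_for(seg)
  tal <- tally_aberrations(seg, samples)
  expect_equal(tal$n_deletions + tal$n_gains + tal$n_upds, nrow(seg))
  expect_equal(tal$n_excluded_complex, 0L)

  all_ids <- unique(seg$sample_id)
  tal0 <- tally_aberrations(seg, samples, exclude = all_ids)
  expect_equal(unlist(tal0[1, 1:3], use.names = FALSE), c(0L, 0L, 0L))
  expect_equal(tal0$n_excluded_complex, length(all_ids))
})
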