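flat_track <- function(depths, chrom = "chr11") {
  tibble::tibble(chrom = chrom, pos = seq_along(depths), depth = depths)
}

test_that("chromosome-total normalisation yields scale-invariant fractions", {
  tr <- flat_track(c(10, 30, 60))
  norm <- normalize_track(tr)
  expect_equal(norm$value, c(0.1, 0.3, 0.6))
  expect_equal(sum(norm$value), 1, tolerance = 1e-9)

  uniform <- normalize_track(flat_track(rep(7, 50)))
  expect_true(all(abs(uniform$value - 1 / 50) < 1e-12))

  seven_x <- flat_track(7 * c(10, 30, 60))
  expect_equal(normalize_track(seven_x)$value, norm$value)

  expect_error(normalize_track(flat_track(c(0, 0))),
               class = "chromscan_validation_error")
})

test_that("control-pool reference is the per-position median", {
  mk <- function(vals) tibble::tibble(chrom = "chr11", pos = 1:3, value = vals)
  controls <- list(mk(c(0.1, 0.5, 0)), mk(c(0.2, 0.3, 0)), mk(c(0.9, 0.2, 0)))
  ref <- build_reference(controls)
  expect_equal(ref$value, c(0.2, 0.3, 0))
  expect_equal(ref$masked, c(FALSE, FALSE, TRUE))

  same <- build_reference(list(mk(c(0.2, 0.3, 0.5)), mk(c(0.2, 0.3, 0.5)),
                               mk(c(0.2, 0.3, 0.5))))
  expect_equal(same$value, c(0.2, 0.3, 0.5))

  expect_error(build_reference(controls[1:2]), "at least 3",
               class = "chromscan_validation_error")

  # only positions present in every control are used
  short <- list(mk(c(0.1, 0.2, 0.3)), mk(c(0.1, 0.2, 0.3)),
                tibble::tibble(chrom = "chr11", pos = 1:2, value = c(0.5, 0.5)))
  expect_equal(build_reference(short)$pos, c(1, 2))
})

test_that("log2 ratio is zero against itself and exact on doubled coverage", {
  norm <- normalize_track(flat_track(c(10, 20, 30, 40)))
  rt <- log2_ratio_track(norm, norm)
  expect_true(all(rt$log2_ratio == 0))

  # doubling checked without renormalisation: values passed straight through
  case <- tibble::tibble(chrom = "chr11", pos = 1:4, value = c(0.2, 0.4, 0.6, 0.8))
  ref <- tibble::tibble(chrom = "chr11", pos = 1:4, value = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(log2_ratio_track(case, ref)$log2_ratio, rep(1, 4))

  # zero-reference positions masked at pseudocount 0, kept with a pseudocount
  ref0 <- tibble::tibble(chrom = "chr11", pos = 1:4, value = c(0.1, 0, 0.3, 0.4))
  rt0 <- log2_ratio_track(case, ref0)
  expect_true(rt0$masked[2])
  expect_true(is.na(rt0$log2_ratio[2]))
  rtp <- log2_ratio_track(case, ref0, pseudocount = 1e-4)
  expect_false(any(rtp$masked))

  far <- tibble::tibble(chrom = "chr11", pos = 100:103, value = rep(0.25, 4))
  expect_error(log2_ratio_track(case, far), "no positions",
               class = "chromscan_validation_error")
})

# a panel large enough that the spike is a negligible share of the
# chromosome-total normaliser (as on a real exome)
spiked_setup <- function(seed, copy_ratio = 1.5, depth = 100, spike = TRUE) {
  targets <- simulate_targets(n_targets = 100, seed = 3)
  ext <- tibble::tibble(target_id = "dup_target", chrom = "chr11",
                        start = max(targets$end) + 5000,
                        end = max(targets$end) + 5513)
  targets <- dplyr::bind_rows(targets, ext)
  spikes <- if (spike) {
    tibble::tibble(chrom = "chr11", start = ext$start, end = ext$end,
                   copy_ratio = copy_ratio)
  } else NULL
  sim <- simulate_depth_tracks(targets, seed = seed, depth = depth,
                               n_controls = 8, spikes = spikes)
  ref <- build_reference(lapply(sim$controls, normalize_track))
  ratio <- log2_ratio_track(normalize_track(sim$case), ref)
  list(targets = targets, spike = ext, ratio = ratio)
}

test_that("a spiked heterozygous duplication is called as a focal gain", {
  s <- spiked_setup(seed = 13)
  in_spike <- s$ratio$pos > s$spike$start & s$ratio$pos <= s$spike$end
  expect_lt(abs(mean(s$ratio$log2_ratio[in_spike]) - log2(1.5)), 0.05)

  calls <- call_focal_events(s$ratio, s$targets)
  gains <- calls[calls$direction == "gain", ]
  expect_equal(nrow(gains), 1L)
  covered <- min(gains$end, s$spike$end) - max(gains$start, s$spike$start)
  expect_gte(covered / (s$spike$end - s$spike$start), 0.9)
  expect_true("dup_target" %in% gains$targets_hit[[1]])
})

test_that("a spiked hemizygous deletion is called as a loss near -1", {
  s <- spiked_setup(seed = 29, copy_ratio = 0.5)
  calls <- call_focal_events(s$ratio, s$targets)
  losses <- calls[calls$direction == "loss", ]
  expect_equal(nrow(losses), 1L)
  expect_equal(losses$mean_log2, -1, tolerance = 0.1)
})

test_that("spike-free data yields no calls and calls stay within targets", {
  s <- spiked_setup(seed = 41, spike = FALSE)
  expect_equal(nrow(call_focal_events(s$ratio, s$targets)), 0L)

  s2 <- spiked_setup(seed = 13)
  calls <- call_focal_events(s2$ratio, s2$targets)
  for (i in seq_len(nrow(calls))) {
    inside <- s2$targets$start <= calls$start[i] & s2$targets$end >= calls$end[i]
    # boundaries lie on observed positions within a single target here
    expect_true(any(inside))
    expect_true((calls$start[i] + 1) %in% s2$ratio$pos)
    expect_true(calls$end[i] %in% s2$ratio$pos)
  }
})

test_that("detection power grows with depth and copy ratio", {
  # detection = a gain call recovering >= 90% of the spiked interval, so
  # chance overlap with low-depth noise runs does not count as power
  grid <- expand.grid(depth = c(20, 50, 100), ratio = c(1.25, 1.5, 2.0))
  rate <- mapply(function(depth, ratio) {
    hits <- vapply(1:8, function(seed) {
      s <- spiked_setup(seed = 100 + seed, copy_ratio = ratio, depth = depth)
      calls <- call_focal_events(s$ratio, s$targets)
      any(calls$direction == "gain" &
            (pmin(calls$end, s$spike$end) - pmax(calls$start, s$spike$start)) >=
              0.9 * (s$spike$end - s$spike$start))
    }, logical(1))
    mean(hits)
  }, grid$depth, grid$ratio)
  power <- matrix(rate, nrow = 3, dimnames = list(c("20", "50", "100"),
                                                  c("1.25", "1.5", "2.0")))
  # non-decreasing along depth for each ratio, and along ratio for each depth
  expect_true(all(apply(power, 2, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(power, 1, function(x) all(diff(x) >= 0))))
  expect_equal(power["100", "2.0"], 1)
})
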