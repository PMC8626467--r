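test_that("event typing follows the Gain/LOH/HD rules against baseline ploidy", {
  segs <- make_segments("S1", list(
    list(chrom = 1, start = 1, end = 1e6, maj = 2, min = 0), # LOH (total 2, not > 2)
    list(chrom = 1, start = 2e6, end = 3e6, maj = 3, min = 1), # Gain (4 > 2)
    list(chrom = 1, start = 4e6, end = 5e6, maj = 0, min = 0), # HD
    list(chrom = 1, start = 6e6, end = 1e7, maj = 1, min = 1),
    list(chrom = 2, start = 1, end = 1e7, maj = 1, min = 1),
    list(chrom = 3, start = 1, end = 1e7, maj = 1, min = 1)
  ))
  ev <- derive_events(segs)
  expect_setequal(
    paste(ev$type, ev$start),
    c("LOH 1", "Gain 2e+06", "HD 4e+06")
  )
  expect_true(all(ev$clonality == "clonal"))
  # 3+0 emits both LOH and Gain; subclonal state emits subclonal events
  segs2 <- make_segments("S2", list(
    list(chrom = 1, start = 1, end = 1e6, maj = 3, min = 0, frac = 0.6),
    list(chrom = 1, start = 2e6, end = 1e7, maj = 1, min = 1)
  ))
  ev2 <- derive_events(segs2)
  expect_setequal(ev2$type, c("LOH", "Gain"))
  expect_true(all(ev2$clonality == "subclonal"))
  # WGD sample: Gain baseline is 4
  segs3 <- make_segments("S3", list(
    list(chrom = 1, start = 1, end = 9e6, maj = 2, min = 2),
    list(chrom = 1, start = 9e6 + 1, end = 1e7, maj = 3, min = 1)
  ))
  expect_equal(nrow(derive_events(segs3)), 0) # 2:2 baseline, 3+1 total 4 not > 4
})

test_that("frequency landscape partitions at breakpoints and conserves mass", {
  ev <- tibble::tibble(
    sample_id = c("a", "b"), chrom = "1",
    start = c(1e6, 2e6), end = c(3e6 - 1, 4e6 - 1),
    type = "LOH", clonality = "clonal"
  )
  ls <- frequency_landscape(ev, toy_genome(), "LOH", n_samples = 2)
  expect_equal(nrow(ls), 3)
  expect_equal(ls$freq, c(0.5, 1.0, 0.5))
  # conservation: sum freq * len * n == total event-covered length
  lhs <- sum(ls$freq * (ls$end - ls$start + 1) * 2)
  rhs <- sum(ev$end - ev$start + 1)
  expect_equal(lhs, rhs)
  # identical intervals collapse to one at frequency 1
  ev2 <- dplyr::mutate(ev, start = 1e6, end = 3e6 - 1)
  ls2 <- frequency_landscape(ev2, toy_genome(), "LOH", n_samples = 2)
  expect_equal(nrow(ls2), 1)
  expect_equal(ls2$freq, 1)
  # no events: empty landscape
  expect_equal(nrow(frequency_landscape(ev[0, ], toy_genome(), "LOH", 2)), 0)
})

test_that("a universally shared region is significant; permutations reproduce bit-for-bit", {
  set.seed(5)
  n <- 12
  shared <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n), chrom = "2",
    start = 4e6, end = 4.5e6, type = "LOH", clonality = "clonal"
  )
  noise <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n), chrom = "1",
    start = round(runif(n, 1, 8e6)), type = "LOH", clonality = "clonal"
  ) |> dplyr::mutate(end = start + 5e5)
  ev <- dplyr::bind_rows(shared, noise)
  r1 <- permutation_test(ev, toy_genome(), n_samples = n, n_perm = 999, seed = 99)
  hit <- r1[r1$chrom == "2" & r1$start == 4e6, ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$q, 0.05)
  r2 <- permutation_test(ev, toy_genome(), n_samples = n, n_perm = 999, seed = 99)
  expect_identical(r1, r2)
  expect_error(
    permutation_test(
      dplyr::mutate(ev, end = start + 2e7), toy_genome(),
      n_samples = n, n_perm = 1
    ),
    "longer than its chromosome"
  )
})

test_that("permutation p-values are super-uniform under a scattered null", {
  # events placed uniformly at random: observed intervals are themselves
  # draws from the null, so p-values must be (super-)uniform
  pvals <- c()
  for (s in 1:30) {
    set.seed(300 + s)
    ev <- tibble::tibble(
      sample_id = sprintf("s%d", 1:8),
      chrom = sample(c("1", "2", "3"), 8, replace = TRUE),
      start = round(runif(8, 1, 9e6)), type = "Gain", clonality = "clonal"
    ) |> dplyr::mutate(end = start + 4e5)
    r <- permutation_test(ev, toy_genome(), n_samples = 8, n_perm = 60, seed = s)
    pvals <- c(pvals, min(r$p_perm)) # genome-wide max statistic per run
  }
  # the minimum p across intervals tracks the max-frequency statistic the
  # null is built on: it should not be systematically small
  expect_gte(mean(pvals > 0.05), 0.8)
  expect_gte(min(pvals), 1 / 61)
})

test_that("region exclusions: HLA overlap, telomeric, singleton", {
  g <- genome_model(
    chrom_lengths = c(`6` = 1e7),
    excluded_regions = tibble::tibble(
      chrom = "6", start = 4e6, end = 5e6, label = "HLA"
    )
  )
  regions <- tibble::tibble(
    chrom = "6",
    start = c(4.5e6, 2e6, 9.5e6, 3e6),
    end = c(6e6, 2.5e6, 9.9e6, 3.5e6),
    type = "LOH",
    n_samples_mut = c(5, 4, 6, 1),
    freq = c(0.5, 0.4, 0.6, 0.1),
    p_perm = 0.001, q = 0.004, significant = TRUE
  )
  out <- filter_regions(regions, g)
  expect_equal(out$excluded_reason, c("HLA", "none", "telomeric", "singleton"))
})

test_that("cna_recurrence runs end to end on a simulated cohort", {
  cohort <- make_fixture("tiny", seed = 5)
  res <- cna_recurrence(cohort$segments, cohort$metadata, toy_genome(),
    n_perm = 100, seed = 42
  )
  expect_true(all(c("p_perm", "q", "excluded_reason") %in% names(res)))
  expect_true(all(res$p_perm >= 1 / 101 & res$p_perm <= 1))
  expect_true(all(res$q >= res$p_perm - 1e-12))
  # the catalog's high-prevalence LOH region should surface as significant
  loh <- res[res$type == "LOH" & res$chrom == "1" & res$significant &
    res$excluded_reason == "none", ]
  expect_gt(nrow(loh), 0)
})
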