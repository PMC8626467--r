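test_that("WGD call compares 2:2 against 1:1 genome fractions", {
  all22 <- make_segments("S1", list(
    list(chrom = 1, start = 1, end = 1e7, maj = 2, min = 2)
  ))
  all11 <- make_segments("S1", list(
    list(chrom = 1, start = 1, end = 1e7, maj = 1, min = 1)
  ))
  mixed <- make_segments("S1", list(
    list(chrom = 1, start = 1, end = 6e7, maj = 2, min = 2),
    list(chrom = 2, start = 1, end = 4e7, maj = 1, min = 1),
    list(chrom = 3, start = 1, end = 9e7, maj = 3, min = 1)
  ))
  expect_true(call_wgd(all22))
  expect_false(call_wgd(all11))
  expect_true(call_wgd(mixed)) # 60 Mb 2:2 vs 40 Mb 1:1
})

test_that("ploidy rule for WGD as a timeable event is strict at 3", {
  expect_equal(call_wgd_for_timing(c(3.2, 3.0, 2.0)), c(TRUE, FALSE, FALSE))
})

test_that("PGA and breakpoints on hand-computable toy cases", {
  flat <- make_segments("S1", list(
    list(chrom = 1, start = 1, end = 1e8, maj = 1, min = 1)
  ))
  r <- compute_pga(flat, wgd = FALSE)
  expect_equal(r$pga, 0)
  expect_equal(r$n_breakpoints, 0L)

  loh <- make_segments("S1", list(
    list(chrom = 1, start = 1, end = 4.5e7, maj = 1, min = 1),
    list(chrom = 1, start = 4.5e7 + 1, end = 5.5e7, maj = 1, min = 0),
    list(chrom = 1, start = 5.5e7 + 1, end = 1e8, maj = 1, min = 1)
  ))
  r2 <- compute_pga(loh, wgd = FALSE)
  expect_equal(r2$pga, 0.1)
  expect_equal(r2$n_breakpoints, 2L)

  wgd_flat <- make_segments("S1", list(
    list(chrom = 1, start = 1, end = 1e8, maj = 2, min = 2)
  ))
  expect_equal(compute_pga(wgd_flat, wgd = TRUE)$pga, 0)
  # row order invariance
  r3 <- compute_pga(loh[c(3, 1, 2), ], wgd = FALSE)
  expect_equal(r3, r2)
})

test_that("PGAn is the geometric mean of PGA and breakpoint count", {
  expect_equal(compute_pgan(0.25, 100), 5)
  expect_equal(compute_pgan(0, 40), 0)
  expect_equal(compute_pgan(1, 1), 1)
})

test_that("PCF dynamic program matches exhaustive search for n <= 12", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    y <- c(rnorm(n %/% 2, 0), rnorm(n - n %/% 2, sample(c(0, 3), 1)))
    gamma <- sample(c(0.5, 2, 5), 1)
    got <- pcf_segment(y, gamma)
    cost_got <- sum(vapply(seq_len(nrow(got)), function(k) {
      seg <- y[got$start_idx[k]:got$end_idx[k]]
      sum((seg - mean(seg))^2)
    }, numeric(1))) + gamma * (nrow(got) - 1)
    expect_equal(cost_got, pcf_oracle(y, gamma)$cost, tolerance = 1e-9)
  }
})

test_that("PCF on inter-mutation distance isolates an embedded tight run", {
  set.seed(22)
  bg <- sort(sample(1e7, 1000))
  bg <- bg[c(diff(bg) > 5000, TRUE)]
  run <- 5e6 + cumsum(c(0, rep(200, 8))) # 9 SNVs at 200 bp
  pos <- sort(c(bg, run))
  seg <- pcf_inter_mutation_distance(pos, gamma = 8)
  low <- seg[seg$mean_imd <= 1000, ]
  expect_equal(nrow(low), 1)
  expect_gte(low$n, 8) # the 8 tight inter-mutation distances
  # constant spacing gives a single segment
  expect_equal(nrow(pcf_inter_mutation_distance(seq(1, 1e6, by = 1000), 8)), 1)
  # single SNV: empty result
  expect_equal(nrow(pcf_inter_mutation_distance(42, 8)), 0)
  expect_error(pcf_inter_mutation_distance(c(5, 1), 8), "sorted")
})

test_that("kataegis detection enforces the six-SNV and 1-kb rules", {
  set.seed(23)
  background <- seq(1e5, 9.9e6, by = 1e5) # sparse background, 100-kb spacing
  make_sample <- function(extra) {
    make_variants("S1", 1, sort(c(background, extra)), 30, 90)
  }
  # 6 SNVs at 200 bp: one focus of exactly those SNVs
  f6 <- detect_kataegis(make_sample(5.05e6 + (0:5) * 200))
  expect_equal(nrow(f6), 1)
  expect_equal(f6$n_snvs, 6L)
  expect_lte(f6$mean_imd, 1000)
  # 5 SNVs at 200 bp: below the minimum, no focus
  f5 <- detect_kataegis(make_sample(5.05e6 + (0:4) * 200))
  expect_equal(nrow(f5), 0)
  # 12 SNVs at 900 bp: mean IMD 900 <= 1000, one focus
  f12 <- detect_kataegis(make_sample(5.05e6 + (0:11) * 900))
  expect_equal(nrow(f12), 1)
  expect_equal(f12$n_snvs, 12L)
  expect_equal(f12$mean_imd, 900)
})

test_that("injected foci are found and Poisson background yields none", {
  found <- 0L
  false_pos <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(100 + s)
    bg <- sort(ceiling(cumsum(rexp(120, rate = 1 / 1e5))))
    bg <- bg[bg < 9.5e6]
    focus_start <- 4e6
    focus <- focus_start + cumsum(c(0, sample(100:500, 7, replace = TRUE)))
    v_inj <- make_variants("S1", 1, sort(c(bg, focus)), 30, 90)
    v_null <- make_variants("S1", 1, bg, 30, 90)
    det <- detect_kataegis(v_inj)
    hit <- any(det$start <= min(focus) & det$end >= max(focus))
    found <- found + hit
    false_pos <- false_pos + nrow(detect_kataegis(v_null))
  }
  expect_equal(found, n_seeds)
  expect_equal(false_pos, 0L)
})

test_that("instability_metrics assembles per-sample rows", {
  cohort <- make_fixture("tiny", seed = 3)
  m <- instability_metrics(cohort$variants, cohort$segments, cohort$metadata)
  expect_equal(sort(m$sample_id), sort(cohort$metadata$sample_id))
  expect_true(all(m$pga >= 0 & m$pga <= 1))
  expect_equal(m$pgan, sqrt(m$pga * m$n_breakpoints))
  truth <- dplyr::arrange(cohort$truth$samples, sample_id)
  expect_equal(dplyr::arrange(m, sample_id)$wgd, truth$wgd)
})
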