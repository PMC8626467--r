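test_that("effective copy number weights states by fraction", {
  seg <- tibble::tibble(
    n_major_1 = c(1, 2, 0), n_minor_1 = c(1, 1, 0),
    frac_1 = c(1, 0.6, 1),
    n_major_2 = c(NA, 1, NA), n_minor_2 = c(NA, 1, NA),
    frac_2 = c(0, 0.4, 0)
  )
  expect_equal(effective_copy_number(seg), c(2.0, 2.6, 0.0))
})

test_that("multiplicity estimator recovers known configurations", {
  expect_equal(estimate_multiplicity(0.5, 1, 2, 1), 1L)
  # mutation on both copies of a duplicated allele
  expect_equal(estimate_multiplicity(0.5, 1, 4, 2), 2L)
  # low-purity het diploid clamps to 1
  expect_equal(estimate_multiplicity(0.25, 0.5, 2, 1), 1L)
  expect_error(estimate_multiplicity(0.5, 0.5, 0), "nt")
  expect_error(estimate_multiplicity(0.5, 1.2, 2), "purity")
})

test_that("CCF formula worked examples", {
  expect_equal(compute_ccf(0.25, 0.5, 2, 1), 1.0)
  expect_equal(compute_ccf(0.5, 1.0, 2, 1), 1.0)
  expect_equal(compute_ccf(0.1, 0.5, 2, 1), 0.4)
})

test_that("CCF identity holds on a purity x ccf grid in diploid regions", {
  # a variant at true CCF c in a clonal 1+1 region has VAF = purity*c/2
  grid <- tidyr::crossing(
    purity = seq(0.1, 1, by = 0.1),
    cc = seq(0.05, 1.2, by = 0.05)
  )
  vaf <- grid$purity * grid$cc / 2
  ccf <- compute_ccf(vaf, grid$purity, 2, 1)
  expect_equal(ccf, grid$cc, tolerance = 1e-12)
})

test_that("ccf is strictly increasing in vaf", {
  vaf <- seq(0.01, 1, by = 0.01)
  for (p in c(0.2, 0.5, 0.9)) {
    ccf <- compute_ccf(vaf, p, 2.6, 2)
    expect_true(all(diff(ccf) > 0))
  }
})

test_that("clonality CI agrees with the Clopper-Pearson oracle at all depths <= 30", {
  for (n in 1:30) {
    x <- 0:n
    got <- assign_clonality(x, n, purity = 0.6, nt = 2, multiplicity = 1)
    oracle <- t(vapply(
      x,
      function(xx) stats::binom.test(xx, n)$conf.int,
      numeric(2)
    ))
    factor <- (0.6 * 2 + 2 * 0.4) / (0.6 * 1)
    expect_equal(got$ccf_low, oracle[, 1] * factor, tolerance = 1e-10)
    expect_equal(got$ccf_high, oracle[, 2] * factor, tolerance = 1e-10)
  }
})

test_that("binomial clonality calls: worked examples and boundaries", {
  r1 <- assign_clonality(45, 90, purity = 0.5, nt = 2, multiplicity = 1)
  expect_equal(r1$status, "clonal")
  expect_equal(r1$ccf, 1)
  r2 <- assign_clonality(10, 100, purity = 0.5, nt = 2, multiplicity = 1)
  expect_equal(r2$status, "subclonal")
  expect_equal(r2$ccf, 0.4)
  r3 <- assign_clonality(90, 90, purity = 0.5, nt = 2, multiplicity = 1)
  expect_equal(r3$status, "clonal")
  expect_error(assign_clonality(0, 0, 0.5, 2, 1), "depth")
})

test_that("clonal and subclonal variants are recovered from simulated reads", {
  set.seed(101)
  n <- 500
  depth <- 90
  purity <- 0.5
  # true clonal: VAF = purity * 1 * 1 / 2 = 0.25; true CCF 0.4: VAF = 0.1
  alt_clonal <- rbinom(n, depth, purity * 1 / 2)
  alt_sub <- rbinom(n, depth, purity * 0.4 / 2)
  call_c <- assign_clonality(alt_clonal, depth, purity, 2, 1)
  call_s <- assign_clonality(alt_sub, depth, purity, 2, 1)
  expect_gte(mean(call_c$status == "clonal"), 0.9)
  expect_gte(mean(call_s$status == "subclonal"), 0.9)
})

test_that("WGD timing classification follows the NCBM rule", {
  expect_equal(classify_wgd_timing("clonal", 2, TRUE), "pre_wgd")
  expect_equal(classify_wgd_timing("clonal", 1, TRUE), "post_wgd")
  expect_equal(classify_wgd_timing("subclonal", 2, TRUE), "post_wgd")
  expect_equal(classify_wgd_timing("clonal", 2, FALSE), "not_applicable")
})

test_that("cohort ccf_calls joins segments and drops HD/uncovered variants", {
  segs <- make_segments("S1", list(
    list(chrom = 1, start = 1, end = 5e6, maj = 1, min = 1),
    list(chrom = 1, start = 5e6 + 1, end = 6e6, maj = 0, min = 0)
  ))
  vars <- make_variants("S1", 1, c(1e6, 5.5e6, 8e6), c(25, 10, 10), 90)
  meta <- make_meta("S1", purity = 0.5, ploidy = 2)
  expect_message(
    out <- ccf_calls(vars, segs, meta),
    "excluded"
  )
  expect_equal(nrow(out), 1) # HD variant and uncovered variant dropped
  expect_equal(attr(out, "dropped")$drop_reason, c("homozygous_deletion", "no_segment"))
  expect_equal(out$nt, 2)
})
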