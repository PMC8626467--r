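test_that("identical seeds give identical cohorts; different seeds differ", {
  c1 <- make_fixture("tiny", seed = 9)
  c2 <- make_fixture("tiny", seed = 9)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$segments, c2$segments)
  expect_identical(c1$truth$samples, c2$truth$samples)
  c3 <- make_fixture("tiny", seed = 10)
  expect_false(identical(c1$variants, c3$variants))
})

test_that("emitted VAFs concentrate at the CCF-purity-copy-number expectation", {
  cfg <- sim_config(
    groups = c(A = 1), purity_range = c(0.5, 0.5), wgd_probability = 0,
    max_subclones = 0, mutation_rate = 60,
    event_catalog = default_event_catalog()[0, ],
    kataegis = list(n_foci_range = c(0, 0), n_snvs_range = c(6, 6), spacing_mean = 300)
  )
  cohort <- simulate_cohort(cfg, seed = 11)
  v <- cohort$variants
  # all-clonal diploid tumor at purity 0.5: VAF expectation 0.25
  expect_gt(nrow(v), 800)
  expect_equal(
    sum(v$alt_count) / sum(v$depth),
    0.25,
    tolerance = 0.02
  )
  # binomial spread: variance of alt at depth d close to d p (1-p)
  d90 <- v[v$depth >= 85 & v$depth <= 95, ]
  expect_equal(
    var(d90$alt_count / d90$depth), 0.25 * 0.75 / 90,
    tolerance = 0.35
  )
})

test_that("recomputing CCF from emitted reads recovers true cluster peaks", {
  cfg <- sim_config(
    groups = c(A = 1), purity_range = c(0.7, 0.7), wgd_probability = 0,
    max_subclones = 1, subclone_ccf_range = c(0.45, 0.45),
    clonal_mut_fraction = 0.5, mutation_rate = 40,
    event_catalog = default_event_catalog()[0, ],
    kataegis = list(n_foci_range = c(0, 0), n_snvs_range = c(6, 6), spacing_mean = 300)
  )
  cohort <- simulate_cohort(cfg, seed = 12)
  v <- cohort$variants
  calls <- ccf_calls(v, cohort$segments, cohort$metadata) |>
    dplyr::inner_join(
      dplyr::select(v, sample_id, chrom, pos, true_cluster, true_ccf),
      by = c("sample_id", "chrom", "pos")
    )
  for (clu in unique(calls$true_cluster)) {
    truth <- calls$true_ccf[calls$true_cluster == clu][1]
    got <- mean(calls$ccf_point[calls$true_cluster == clu])
    expect_equal(got, truth, tolerance = 0.08)
  }
})

test_that("forced WGD produces 2:2-dominated segment tables and high ploidy", {
  cfg <- sim_config(
    groups = c(A = 3), wgd_probability = 1,
    event_catalog = default_event_catalog()[0, ]
  )
  cohort <- simulate_cohort(cfg, seed = 13)
  expect_true(all(cohort$truth$samples$wgd))
  expect_true(all(cohort$metadata$ploidy > 3))
  for (s in cohort$metadata$sample_id) {
    seg <- cohort$segments[cohort$segments$sample_id == s, ]
    expect_true(call_wgd(seg))
  }
})

test_that("catalog validation rejects bad prevalence, times and overlapping loci", {
  bad_prev <- default_event_catalog()
  bad_prev$prevalence[1] <- 1.4
  expect_error(sim_config(event_catalog = bad_prev), "prevalence")
  bad_t <- default_event_catalog()
  bad_t$true_rel_time[1] <- 2
  expect_error(sim_config(event_catalog = bad_t), "true_rel_time")
  overlap <- default_event_catalog()
  overlap$chrom[2] <- overlap$chrom[1]
  overlap$start[2] <- overlap$start[1] + 1e5
  overlap$end[2] <- overlap$end[1] + 1e5
  expect_error(sim_config(event_catalog = overlap), "disjoint")
  expect_error(sim_config(subclone_ccf_range = c(0.2, 1.4)), "sum-rule")
})

test_that("truth tables are consistent with emitted files", {
  cohort <- make_fixture("tiny", seed = 14)
  # every truth event of CNA type has a matching aberrant segment
  cna <- cohort$truth$events[cohort$truth$events$type != "driver", ]
  if (nrow(cna)) {
    for (k in seq_len(nrow(cna))) {
      seg <- cohort$segments[
        cohort$segments$sample_id == cna$sample_id[k] &
          cohort$segments$chrom == cna$chrom[k] &
          cohort$segments$start == cna$start[k],
      ]
      expect_equal(nrow(seg), 1)
    }
  }
  # cluster table wccf matches the truth wccf
  for (s in unique(cohort$truth$samples$sample_id)) {
    cl <- cohort$clusters[cohort$clusters$sample_id == s, ]
    expect_equal(
      compute_wccf(cl),
      cohort$truth$samples$wccf[cohort$truth$samples$sample_id == s]
    )
  }
  # kataegis truth foci exist among emitted variants
  kat <- cohort$truth$kataegis
  if (!is.null(kat) && nrow(kat)) {
    for (k in seq_len(nrow(kat))) {
      n_in <- sum(
        cohort$variants$sample_id == kat$sample_id[k] &
          cohort$variants$chrom == kat$chrom[k] &
          cohort$variants$pos >= kat$start[k] &
          cohort$variants$pos <= kat$end[k]
      )
      expect_gte(n_in, 5) # a rare zero-alt draw may drop one SNV
    }
  }
})
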