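test_that("fisher_exact matches enumeration and applies Haldane only at zero cells", {
  set.seed(51)
  for (i in 1:60) {
    tab <- matrix(rpois(4, sample(3:10, 1)), 2)
    expect_equal(fisher_exact(tab)$p, fisher_oracle_p(tab), tolerance = 1e-10)
  }
  perfect <- fisher_exact(matrix(c(10, 0, 0, 10), 2))
  expect_equal(perfect$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(perfect$odds_ratio, 10.5 * 10.5 / (0.5 * 0.5)) # Haldane-corrected
  plain <- fisher_exact(matrix(c(8, 2, 3, 7), 2))
  expect_equal(plain$odds_ratio, 8 * 7 / (2 * 3)) # sample OR, no correction
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("BH q-values follow the step-up arithmetic", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.02, 0.5, 0.04)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  # permutation invariance up to reordering
  o <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p[o]), q[o])
})

test_that("Cochran-Armitage trend test matches the closed-form statistic", {
  flat <- trend_test(c(5, 5, 5), c(50, 50, 50))
  expect_gt(flat$p, 0.99)
  # hand computation for 0/50, 10/50, 20/50 with scores 1,2,3
  x <- c(0, 10, 20)
  n <- c(50, 50, 50)
  s <- 1:3
  N <- sum(n)
  pbar <- sum(x) / N
  num <- sum(x * s) - sum(n * s) * pbar
  den <- pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / N)
  chi2_hand <- num^2 / den
  got <- trend_test(x, n, s)
  expect_equal(got$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(got$p, stats::pchisq(chi2_hand, 1, lower.tail = FALSE))
  # two groups: reduces to the 2x2 proportion trend
  two <- trend_test(c(5, 15), c(40, 40), scores = c(1, 2))
  expect_equal(two$df, 1)
})

test_that("trend-test type-I error is controlled under a flat null", {
  set.seed(52)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i) {
    # a rare all-zero draw triggers the chi-square small-count warning
    suppressWarnings(trend_test(rbinom(3, 60, 0.2), rep(60, 3))$p)
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("enrichment_scan finds a strongly enriched event and BH-corrects", {
  set.seed(53)
  samples <- c(sprintf("a%02d", 1:40), sprintf("b%02d", 1:40))
  groups <- tibble::tibble(
    sample_id = samples, group = rep(c("A", "B"), each = 40)
  )
  m <- tibble::tibble(
    sample_id = samples,
    hit = c(rbinom(40, 1, 0.5), rbinom(40, 1, 0.05)),
    flat = rbinom(80, 1, 0.3),
    absent = 0L
  )
  res <- enrichment_scan(m, groups, "A")
  expect_false("absent" %in% res$event) # never-mutated events skipped
  hit <- res[res$event == "hit", ]
  expect_true(hit$q < 0.05)
  expect_gt(hit$odds_ratio, 1)
  expect_false(res$significant[res$event == "flat"])
})

test_that("somatic interactions classify planted overlap and exclusivity", {
  samples <- sprintf("s%02d", 1:40)
  m <- tibble::tibble(
    sample_id = samples,
    co_a = rep(c(1L, 0L), each = 20),
    co_b = rep(c(1L, 0L), each = 20),
    ex_a = rep(c(1L, 0L), each = 20),
    ex_b = rep(c(0L, 1L), each = 20)
  )
  res <- somatic_interactions(m)
  co <- res[res$event_a == "co_a" & res$event_b == "co_b", ]
  ex <- res[res$event_a == "ex_a" & res$event_b == "ex_b", ]
  expect_equal(co$direction, "co_occurrence")
  expect_gt(co$odds_ratio, 1)
  expect_equal(ex$direction, "mutual_exclusivity")
  expect_lt(ex$odds_ratio, 1)
})

test_that("independent events yield no significant interactions", {
  ok <- vapply(1:100, function(s) {
    set.seed(700 + s)
    m <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:30),
      e1 = rbinom(30, 1, 0.4), e2 = rbinom(30, 1, 0.4),
      e3 = rbinom(30, 1, 0.3), e4 = rbinom(30, 1, 0.5)
    )
    all(somatic_interactions(m)$direction == "none")
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("20/20 classification scores recurrence and truncation", {
  catalog <- dplyr::bind_rows(
    tibble::tibble(
      gene = "tsg_like", sample_id = sprintf("s%d", 1:10),
      consequence = "nonsense", protein_position = sample(1:500, 10)
    ),
    tibble::tibble(
      gene = "onc_like", sample_id = sprintf("s%d", 1:10),
      consequence = "missense",
      protein_position = c(rep(600, 8), 12, 45)
    ),
    tibble::tibble(
      gene = "mixed", sample_id = c("s1", "s2"),
      consequence = c("missense", "nonsense"),
      protein_position = c(100, 200)
    )
  )
  res <- classify_2020(catalog)
  expect_equal(res$label[res$gene == "tsg_like"], "TSG")
  expect_equal(res$tsg_score[res$gene == "tsg_like"], 1)
  expect_equal(res$label[res$gene == "onc_like"], "ONC")
  expect_equal(res$onc_score[res$gene == "onc_like"], 0.8)
  # 1 missense (no recurrence) + 1 nonsense: onc 0, tsg 0.5 -> TSG
  expect_equal(res$onc_score[res$gene == "mixed"], 0)
  expect_equal(res$tsg_score[res$gene == "mixed"], 0.5)
  expect_equal(res$label[res$gene == "mixed"], "TSG")
})
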