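# Brute-force Plackett-Luce likelihood on a worth grid (3 items).
pl_grid_oracle <- function(rankings, step = 0.004) {
  items <- sort(unique(unlist(rankings)))
  stopifnot(length(items) == 3)
  ll <- function(w) {
    names(w) <- items
    sum(vapply(rankings, function(r) {
      v <- w[r]
      tot <- rev(cumsum(rev(v)))
      m <- length(v)
      sum(log(v[seq_len(m - 1)])) - sum(log(tot[seq_len(m - 1)]))
    }, numeric(1)))
  }
  grid <- seq(step, 1 - step, by = step)
  best <- NULL
  best_ll <- -Inf
  for (w1 in grid) {
    if (1 - w1 - step < step) next
    for (w2 in seq(step, 1 - w1 - step, by = step)) {
      w <- c(w1, w2, 1 - w1 - w2)
      v <- ll(w)
      if (v > best_ll) {
        best_ll <- v
        best <- w
      }
    }
  }
  stats::setNames(best, items)
}

test_that("subclone tree enumeration respects the CCF sum rule", {
  cl <- function(peaks) {
    tibble::tibble(
      cluster = as.character(seq_along(peaks)), ccf_peak = peaks,
      is_clonal = peaks == 1
    )
  }
  # {1.0, 0.6, 0.3}: chain and branching both valid
  t1 <- enumerate_subclone_trees(cl(c(1, 0.6, 0.3)))
  expect_equal(length(t1), 2)
  expect_setequal(
    vapply(t1, paste, collapse = ",", character(1)),
    c("0,1,1", "0,1,2")
  )
  # {1.0, 0.7, 0.6}: branching violates 0.7 + 0.6 <= 1, only the chain
  t2 <- enumerate_subclone_trees(cl(c(1, 0.7, 0.6)))
  expect_equal(length(t2), 1)
  expect_equal(t2[[1]], c(0L, 1L, 2L))
  # clonal only: the single root-only tree
  t3 <- enumerate_subclone_trees(cl(1))
  expect_equal(t3, list(c(0L)))
})

test_that("ranking samples respect WGD blocks and tree ancestry", {
  ev_wgd <- tibble::tibble(
    event_id = c("A", "B"), clonality = "clonal",
    wgd_class = c("pre_wgd", "post_wgd"), cluster = NA_character_
  )
  for (i in 1:20) {
    r <- sample_ranking(ev_wgd, wgd = TRUE)
    expect_equal(r, c("A", "WGD", "B")) # forced order
  }
  # pre-WGD event in a non-WGD sample is contradictory
  expect_error(sample_ranking(ev_wgd, wgd = FALSE), "without WGD")

  # parent cluster always precedes child
  clusters <- tibble::tibble(
    cluster = c("root", "p", "c"), ccf_peak = c(1, 0.6, 0.3),
    is_clonal = c(TRUE, FALSE, FALSE)
  )
  trees <- enumerate_subclone_trees(clusters)
  chain_only <- trees[vapply(trees, function(t) all(t == c(0L, 1L, 2L)), logical(1))]
  attr(chain_only, "clusters") <- attr(trees, "clusters")
  ev_sub <- tibble::tibble(
    event_id = c("C", "P"), clonality = "subclonal",
    wgd_class = "not_applicable", cluster = c("c", "p")
  )
  set.seed(7)
  for (i in 1:20) {
    r <- sample_ranking(ev_sub, trees = chain_only, wgd = FALSE)
    expect_lt(which(r == "P"), which(r == "C"))
  }
})

test_that("two clonal events are ordered uniformly at random", {
  ev <- tibble::tibble(
    event_id = c("A", "B"), clonality = "clonal",
    wgd_class = "not_applicable", cluster = NA_character_
  )
  set.seed(8)
  first <- vapply(1:4000, function(i) sample_ranking(ev)[1], character(1))
  tab <- table(first)
  chi <- stats::chisq.test(tab, p = c(0.5, 0.5))
  expect_gt(chi$p.value, 0.001)
})

test_that("unanimous rankings give monotone worths", {
  fit <- fit_plackett_luce(rep(list(c("A", "B", "C")), 20))
  expect_true(fit$worth["A"] > fit$worth["B"])
  expect_true(fit$worth["B"] > fit$worth["C"])
  expect_equal(sum(fit$worth), 1)
  expect_equal(fit$npseudo_used, 0.5) # C never wins: prior engaged
})

test_that("pair data recover the closed-form worth ratio", {
  rankings <- c(
    rep(list(c("A", "B")), 75),
    rep(list(c("B", "A")), 25)
  )
  fit <- fit_plackett_luce(rankings)
  expect_equal(fit$npseudo_used, 0) # both events win: pure MLE
  expect_equal(unname(fit$worth["A"] / (fit$worth["A"] + fit$worth["B"])),
    0.75,
    tolerance = 1e-6
  )
})

test_that("MM fit matches the grid-search likelihood oracle on 3 events", {
  set.seed(9)
  for (rep in 1:3) {
    rankings <- lapply(1:10, function(i) {
      k <- sample(2:3, 1)
      sample(c("A", "B", "C"), k)
    })
    wins <- table(factor(
      unlist(lapply(rankings, function(r) r[-length(r)])),
      levels = c("A", "B", "C")
    ))
    if (any(wins == 0)) next # oracle is for the unpenalized MLE
    fit <- fit_plackett_luce(rankings)
    if (fit$npseudo_used > 0) next
    oracle <- pl_grid_oracle(rankings)
    expect_equal(unname(fit$worth[names(oracle)]), unname(oracle),
      tolerance = 1e-2
    )
    # likelihood at the MM solution is at least the oracle's best
    ll_at <- function(w) {
      sum(vapply(rankings, function(r) {
        v <- w[r]
        tot <- rev(cumsum(rev(v)))
        m <- length(v)
        sum(log(v[seq_len(m - 1)])) - sum(log(tot[seq_len(m - 1)]))
      }, numeric(1)))
    }
    expect_gte(ll_at(fit$worth) + 1e-3, ll_at(oracle))
  }
})

test_that("permuting event labels permutes worths identically", {
  set.seed(10)
  rankings <- lapply(1:30, function(i) sample(c("A", "B", "C", "D"), sample(2:4, 1)))
  fit1 <- fit_plackett_luce(rankings)
  swap <- c(A = "D", B = "C", C = "B", D = "A")
  rankings2 <- lapply(rankings, function(r) unname(swap[r]))
  fit2 <- fit_plackett_luce(rankings2)
  expect_equal(unname(fit1$worth[c("A", "B", "C", "D")]),
    unname(fit2$worth[c("D", "C", "B", "A")]),
    tolerance = 1e-6
  )
})

test_that("single-event ranking is degenerate with worth 1", {
  fit <- fit_plackett_luce(list("A"))
  expect_equal(unname(fit$worth), 1)
})

test_that("timing recovery: mean relative times follow the true order", {
  cohort <- make_fixture("recovery", seed = 13)
  truth <- cohort$truth$catalog
  events <- cohort$truth$events |>
    dplyr::select(sample_id, event_id, clonality, ccf, wgd_class, cluster)
  wgd_samples <- cohort$truth$samples$sample_id[cohort$truth$samples$wgd]
  est <- estimate_timing(events,
    wgd_samples = intersect(wgd_samples, events$sample_id),
    n_iter = 60, seed = 17
  )
  got <- est$summary[match(truth$event_id, est$summary$event_id), ]
  rho <- stats::cor(got$mean_rel_time, truth$true_rel_time, method = "spearman")
  expect_gte(rho, 0.9)
  expect_true(all(est$summary$ci_low <= est$summary$mean_rel_time + 1e-12))
  expect_true(all(est$summary$ci_high >= est$summary$mean_rel_time - 1e-12))
})

test_that("rarer events get wider confidence intervals at equal true time", {
  set.seed(14)
  # identical latent behavior for the two mid events (clonal half the
  # time), but one is observed in ~12% of tumors and the other in all
  mid_row <- function(s, id) {
    cl <- runif(1) < 0.5
    tibble::tibble(
      sample_id = s, event_id = id,
      clonality = ifelse(cl, "clonal", "subclonal"),
      ccf = ifelse(cl, 1, 0.4),
      wgd_class = "not_applicable",
      cluster = ifelse(cl, NA_character_, "c1")
    )
  }
  base_events <- purrr::map_dfr(sprintf("s%02d", 1:60), function(s) {
    dplyr::bind_rows(
      tibble::tibble(
        sample_id = s, event_id = "early", clonality = "clonal", ccf = 1,
        wgd_class = "not_applicable", cluster = NA_character_
      ),
      tibble::tibble(
        sample_id = s, event_id = "late", clonality = "subclonal", ccf = 0.4,
        wgd_class = "not_applicable", cluster = "c1"
      ),
      mid_row(s, "common_mid"),
      if (runif(1) < 0.12) mid_row(s, "rare_mid")
    )
  })
  est <- estimate_timing(base_events, n_iter = 80, seed = 15)
  s <- est$summary
  width <- s$ci_high - s$ci_low
  expect_gt(
    width[s$event_id == "rare_mid"],
    width[s$event_id == "common_mid"]
  )
})

test_that("identical seeds reproduce the timing table exactly", {
  ev <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:10), each = 2),
    event_id = rep(c("X", "Y"), 10),
    clonality = rep(c("clonal", "subclonal"), 10),
    ccf = rep(c(1, 0.5), 10),
    wgd_class = "not_applicable",
    cluster = rep(c(NA_character_, "c1"), 10)
  )
  e1 <- estimate_timing(ev, n_iter = 30, seed = 5)
  e2 <- estimate_timing(ev, n_iter = 30, seed = 5)
  expect_identical(e1$summary, e2$summary)
  # n_iter = 1: degenerate CI equal to the point estimate
  e3 <- estimate_timing(ev, n_iter = 1, seed = 5)
  expect_equal(e3$summary$ci_low, e3$summary$mean_rel_time)
  expect_equal(e3$summary$ci_high, e3$summary$mean_rel_time)
})

test_that("tidy and glance methods expose fits as tibbles", {
  fit <- fit_plackett_luce(rep(list(c("A", "B")), 5))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$event_id[1], "A")
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_rankings, 5)
})
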