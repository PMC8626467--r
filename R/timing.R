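# Chronological ordering of genomic events.
#
# Per tumor, clonal events precede subclonal ones; within the clonal block
# pre-WGD events precede WGD which precedes post-WGD events; subclonal
# events follow a phylogeny over their CCF clusters (every valid tree under
# the sum rule is enumerated and one is drawn per iteration). Each sampling
# iteration yields one strict ranking per tumor; a Plackett-Luce model
# fitted to the partial rankings of the whole cohort gives population-level
# event worths, and repeating the sampling yields a confidence interval on
# each event's relative time.

#' Enumerate subclone trees under the CCF sum rule
#'
#' All rooted trees over the clonal root plus the subclonal clusters in
#' which every parent has CCF at least each child's and, at every node, the
#' children's CCFs sum to at most the parent's (pigeonhole constraint).
#' Found by exhaustive parent-assignment search for up to `max_enumerate`
#' subclones; beyond that, `n_sampled` valid trees are drawn at random
#' instead (with replacement, duplicates removed).
#'
#' @param clusters Cluster tibble with `ccf_peak` and `is_clonal` columns
#'   (one clonal row).
#' @param max_enumerate Exhaustive-search guard (default 6 subclones).
#' @param n_sampled Trees drawn when beyond the guard (default 100).
#' @return List of trees; each tree is an integer vector `parent` indexed
#'   by cluster row (clusters sorted by decreasing CCF, root first), with
#'   `parent[1] = 0`.
#' @export
enumerate_subclone_trees <- function(clusters, max_enumerate = 6,
                                     n_sampled = 100) {
  cl <- dplyr::arrange(clusters, dplyr::desc(.data$is_clonal), dplyr::desc(.data$ccf_peak))
  if (sum(cl$is_clonal) != 1) {
    stop("exactly one clonal cluster required", call. = FALSE)
  }
  ccf <- pmin(cl$ccf_peak, 1)
  ccf[1] <- 1 # clonal root
  n <- length(ccf)
  if (n == 1) return(list(c(0L)))
  valid <- function(parent) {
    for (p in unique(parent[-1])) {
      if (sum(ccf[parent == p], na.rm = TRUE) > ccf[p] + 1e-9) return(FALSE)
    }
    TRUE
  }
  cand <- lapply(seq_len(n), function(i) {
    if (i == 1) return(0L)
    which(ccf[seq_len(i - 1)] >= ccf[i] - 1e-9)
  })
  if (n - 1 <= max_enumerate) {
    grids <- do.call(expand.grid, c(cand[-1], list(KEEP.OUT.ATTRS = FALSE)))
    trees <- lapply(seq_len(nrow(grids)), function(r) {
      c(0L, as.integer(unlist(grids[r, ], use.names = FALSE)))
    })
    trees <- Filter(valid, trees)
  } else {
    trees <- list()
    for (s in seq_len(n_sampled * 10)) {
      parent <- c(0L, vapply(2:n, function(i) {
        as.integer(sample(rep(cand[[i]], 2), 1)) # rep() guards length-1 sample()
      }, integer(1)))
      if (valid(parent)) trees <- c(trees, list(parent))
      if (length(trees) >= n_sampled) break
    }
    trees <- unique(trees)
  }
  if (!length(trees)) {
    stop("no subclone tree satisfies the CCF sum rule", call. = FALSE)
  }
  attr(trees, "clusters") <- cl
  trees
}

# Uniform random linear extension of a parent-vector tree: repeatedly pick
# uniformly among nodes whose parent is already placed.
random_linear_extension <- function(parent) {
  n <- length(parent)
  placed <- logical(n)
  out <- integer(0)
  while (length(out) < n) {
    avail <- which(!placed & (parent == 0L | placed[pmax(parent, 1L)]))
    pick <- if (length(avail) == 1) avail else sample(avail, 1)
    placed[pick] <- TRUE
    out <- c(out, pick)
  }
  out
}

#' Sample one event ranking for a tumor
#'
#' Draws one ordering realization: clonal events with their within-block
#' order randomized (pre-WGD block, then WGD, then post-WGD block in WGD
#' tumors; unclassifiable clonal events are inserted at uniformly random
#' clonal positions), followed by subclonal events in an order consistent
#' with a random linear extension of a tree drawn uniformly from `trees`
#' (events sharing a cluster are shuffled within it).
#'
#' @param events Event tibble for one sample: `event_id`, `clonality`
#'   (`"clonal"|"subclonal"`), `wgd_class`
#'   (`"pre_wgd"|"post_wgd"|"not_applicable"`), `cluster` (subclone cluster
#'   id, `NA` for clonal events).
#' @param trees Tree list from [enumerate_subclone_trees()] (or `NULL` when
#'   the sample has no subclonal events).
#' @param wgd Logical; whether the tumor carries WGD as a timeable event
#'   (adds the `"WGD"` pseudo-event between the blocks).
#' @return Character vector of event ids, earliest first.
#' @export
sample_ranking <- function(events, trees = NULL, wgd = FALSE) {
  if (any(events$wgd_class == "pre_wgd" & !wgd)) {
    stop("pre-WGD event in a sample without WGD", call. = FALSE)
  }
  clonal <- events[events$clonality == "clonal", , drop = FALSE]
  sub <- events[events$clonality == "subclonal", , drop = FALSE]
  shuffle <- function(x) if (length(x) > 1) sample(x) else x
  if (wgd) {
    pre <- shuffle(clonal$event_id[clonal$wgd_class == "pre_wgd"])
    post <- shuffle(clonal$event_id[clonal$wgd_class == "post_wgd"])
    na_cl <- clonal$event_id[clonal$wgd_class == "not_applicable"]
    ranking <- c(pre, "WGD", post)
    for (ev in shuffle(na_cl)) {
      slot <- sample.int(length(ranking) + 1, 1)
      ranking <- append(ranking, ev, after = slot - 1)
    }
  } else {
    ranking <- shuffle(clonal$event_id)
  }
  if (nrow(sub)) {
    if (is.null(trees)) stop("subclonal events need a tree set", call. = FALSE)
    tree <- trees[[if (length(trees) == 1) 1 else sample.int(length(trees), 1)]]
    cl <- attr(trees, "clusters")
    ext <- random_linear_extension(tree)
    ext <- ext[ext != 1] # root = clonal block, already placed
    for (node in ext) {
      ids <- sub$event_id[sub$cluster == cl$cluster[node]]
      ranking <- c(ranking, shuffle(ids))
    }
    missing <- setdiff(sub$event_id, ranking)
    if (length(missing)) {
      stop("subclonal event(s) with unknown cluster: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
  }
  ranking
}

#' Fit a Plackett-Luce model to partial rankings
#'
#' Maximum-likelihood worths under the Plackett-Luce choice model, fitted
#' by minorization-maximization until the relative log-likelihood change
#' drops below `tol` (default 1e-8, capped at `maxit` iterations). Partial
#' rankings are handled natively: each ranking only compares the events it
#' contains. When an event never wins a comparison (always ranked last) or
#' the comparison graph is disconnected, the MLE does not exist; in that
#' case a pseudo-observation prior is applied automatically (every event
#' beats and loses to a shadow reference event `npseudo` times; the shadow
#' is dropped after fitting), and this is recorded on the returned object.
#'
#' @param rankings List of character vectors, each a strict partial ranking
#'   (earliest first). Length-1 rankings carry no information and are
#'   ignored.
#' @param npseudo Pseudo-observation weight used when regularization is
#'   needed (default 0.5).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Iteration cap.
#' @return Object of class `somevo_pl`: list with `worth` (named, sums to
#'   1), `loglik`, `iterations`, `converged`, `npseudo_used`,
#'   `n_rankings`.
#' @export
fit_plackett_luce <- function(rankings, npseudo = 0.5, tol = 1e-8,
                              maxit = 10000) {
  rankings <- Filter(function(r) length(r) >= 1, rankings)
  items <- sort(unique(unlist(rankings)))
  if (!length(items)) stop("no events in rankings", call. = FALSE)
  K <- length(items)
  idx <- lapply(rankings, function(r) match(r, items))
  if (K == 1) {
    return(structure(
      list(
        worth = stats::setNames(1, items), loglik = 0, iterations = 0L,
        converged = TRUE, npseudo_used = 0, n_rankings = length(rankings)
      ),
      class = "somevo_pl"
    ))
  }
  wins <- integer(K)
  for (v in idx) {
    if (length(v) > 1) {
      w <- v[-length(v)]
      wins[w] <- wins[w] + 1L
    }
  }
  # connectivity of the co-occurrence graph (union-find over rankings)
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (v in idx) {
    if (length(v) > 1) {
      for (j in v[-1]) parent[find(j)] <- find(v[1])
    }
  }
  connected <- length(unique(vapply(seq_len(K), find, integer(1)))) == 1
  need_pseudo <- any(wins == 0) || !connected
  use_np <- if (need_pseudo) npseudo else 0
  if (need_pseudo) {
    # shadow item K+1: each item beats and loses to it use_np times
    shadow <- K + 1L
    extra <- unlist(lapply(seq_len(K), function(i) {
      list(c(i, shadow), c(shadow, i))
    }), recursive = FALSE)
    fit <- pl_mm(c(idx, extra), shadow,
      weights = c(rep(1, length(idx)), rep(use_np, 2L * K)),
      tol = tol, maxit = maxit
    )
    worth <- fit$w[seq_len(K)]
    worth <- worth / sum(worth)
    ll <- pl_loglik(idx, worth)
  } else {
    fit <- pl_mm(idx, K, weights = rep(1, length(idx)), tol = tol, maxit = maxit)
    worth <- fit$w / sum(fit$w)
    ll <- pl_loglik(idx, worth)
  }
  structure(
    list(
      worth = stats::setNames(worth, items), loglik = ll,
      iterations = fit$iter, converged = fit$converged,
      npseudo_used = use_np, n_rankings = length(rankings)
    ),
    class = "somevo_pl"
  )
}

# MM core on integer rankings over n items with per-ranking weights.
pl_mm <- function(idx, n, weights, tol, maxit) {
  keep <- lengths(idx) > 1
  idx <- idx[keep]
  weights <- weights[keep]
  w <- rep(1 / n, n)
  wins <- numeric(n)
  for (r in seq_along(idx)) {
    v <- idx[[r]]
    ww <- v[-length(v)]
    wins[ww] <- wins[ww] + weights[r]
  }
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    denom <- numeric(n)
    ll <- 0
    for (r in seq_along(idx)) {
      v <- idx[[r]]
      m <- length(v)
      wv <- w[v]
      s <- rev(cumsum(rev(wv))) # s[j] = sum of worths from position j on
      inv <- 1 / s[seq_len(m - 1)]
      cum <- cumsum(inv)
      contrib <- c(cum, cum[m - 1]) # item at pos k is in stages 1..min(k, m-1)
      denom[v] <- denom[v] + weights[r] * contrib
      ll <- ll + weights[r] * (sum(log(wv[seq_len(m - 1)])) - sum(log(s[seq_len(m - 1)])))
    }
    w_new <- wins / denom
    w_new[!is.finite(w_new)] <- 1e-12
    w_new <- pmax(w_new, 1e-300)
    w <- w_new / sum(w_new)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w = w, iter = iter, converged = converged)
}

pl_loglik <- function(idx, w) {
  ll <- 0
  for (v in idx) {
    m <- length(v)
    if (m < 2) next
    wv <- w[v]
    s <- rev(cumsum(rev(wv)))
    ll <- ll + sum(log(wv[seq_len(m - 1)])) - sum(log(s[seq_len(m - 1)]))
  }
  ll
}

#' @export
print.somevo_pl <- function(x, ...) {
  cat("<somevo_pl> Plackett-Luce fit:", length(x$worth), "events,",
    x$n_rankings, "rankings; logLik", format(x$loglik, digits = 6), "\n"
  )
  print(round(sort(x$worth, decreasing = TRUE), 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.somevo_pl <- function(x, ...) {
  ord <- order(-x$worth, names(x$worth))
  tibble::tibble(
    event_id = names(x$worth)[ord],
    worth = unname(x$worth[ord]),
    log_worth = log(unname(x$worth[ord])),
    rank = seq_along(ord)
  )
}

#' @exportS3Method generics::glance
glance.somevo_pl <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, iterations = x$iterations, converged = x$converged,
    n_events = length(x$worth), n_rankings = x$n_rankings,
    npseudo = x$npseudo_used
  )
}

#' Population-level event timing with confidence intervals
#'
#' Repeats ranking sampling and Plackett-Luce fitting `n_iter` times: in
#' each iteration one ranking per tumor is drawn with [sample_ranking()],
#' the model is fitted to the cohort, and each event's relative time is its
#' normalized rank by descending worth (`(rank - 1) / (K - 1)`, 0 =
#' earliest; worth ties break stably by event id). The per-event mean and
#' 2.5/97.5 percentiles over iterations give the timing estimate and its
#' 95% CI; rarer events naturally get wider intervals.
#'
#' @param events Cohort event tibble: `sample_id`, `event_id`, `clonality`,
#'   `ccf`, `wgd_class`, `cluster` (`NA` for clonal events).
#' @param clusters Optional cohort cluster tibble (`sample_id`, `cluster`,
#'   `ccf_peak`, `is_clonal`); when absent, each sample's subclone clusters
#'   are reconstructed from the distinct subclonal event CCFs.
#' @param wgd_samples Character vector of sample ids carrying WGD as an
#'   event; default: samples with any `pre_wgd`/`post_wgd` classification.
#' @param n_iter Sampling iterations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `somevo_timing`: list with `summary` (tibble:
#'   `event_id`, `mean_rel_time`, `ci_low`, `ci_high`, `mean_worth`,
#'   `n_samples_observed`), `draws` (n_iter x K matrix of relative times)
#'   and the call parameters. `tidy()` returns the summary.
#' @export
estimate_timing <- function(events, clusters = NULL, wgd_samples = NULL,
                            n_iter = 1000, seed = 1) {
  stopifnot(n_iter >= 1)
  if (is.null(wgd_samples)) {
    wgd_samples <- unique(
      events$sample_id[events$wgd_class %in% c("pre_wgd", "post_wgd")]
    )
  }
  if (!"cluster" %in% names(events)) events$cluster <- NA_character_
  samples <- unique(events$sample_id)
  per_sample <- lapply(samples, function(s) {
    ev <- events[events$sample_id == s, , drop = FALSE]
    sub <- ev[ev$clonality == "subclonal", , drop = FALSE]
    trees <- NULL
    if (nrow(sub)) {
      cl <- if (!is.null(clusters)) {
        clusters[clusters$sample_id == s, , drop = FALSE]
      } else {
        sub |>
          dplyr::group_by(cluster = as.character(.data$cluster)) |>
          dplyr::summarise(ccf_peak = max(.data$ccf), .groups = "drop") |>
          dplyr::mutate(is_clonal = FALSE) |>
          dplyr::bind_rows(
            tibble::tibble(cluster = ".clonal", ccf_peak = 1, is_clonal = TRUE)
          )
      }
      cl$cluster <- as.character(cl$cluster)
      trees <- enumerate_subclone_trees(cl)
    }
    list(events = dplyr::mutate(ev, cluster = as.character(.data$cluster)),
         trees = trees, wgd = s %in% wgd_samples)
  })
  all_events <- sort(unique(c(
    events$event_id, if (length(wgd_samples)) "WGD"
  )))
  K <- length(all_events)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = K,
    dimnames = list(NULL, all_events)
  )
  worths <- matrix(NA_real_, nrow = n_iter, ncol = K,
    dimnames = list(NULL, all_events)
  )
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    rankings <- lapply(per_sample, function(ps) {
      sample_ranking(ps$events, trees = ps$trees, wgd = ps$wgd)
    })
    fit <- fit_plackett_luce(rankings)
    w <- fit$worth[all_events]
    ord <- order(-w, all_events) # stable tie-break by event id
    rk <- integer(K)
    rk[ord] <- seq_len(K)
    draws[it, ] <- if (K > 1) (rk - 1) / (K - 1) else 0
    worths[it, ] <- w
  }
  n_obs <- events |>
    dplyr::distinct(.data$sample_id, .data$event_id) |>
    dplyr::count(.data$event_id, name = "n_samples_observed")
  if (length(wgd_samples)) {
    n_obs <- dplyr::bind_rows(
      n_obs,
      tibble::tibble(event_id = "WGD", n_samples_observed = length(wgd_samples))
    )
  }
  summary <- tibble::tibble(
    event_id = all_events,
    mean_rel_time = colMeans(draws),
    ci_low = apply(draws, 2, stats::quantile, probs = 0.025),
    ci_high = apply(draws, 2, stats::quantile, probs = 0.975),
    mean_worth = colMeans(worths)
  ) |>
    dplyr::left_join(n_obs, by = "event_id") |>
    dplyr::arrange(.data$mean_rel_time)
  structure(
    list(summary = summary, draws = draws, n_iter = n_iter, seed = seed),
    class = "somevo_timing"
  )
}

#' @export
print.somevo_timing <- function(x, ...) {
  cat("<somevo_timing>", x$n_iter, "iterations over",
    nrow(x$summary), "events\n"
  )
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.somevo_timing <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.somevo_timing <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$summary), n_iter = x$n_iter, seed = x$seed
  )
}
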