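# Cohort-level statistics: Fisher-exact utilities, enrichment, trend,
# somatic interactions, and the 20/20 oncogene / tumor-suppressor rule.

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value (the "sum of tables at most as probable as the
#' observed" convention, via [stats::fisher.test()]) together with the
#' sample odds ratio `ad/bc`. When any cell is zero the reported OR uses the
#' Haldane-Anscombe 0.5 correction so it stays finite and comparable across
#' tables; the p-value is always from the uncorrected exact test.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: `odds_ratio`, `p`.
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2)) # OR 1, p 1
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table))) {
    stop("table must hold non-negative integer counts", call. = FALSE)
  }
  p <- stats::fisher.test(table)$p.value
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  or <- if (any(table == 0)) {
    (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
  } else {
    a * d / (b * c_)
  }
  tibble::tibble(odds_ratio = or, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(p, method = "BH")` kept as the single
#' named entry point for multiple-testing correction across the package.
#'
#' @param pvalues Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Event enrichment across groups
#'
#' One Fisher's exact test per event on the 2x2 of event presence against
#' membership of `group_a` (vs everything else, or `group_b` when given),
#' BH-corrected across events. The OR confidence interval is the exact
#' conditional interval from [stats::fisher.test()].
#'
#' @param matrix Binary incidence tibble or matrix, samples in rows, events
#'   in columns; rownames (or an explicit `sample_id` column) identify
#'   samples.
#' @param groups Named character vector or tibble mapping `sample_id` to
#'   `group`.
#' @param group_a Focal group label.
#' @param group_b Comparison group label (default: all other samples).
#' @param fdr Significance threshold on q (default 0.05).
#' @return Tibble: `event`, `n_a`, `N_a`, `n_b`, `N_b`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`, `q`, `significant`. Events absent from both
#'   groups are skipped.
#' @export
enrichment_scan <- function(matrix, groups, group_a, group_b = NULL,
                            fdr = 0.05) {
  em <- as_event_matrix(matrix)
  grp <- as_group_map(groups)[rownames(em)]
  in_a <- grp == group_a
  in_b <- if (is.null(group_b)) !in_a else grp == group_b
  res <- purrr::map_dfr(colnames(em), function(ev) {
    n_a <- sum(em[in_a, ev])
    n_b <- sum(em[in_b, ev])
    if (n_a + n_b == 0) return(NULL)
    tab <- matrix(c(n_a, sum(in_a) - n_a, n_b, sum(in_b) - n_b), 2,
      byrow = TRUE
    )
    ft <- stats::fisher.test(tab)
    fe <- fisher_exact(tab)
    tibble::tibble(
      event = ev, n_a = n_a, N_a = sum(in_a), n_b = n_b, N_b = sum(in_b),
      odds_ratio = fe$odds_ratio, ci_low = ft$conf.int[1],
      ci_high = ft$conf.int[2], p = fe$p
    )
  })
  if (!nrow(res)) return(res)
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < fdr
  dplyr::arrange(res, .data$p)
}

#' Cochran-Armitage trend test
#'
#' Tests whether per-group proportions are monotone in an ordered score
#' (default 1, 2, 3, ... in the order supplied), via
#' [stats::prop.trend.test()].
#'
#' @param successes Per-group success counts.
#' @param totals Per-group sizes.
#' @param scores Ordered group scores (default `seq_along(successes)`).
#' @return One-row tibble: `chi2`, `df`, `p`.
#' @export
trend_test <- function(successes, totals, scores = seq_along(successes)) {
  # perfectly flat proportions trigger an internal lm() F-test warning that
  # does not concern the chi-square statistic extracted here
  tt <- withCallingHandlers(
    stats::prop.trend.test(successes, totals, score = scores),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble::tibble(
    chi2 = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value
  )
}

#' Pairwise somatic interactions
#'
#' All event pairs are tested with Fisher's exact test on the 2x2 of joint
#' presence; BH correction runs over all pairs. Significant pairs with
#' OR > 1 are co-occurrent, with 0 < OR < 1 mutually exclusive.
#'
#' @param matrix Binary incidence (samples x events), as in
#'   [enrichment_scan()].
#' @param fdr Significance threshold on q (default 0.05).
#' @return Tibble: `event_a`, `event_b`, `n_both`, `n_a_only`, `n_b_only`,
#'   `n_neither`, `odds_ratio`, `p`, `q`, `direction`.
#' @export
somatic_interactions <- function(matrix, fdr = 0.05) {
  em <- as_event_matrix(matrix)
  evs <- colnames(em)
  if (length(evs) < 2) {
    stop("need at least two events", call. = FALSE)
  }
  pairs <- utils::combn(evs, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- em[, pairs[1, k]]
    b <- em[, pairs[2, k]]
    tab <- matrix(c(
      sum(a & b), sum(a & !b),
      sum(!a & b), sum(!a & !b)
    ), 2, byrow = TRUE)
    fe <- fisher_exact(tab)
    tibble::tibble(
      event_a = pairs[1, k], event_b = pairs[2, k],
      n_both = tab[1, 1], n_a_only = tab[1, 2], n_b_only = tab[2, 1],
      n_neither = tab[2, 2], odds_ratio = fe$odds_ratio, p = fe$p
    )
  })
  res$q <- bh_fdr(res$p)
  res$direction <- dplyr::case_when(
    res$q < fdr & res$odds_ratio > 1 ~ "co_occurrence",
    res$q < fdr & res$odds_ratio < 1 ~ "mutual_exclusivity",
    TRUE ~ "none"
  )
  dplyr::arrange(res, .data$p)
}

#' 20/20 oncogene / tumor-suppressor classification
#'
#' From a per-gene catalog of variant consequences: the oncogene score is
#' the fraction of a gene's missense/in-frame mutations falling at recurrent
#' protein positions (a position seen at least `min_recurrence` times in the
#' catalog), and the TSG score is the fraction of all its mutations that are
#' truncating (nonsense, frameshift, splice). Genes at or above the 20%
#' threshold on either score are labelled accordingly (`both` when on both).
#'
#' @param catalog Tibble with columns `gene`, `sample_id`, `consequence`
#'   (one of `missense`, `inframe`, `nonsense`, `frameshift`, `splice`,
#'   `synonymous`, `other`) and `protein_position`.
#' @param onc_threshold,tsg_threshold Score thresholds (default 0.2).
#' @param min_recurrence Times a position must recur to count (default 2).
#' @return Tibble: `gene`, `n_mutations`, `onc_score`, `tsg_score`, `label`.
#' @export
classify_2020 <- function(catalog, onc_threshold = 0.2, tsg_threshold = 0.2,
                          min_recurrence = 2) {
  truncating <- c("nonsense", "frameshift", "splice")
  activating <- c("missense", "inframe")
  catalog |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      act <- g[g$consequence %in% activating, , drop = FALSE]
      onc <- if (nrow(act)) {
        pos_counts <- table(act$protein_position)
        recur <- names(pos_counts)[pos_counts >= min_recurrence]
        sum(act$protein_position %in% recur) / nrow(act)
      } else {
        0
      }
      tsg <- sum(g$consequence %in% truncating) / n
      tibble::tibble(
        gene = key$gene, n_mutations = n, onc_score = onc, tsg_score = tsg,
        label = dplyr::case_when(
          onc >= onc_threshold & tsg >= tsg_threshold ~ "both",
          onc >= onc_threshold ~ "ONC",
          tsg >= tsg_threshold ~ "TSG",
          TRUE ~ "neither"
        )
      )
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$gene)
}

# Coerce incidence input (tibble with sample_id column, or matrix) to a
# binary matrix with sample rownames.
as_event_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    x <- tibble::as_tibble(x)
    stopifnot("sample_id" %in% names(x))
    m <- as.matrix(x[setdiff(names(x), "sample_id")])
    rownames(m) <- x$sample_id
  }
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("incidence entries must be 0/1", call. = FALSE)
  m
}

as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    stats::setNames(groups$group, groups$sample_id)
  } else {
    groups
  }
}
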