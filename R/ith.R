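# Intra-tumor heterogeneity via the weighted-CCF statistic.
#
# Mutation clusters are local peaks of the per-mutation CCF density (a
# deliberately simple density-peak stand-in for full Dirichlet-process
# clustering; externally produced cluster tables are accepted everywhere a
# cluster table is, making the stand-in non-load-bearing). wCCF is the
# mutation-burden-weighted mean of cluster peak CCFs: 1 for a purely clonal
# tumor, lower the more mutations sit in subclones.

#' Cluster per-mutation CCFs into mutation clusters
#'
#' Kernel-density estimate of the CCF distribution over (0, 1.5]; local
#' maxima with prominence at least `min_prominence` of the density maximum
#' become cluster peaks, each mutation is assigned to its nearest peak, and
#' the peak closest to CCF 1 (within `clonal_window`) is flagged clonal.
#' When no peak falls near 1 a clonal cluster is forced at CCF 1 with a
#' warning (it may end up with zero assigned mutations and is then dropped
#' from the output but still noted).
#'
#' @param ccfs Numeric vector of per-mutation CCFs (values above 1.5 are
#'   clamped to 1.5; non-finite values dropped).
#' @param min_mutations Minimum number of mutations required (default 20).
#' @param min_prominence Peak prominence floor as a fraction of the maximum
#'   density (default 0.05).
#' @param clonal_window Half-width around CCF 1 within which a peak counts
#'   as the clonal cluster (default 0.1).
#' @return Cluster tibble: `cluster`, `ccf_peak`, `n_mutations`,
#'   `is_clonal`, ordered by decreasing peak.
#' @export
cluster_ccf <- function(ccfs, min_mutations = 20, min_prominence = 0.05,
                        clonal_window = 0.1) {
  ccfs <- ccfs[is.finite(ccfs) & ccfs > 0]
  ccfs <- pmin(ccfs, 1.5)
  if (length(ccfs) < min_mutations) {
    stop("need at least ", min_mutations, " mutations to cluster",
      call. = FALSE
    )
  }
  d <- stats::density(ccfs, bw = "nrd0", from = 0, to = 1.5, n = 512)
  pk <- density_peaks(d$x, d$y)
  pk <- pk[pk$prominence >= min_prominence * max(d$y), , drop = FALSE]
  if (!nrow(pk)) pk <- tibble::tibble(x = d$x[which.max(d$y)], y = max(d$y))
  peaks <- sort(pk$x, decreasing = TRUE)
  near1 <- abs(peaks - 1) <= clonal_window
  if (!any(near1)) {
    warning("no CCF peak within ", clonal_window,
      " of 1; forcing a clonal cluster at CCF 1",
      call. = FALSE
    )
    peaks <- sort(c(peaks, 1), decreasing = TRUE)
    clonal_peak <- 1
  } else {
    clonal_peak <- peaks[near1][which.min(abs(peaks[near1] - 1))]
  }
  assign <- vapply(ccfs, function(v) which.min(abs(peaks - v)), integer(1))
  clonal_idx <- which(peaks == clonal_peak)[1]
  if (!any(assign == clonal_idx)) {
    # a forced clonal cluster must own at least one mutation: take the
    # highest-CCF mutation (conservation of assigned mutations holds)
    assign[which.max(ccfs)] <- clonal_idx
  }
  counts <- tabulate(assign, nbins = length(peaks))
  keep <- counts > 0
  tibble::tibble(
    cluster = seq_len(sum(keep)),
    ccf_peak = peaks[keep],
    n_mutations = counts[keep],
    is_clonal = seq_along(peaks)[keep] == clonal_idx
  )
}

#' Weighted CCF (wCCF)
#'
#' The mutation-burden-weighted mean of cluster peak CCFs,
#' `sum(min(peak, 1) * n) / sum(n)`. Peaks above 1 (clonal by the binomial
#' clonality rule) are capped at 1 for weighting; the raw peaks are left
#' untouched in the cluster table. wCCF is 1 exactly when every mutation is
#' clonal and decreases as subclonal burden grows, so lower wCCF means
#' higher intra-tumor heterogeneity.
#'
#' @param clusters Cluster tibble with `ccf_peak` and `n_mutations`
#'   (from [cluster_ccf()] or [read_clusters()]).
#' @return Numeric wCCF in (0, 1].
#' @examples
#' compute_wccf(tibble::tibble(ccf_peak = c(1, 0.4), n_mutations = c(50, 50))) # 0.7
#' @export
compute_wccf <- function(clusters) {
  stopifnot(all(c("ccf_peak", "n_mutations") %in% names(clusters)))
  w <- clusters$n_mutations
  sum(pmin(clusters$ccf_peak, 1) * w) / sum(w)
}

#' Intra-tumor-heterogeneity table for a cohort
#'
#' Computes wCCF per sample from either externally supplied cluster tables
#' or by clustering per-mutation CCFs, and annotates each sample with NRPCC
#' and the NRPCC >= `min_nrpcc` power flag (samples failing it are reported
#' but flagged, for the caller to exclude).
#'
#' @param ccf_table Per-mutation CCF tibble with `sample_id` and `ccf`
#'   columns (e.g. from [ccf_calls()]); ignored when `clusters` is given.
#' @param metadata Sample metadata tibble.
#' @param clusters Optional cluster tibble ([read_clusters()] layout); when
#'   supplied, [cluster_ccf()] is bypassed entirely.
#' @param min_nrpcc Power threshold (default 10).
#' @param min_mutations Passed to [cluster_ccf()].
#' @return Tibble: `sample_id`, `wccf`, `n_clusters`,
#'   `n_subclonal_mutations`, `cluster_json` (peaks and burdens as JSON),
#'   `nrpcc`, `nrpcc_pass`.
#' @export
ith_analysis <- function(ccf_table = NULL, metadata, clusters = NULL,
                         min_nrpcc = 10, min_mutations = 20) {
  if (is.null(clusters)) {
    if (is.null(ccf_table)) {
      stop("supply either ccf_table or clusters", call. = FALSE)
    }
    clusters <- ccf_table |>
      dplyr::group_split(.data$sample_id) |>
      purrr::map_dfr(function(g) {
        cl <- cluster_ccf(g$ccf, min_mutations = min_mutations)
        cl$sample_id <- g$sample_id[1]
        cl
      })
  }
  clusters |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map_dfr(function(cl) {
      tibble::tibble(
        sample_id = cl$sample_id[1],
        wccf = compute_wccf(cl),
        n_clusters = nrow(cl),
        n_subclonal_mutations = sum(cl$n_mutations[!cl$is_clonal]),
        cluster_json = jsonlite::toJSON(
          list(peaks = cl$ccf_peak, burdens = cl$n_mutations),
          auto_unbox = FALSE
        ) |> as.character()
      )
    }) |>
    dplyr::left_join(
      metadata |>
        dplyr::mutate(
          nrpcc = compute_nrpcc(.data$mean_depth, .data$purity, .data$ploidy)
        ) |>
        dplyr::select("sample_id", "nrpcc"),
      by = "sample_id"
    ) |>
    dplyr::mutate(nrpcc_pass = .data$nrpcc >= min_nrpcc)
}
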