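# Genome-wide 100-kb-bin scan for differential SNV recurrence between
# cohorts. Recurrence is sample-level: a sample counts once per bin when it
# carries at least one SNV there, so hypermutator samples cannot dominate a
# bin. An optional coding mask restricts the scan to non-coding territory.

#' Count per-bin sample recurrence by group
#'
#' @param variants Cohort variant tibble; only SNVs (single-base ref and
#'   alt) are counted.
#' @param bins Bin tiling from [bin_genome()].
#' @param metadata Sample metadata tibble (`sample_id`, `group`); supplies
#'   group sizes including unmutated samples.
#' @param mask Optional tibble of (`chrom`, `start`, `end`) intervals (e.g.
#'   coding regions); SNVs overlapping the mask are dropped before
#'   counting.
#' @return Tibble: `chrom`, `start`, `end`, `group`, `n_mutated`,
#'   `n_total`, one row per bin x group.
#' @export
count_recurrence <- function(variants, bins, metadata, mask = NULL) {
  snv <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref != "-" & variants$alt != "-", , drop = FALSE]
  if (!is.null(mask) && nrow(mask) && nrow(snv)) {
    masked <- vapply(seq_len(nrow(snv)), function(k) {
      any(mask$chrom == snv$chrom[k] & mask$start <= snv$pos[k] &
        mask$end >= snv$pos[k])
    }, logical(1))
    snv <- snv[!masked, , drop = FALSE]
  }
  group_sizes <- metadata |>
    dplyr::count(.data$group, name = "n_total")
  # assign each SNV to its bin by position arithmetic (fixed-width tiling)
  width <- bins$end[1] - bins$start[1] + 1
  snv$bin_start <- (snv$pos - 1) %/% width * width + 1
  hits <- snv |>
    dplyr::inner_join(
      dplyr::select(metadata, "sample_id", "group"),
      by = "sample_id"
    ) |>
    dplyr::distinct(.data$chrom, .data$bin_start, .data$group, .data$sample_id) |>
    dplyr::count(.data$chrom, .data$bin_start, .data$group, name = "n_mutated")
  bins |>
    tidyr::crossing(group_sizes) |>
    dplyr::left_join(
      hits,
      by = c("chrom", start = "bin_start", "group")
    ) |>
    dplyr::mutate(n_mutated = dplyr::coalesce(.data$n_mutated, 0L)) |>
    dplyr::select("chrom", "start", "end", "group", "n_mutated", "n_total")
}

#' Scan bins for differential recurrence between two groups
#'
#' Two-sided Fisher's exact test per bin on the 2x2 of mutated/unmutated
#' samples by group, BH-corrected across the bins with at least one mutated
#' sample in either group (empty bins are excluded from the family).
#'
#' @param counts Output of [count_recurrence()].
#' @param group_a,group_b Group labels to compare.
#' @param fdr Significance threshold on q (default 0.1).
#' @return Tibble: `chrom`, `start`, `end`, `n_a`, `N_a`, `n_b`, `N_b`,
#'   `odds_ratio`, `p`, `q`, `significant`; one row per tested bin.
#' @export
scan_bins <- function(counts, group_a, group_b, fdr = 0.1) {
  wide <- counts |>
    dplyr::filter(.data$group %in% c(group_a, group_b)) |>
    tidyr::pivot_wider(
      id_cols = c("chrom", "start", "end"),
      names_from = "group",
      values_from = c("n_mutated", "n_total")
    )
  n_a <- wide[[paste0("n_mutated_", group_a)]]
  N_a <- wide[[paste0("n_total_", group_a)]]
  n_b <- wide[[paste0("n_mutated_", group_b)]]
  N_b <- wide[[paste0("n_total_", group_b)]]
  keep <- (n_a + n_b) > 0
  out <- tibble::tibble(
    chrom = wide$chrom[keep], start = wide$start[keep], end = wide$end[keep],
    n_a = n_a[keep], N_a = N_a[keep], n_b = n_b[keep], N_b = N_b[keep]
  )
  if (!nrow(out)) {
    out$odds_ratio <- numeric(0)
    out$p <- numeric(0)
    out$q <- numeric(0)
    out$significant <- logical(0)
    return(out)
  }
  ft <- purrr::map_dfr(seq_len(nrow(out)), function(k) {
    fisher_exact(matrix(
      c(out$n_a[k], out$N_a[k] - out$n_a[k], out$n_b[k], out$N_b[k] - out$n_b[k]),
      2,
      byrow = TRUE
    ))
  })
  out$odds_ratio <- ft$odds_ratio
  out$p <- ft$p
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr
  dplyr::arrange(out, .data$p)
}

#' Non-coding hotspot scan end to end
#'
#' [bin_genome()] then [count_recurrence()] then [scan_bins()].
#'
#' @inheritParams count_recurrence
#' @inheritParams scan_bins
#' @param genome A [genome_model()].
#' @param bin_width Bin width in bp (default 100 kb).
#' @return The per-bin test table from [scan_bins()].
#' @export
hotspot_scan <- function(variants, metadata, genome, group_a, group_b,
                         bin_width = 100000, fdr = 0.1, mask = NULL) {
  bins <- bin_genome(genome, width = bin_width)
  counts <- count_recurrence(variants, bins, metadata, mask = mask)
  scan_bins(counts, group_a, group_b, fdr = fdr)
}
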