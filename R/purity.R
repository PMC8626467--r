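# VAF-based purity estimation and power QC.
#
# In a tumor of purity p, heterozygous clonal SNVs in diploid (1+1) regions
# sit at VAF p/2, so twice the clonal VAF peak recovers purity independently
# of the copy-number-based estimate. NRPCC (reads per chromosome copy)
# summarizes the power to detect subclones from depth, purity and ploidy.

# Local maxima of a density grid with a simple topographic prominence:
# height above the higher of the two saddles separating the peak from
# higher terrain (or the grid boundary).
density_peaks <- function(x, y) {
  n <- length(y)
  is_max <- which(
    y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  )
  if (!length(is_max)) return(tibble::tibble(x = numeric(), y = numeric(), prominence = numeric()))
  prom <- vapply(is_max, function(i) {
    left <- y[seq_len(i)]
    right <- y[i:n]
    higher_l <- which(left > y[i])
    higher_r <- which(right > y[i]) + i - 1L
    saddle_l <- if (length(higher_l)) min(y[max(higher_l):i]) else min(left)
    saddle_r <- if (length(higher_r)) min(y[i:min(higher_r)]) else min(right)
    y[i] - max(saddle_l, saddle_r)
  }, numeric(1))
  tibble::tibble(x = x[is_max], y = y[is_max], prominence = prom)
}

#' Estimate tumor purity from the clonal VAF peak
#'
#' Restricts to SNVs inside clonal diploid (1+1, single-state) segments,
#' kernel-density-estimates the VAF distribution (Silverman's bandwidth),
#' finds local maxima with prominence at least `min_prominence` of the
#' density maximum, takes the local maximum at the largest VAF as the clonal
#' peak, and reports `purity = 2 * clonal peak VAF`. Ties between
#' equal-height peaks resolve to the larger VAF.
#'
#' @param variants Variant tibble for one sample ([read_variants()] layout).
#' @param segments Segment tibble for the same sample; used to select clonal
#'   1+1 regions. Pass `NULL` if `variants` is already diploid-restricted.
#' @param min_snvs Minimum number of diploid SNVs required (default 50);
#'   below it no estimate is made and the result row carries `NA` with a
#'   flag.
#' @param min_prominence Peak prominence floor as a fraction of the maximum
#'   density (default 0.05).
#' @return One-row tibble: `sample_id`, `purity_vaf`, `clonal_peak_vaf`,
#'   `n_diploid_snvs`, `flagged` (TRUE when no estimate was possible or
#'   `purity_vaf` > 1).
#' @export
estimate_purity_from_vaf <- function(variants, segments = NULL, min_snvs = 50,
                                     min_prominence = 0.05) {
  sample_id <- unique(variants$sample_id)
  if (length(sample_id) != 1) {
    stop("estimate_purity_from_vaf expects a single sample", call. = FALSE)
  }
  if (!is.null(segments)) {
    dip <- segments |>
      dplyr::filter(
        .data$sample_id == !!sample_id,
        .data$n_major_1 == 1, .data$n_minor_1 == 1,
        .data$frac_1 == 1
      )
    variants <- join_segments(variants, dip)
    variants <- variants[!is.na(variants$n_major_1), , drop = FALSE]
  }
  vafs <- variants$vaf[is.finite(variants$vaf)]
  if (length(vafs) < min_snvs) {
    return(tibble::tibble(
      sample_id = sample_id, purity_vaf = NA_real_,
      clonal_peak_vaf = NA_real_, n_diploid_snvs = length(vafs),
      flagged = TRUE
    ))
  }
  d <- stats::density(vafs, bw = "nrd0", from = 0, to = 1, n = 512)
  pk <- density_peaks(d$x, d$y)
  pk <- pk[pk$prominence >= min_prominence * max(d$y), , drop = FALSE]
  if (!nrow(pk)) pk <- tibble::tibble(x = d$x[which.max(d$y)], y = max(d$y))
  peak <- max(pk$x) # largest-VAF qualifying peak = clonal peak
  purity <- 2 * peak
  tibble::tibble(
    sample_id = sample_id, purity_vaf = purity, clonal_peak_vaf = peak,
    n_diploid_snvs = length(vafs), flagged = purity > 1
  )
}

#' Flag samples with very low copy-number purity
#'
#' @param metadata Sample metadata tibble with a `purity` column.
#' @param threshold Exclusion threshold; samples with `purity < threshold`
#'   (strict) are flagged. Default 0.10.
#' @return `metadata` with a logical `low_purity_flag` column.
#' @export
flag_low_purity <- function(metadata, threshold = 0.10) {
  dplyr::mutate(metadata, low_purity_flag = .data$purity < threshold)
}

#' Number of reads per chromosome copy
#'
#' `nrpcc = mean_depth * purity / (purity * ploidy + 2 * (1 - purity))` —
#' the expected coverage supporting each copy of the tumor genome, the
#' quantity that limits subclone detectability.
#'
#' @param mean_depth Mean sequencing depth (> 0).
#' @param purity Tumor purity in `(0, 1]`.
#' @param ploidy Mean tumor ploidy (> 0).
#' @return Numeric NRPCC, vectorized.
#' @examples
#' compute_nrpcc(90, 0.5, 2) # 22.5
#' @export
compute_nrpcc <- function(mean_depth, purity, ploidy) {
  if (any(mean_depth <= 0 | purity <= 0 | ploidy <= 0)) {
    stop("mean_depth, purity and ploidy must all be > 0", call. = FALSE)
  }
  mean_depth * purity / (purity * ploidy + 2 * (1 - purity))
}

#' Filter samples by NRPCC
#'
#' Retains exactly the samples with `nrpcc >= min_nrpcc` (default 10, the
#' power threshold for detecting subclones of CCF > 0.3 at cohort depths).
#'
#' @param metadata Sample metadata tibble with `mean_depth`, `purity`,
#'   `ploidy` (an existing `nrpcc` column is reused).
#' @param min_nrpcc Retention threshold (>=, default 10).
#' @return The retained rows, with an `nrpcc` column.
#' @export
filter_by_nrpcc <- function(metadata, min_nrpcc = 10) {
  if (!"nrpcc" %in% names(metadata)) {
    metadata$nrpcc <- compute_nrpcc(
      metadata$mean_depth, metadata$purity, metadata$ploidy
    )
  }
  dplyr::filter(metadata, .data$nrpcc >= min_nrpcc)
}

#' Purity and power QC table for a cohort
#'
#' Combines the copy-number purity (from metadata), the independent
#' VAF-based estimate, NRPCC and the two QC flags into one table.
#'
#' @param variants Cohort variant tibble.
#' @param segments Cohort segment tibble.
#' @param metadata Sample metadata tibble.
#' @param low_purity_threshold,min_nrpcc,min_snvs See
#'   [flag_low_purity()], [filter_by_nrpcc()], [estimate_purity_from_vaf()].
#' @return Tibble: `sample_id`, `purity_cn`, `purity_vaf`, `n_diploid_snvs`,
#'   `nrpcc`, `low_purity_flag`, `nrpcc_pass`.
#' @export
purity_qc <- function(variants, segments, metadata,
                      low_purity_threshold = 0.10, min_nrpcc = 10,
                      min_snvs = 50) {
  est <- variants |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map_dfr(estimate_purity_from_vaf, segments = segments, min_snvs = min_snvs)
  metadata |>
    dplyr::left_join(
      dplyr::select(est, "sample_id", "purity_vaf", "n_diploid_snvs"),
      by = "sample_id"
    ) |>
    dplyr::mutate(
      purity_cn = .data$purity,
      nrpcc = compute_nrpcc(.data$mean_depth, .data$purity, .data$ploidy),
      low_purity_flag = .data$purity < low_purity_threshold,
      nrpcc_pass = .data$nrpcc >= min_nrpcc
    ) |>
    dplyr::select(
      "sample_id", "purity_cn", "purity_vaf", "n_diploid_snvs", "nrpcc",
      "low_purity_flag", "nrpcc_pass"
    )
}
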