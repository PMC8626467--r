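# Cancer cell fraction, multiplicity (NCBM) and binomial-interval clonality.
#
# The CCF of a variant adjusts its VAF for local copy number, tumor purity
# and multiplicity:
#
#   ccf = vaf * (purity * nt + 2 * (1 - purity)) / (purity * m)
#
# where nt is the (fraction-weighted) total tumor copy number at the locus and
# m the number of chromosome copies bearing the mutation (NCBM). Clonality is
# decided by pushing a 95% binomial interval on the VAF through the same map:
# a variant whose upper CCF bound reaches 1 does not deviate from clonality
# and is assigned CCF 1; otherwise it is subclonal and keeps its point CCF.

#' Effective total copy number of a segment
#'
#' Fraction-weighted total tumor copy number across the (up to two)
#' copy-number states of a segment:
#' `frac_1 * (n_major_1 + n_minor_1) + frac_2 * (n_major_2 + n_minor_2)`.
#'
#' @param segment One-row data frame (or list) with the segment columns of
#'   [read_segments()]. Vectorized over rows.
#' @return Numeric effective copy number (0 for homozygous deletions).
#' @examples
#' seg <- tibble::tibble(
#'   n_major_1 = 2, n_minor_1 = 1, frac_1 = 0.6,
#'   n_major_2 = 1, n_minor_2 = 1, frac_2 = 0.4
#' )
#' effective_copy_number(seg) # 0.6*3 + 0.4*2 = 2.6
#' @export
effective_copy_number <- function(segment) {
  s2 <- ifelse(
    is.na(segment$frac_2) | segment$frac_2 == 0,
    0,
    segment$frac_2 * (segment$n_major_2 + segment$n_minor_2)
  )
  segment$frac_1 * (segment$n_major_1 + segment$n_minor_1) + s2
}

#' Estimate mutation multiplicity (NCBM)
#'
#' The estimated number of chromosome copies bearing the mutation:
#' `round(vaf * (purity * nt + 2 * (1 - purity)) / purity)`, clamped to
#' `[1, max(n_major_max, 1)]`. A heterozygous diploid clonal variant has
#' multiplicity 1; a variant duplicated along with its allele before a gain
#' (or a whole-genome duplication) has multiplicity 2.
#'
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param nt Effective total tumor copy number at the locus (must be > 0;
#'   variants inside homozygous deletions have no defined multiplicity).
#' @param n_major_max Largest major-allele copy number across the segment's
#'   states; upper clamp for the estimate.
#' @return Integer multiplicity, vectorized.
#' @export
estimate_multiplicity <- function(vaf, purity, nt, n_major_max = NULL) {
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]", call. = FALSE)
  if (any(nt <= 0)) {
    stop("nt must be > 0 (homozygous-deletion loci are excluded upstream)",
      call. = FALSE
    )
  }
  if (is.null(n_major_max)) n_major_max <- ceiling(nt)
  m <- round(vaf * (purity * nt + 2 * (1 - purity)) / purity)
  as.integer(pmin(pmax(m, 1), pmax(n_major_max, 1)))
}

#' Cancer cell fraction of a variant
#'
#' `ccf = vaf * (purity * nt + 2 * (1 - purity)) / (purity * multiplicity)`.
#' Values above 1 can arise from read-sampling noise and are retained;
#' truncation to the clonal state is the job of [assign_clonality()].
#'
#' @inheritParams estimate_multiplicity
#' @param multiplicity Integer NCBM >= 1.
#' @return Numeric CCF, vectorized.
#' @examples
#' compute_ccf(vaf = 0.25, purity = 0.5, nt = 2, multiplicity = 1) # 1
#' compute_ccf(vaf = 0.10, purity = 0.5, nt = 2, multiplicity = 1) # 0.4
#' @export
compute_ccf <- function(vaf, purity, nt, multiplicity) {
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1", call. = FALSE)
  vaf * (purity * nt + 2 * (1 - purity)) / (purity * multiplicity)
}

# 95% binomial interval on the success probability for x successes in n
# trials. Clopper-Pearson (exact, beta quantiles) by default; a normal
# (Wald) approximation is kept behind the flag for comparison.
binom_interval <- function(x, n, conf = 0.95, method = c("clopper-pearson", "normal")) {
  method <- match.arg(method)
  a <- (1 - conf) / 2
  if (method == "clopper-pearson") {
    lo <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
    hi <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  } else {
    p <- x / n
    se <- sqrt(p * (1 - p) / n)
    z <- stats::qnorm(1 - a)
    lo <- pmax(0, p - z * se)
    hi <- pmin(1, p + z * se)
  }
  list(lower = lo, upper = hi)
}

#' Clonality call from read counts
#'
#' Models the observed VAF as binomial, takes the 95% interval on the VAF,
#' and maps point and bounds through [compute_ccf()]. Variants whose upper
#' CCF bound reaches 1 are not distinguishable from clonal and are reported
#' with `status = "clonal"` and `ccf = 1`; otherwise the point CCF is kept
#' and `status = "subclonal"`. This avoids any arbitrary CCF cut-off.
#'
#' @param alt_count,depth Alt-supporting and total read counts (depth > 0).
#' @param purity Tumor purity in `(0, 1]`.
#' @param nt Effective total copy number at the locus.
#' @param multiplicity Integer NCBM >= 1 (see [estimate_multiplicity()]).
#' @param ci_method `"clopper-pearson"` (exact, default) or `"normal"`.
#' @return Tibble with columns `ccf` (1 for clonal calls), `ccf_point` (the
#'   raw point estimate), `ccf_low`, `ccf_high`, `status`, `multiplicity`.
#' @examples
#' assign_clonality(45, 90, purity = 0.5, nt = 2, multiplicity = 1)$status
#' assign_clonality(10, 100, purity = 0.5, nt = 2, multiplicity = 1)$ccf
#' @export
assign_clonality <- function(alt_count, depth, purity, nt, multiplicity,
                             ci_method = c("clopper-pearson", "normal")) {
  if (any(depth <= 0)) stop("depth must be > 0", call. = FALSE)
  if (any(alt_count < 0 | alt_count > depth)) {
    stop("need 0 <= alt_count <= depth", call. = FALSE)
  }
  ci_method <- match.arg(ci_method)
  vaf <- alt_count / depth
  ci <- binom_interval(alt_count, depth, method = ci_method)
  point <- compute_ccf(vaf, purity, nt, multiplicity)
  lo <- compute_ccf(ci$lower, purity, nt, multiplicity)
  hi <- compute_ccf(ci$upper, purity, nt, multiplicity)
  clonal <- hi >= 1
  tibble::tibble(
    ccf = ifelse(clonal, 1, point),
    ccf_point = point,
    ccf_low = lo,
    ccf_high = hi,
    status = ifelse(clonal, "clonal", "subclonal"),
    multiplicity = as.integer(multiplicity)
  )
}

#' Classify a mutation relative to whole-genome duplication
#'
#' In a WGD tumor a clonal mutation present on two or more chromosome copies
#' (NCBM >= 2) must have preceded the duplication, while a clonal mutation on
#' a single copy arose after it; subclonal mutations postdate the (clonal)
#' WGD. Non-WGD samples get `"not_applicable"`.
#'
#' @param status `"clonal"` or `"subclonal"` (vectorized).
#' @param multiplicity Integer NCBM.
#' @param sample_is_wgd Logical flag (scalar or vectorized).
#' @return Character vector: `"pre_wgd"`, `"post_wgd"` or `"not_applicable"`.
#' @export
classify_wgd_timing <- function(status, multiplicity, sample_is_wgd) {
  ifelse(
    !sample_is_wgd,
    "not_applicable",
    ifelse(
      status == "subclonal", "post_wgd",
      ifelse(multiplicity >= 2, "pre_wgd", "post_wgd")
    )
  )
}

#' Per-variant CCF and clonality for a cohort
#'
#' Joins variants to the copy-number segment covering each position, computes
#' effective copy number, multiplicity, CCF with binomial-interval clonality,
#' and the pre/post-WGD timing class. Variants falling in homozygous
#' deletions or outside any segment cannot carry a CCF and are returned in
#' the `dropped` attribute (and counted in a message).
#'
#' @param variants Variant tibble ([read_variants()] layout).
#' @param segments Segment tibble ([read_segments()] layout).
#' @param metadata Sample metadata tibble ([read_sample_metadata()] layout);
#'   supplies purity and ploidy. WGD status for the timing class comes from
#'   [call_wgd_for_timing()] (ploidy > 3) unless a logical `wgd` column is
#'   already present.
#' @param ci_method Passed to [assign_clonality()].
#' @return Tibble: variant columns plus `nt`, `multiplicity`, `ccf`,
#'   `ccf_low`, `ccf_high`, `status`, `timing_class`. Attribute `dropped`
#'   holds the excluded variants with a `drop_reason` column.
#' @export
ccf_calls <- function(variants, segments, metadata,
                      ci_method = c("clopper-pearson", "normal")) {
  ci_method <- match.arg(ci_method)
  if (!"wgd" %in% names(metadata)) {
    metadata$wgd <- call_wgd_for_timing(metadata$ploidy)
  }
  x <- variants |>
    dplyr::inner_join(
      dplyr::select(metadata, "sample_id", "purity", "wgd"),
      by = "sample_id"
    ) |>
    join_segments(segments)
  x$nt <- effective_copy_number(x)
  no_seg <- is.na(x$n_major_1)
  in_hd <- !no_seg & x$nt <= 0
  dropped <- x[no_seg | in_hd, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$drop_reason <- ifelse(
      is.na(dropped$n_major_1), "no_segment", "homozygous_deletion"
    )
    message(
      nrow(dropped), " variant(s) excluded from CCF analysis (",
      sum(no_seg), " uncovered, ", sum(in_hd), " in homozygous deletions)"
    )
  }
  x <- x[!(no_seg | in_hd), , drop = FALSE]
  n_major_max <- pmax(x$n_major_1, ifelse(is.na(x$n_major_2), 0, x$n_major_2))
  x$multiplicity <- estimate_multiplicity(x$vaf, x$purity, x$nt, n_major_max)
  cl <- assign_clonality(x$alt_count, x$depth, x$purity, x$nt, x$multiplicity,
    ci_method = ci_method
  )
  x$ccf <- cl$ccf
  x$ccf_point <- cl$ccf_point
  x$ccf_low <- cl$ccf_low
  x$ccf_high <- cl$ccf_high
  x$status <- cl$status
  x$timing_class <- classify_wgd_timing(x$status, x$multiplicity, x$wgd)
  out <- dplyr::select(
    x, dplyr::all_of(variant_cols), "purity", "nt", "multiplicity",
    "ccf", "ccf_point", "ccf_low", "ccf_high", "status", "timing_class"
  )
  attr(out, "dropped") <- dropped
  out
}

# Annotate each variant row with the covering segment's copy-number columns.
# Interval join per (sample, chrom) using findInterval on segment starts.
join_segments <- function(variants, segments) {
  seg_cols <- c(
    "n_major_1", "n_minor_1", "frac_1", "n_major_2", "n_minor_2", "frac_2"
  )
  for (cc in seg_cols) variants[[cc]] <- NA_real_
  if (!nrow(variants) || !nrow(segments)) return(variants)
  segs <- dplyr::arrange(segments, .data$sample_id, .data$chrom, .data$start)
  key_v <- paste(variants$sample_id, variants$chrom)
  key_s <- paste(segs$sample_id, segs$chrom)
  for (k in unique(key_v)) {
    vi <- which(key_v == k)
    si <- which(key_s == k)
    if (!length(si)) next
    idx <- findInterval(variants$pos[vi], segs$start[si])
    hit <- idx >= 1 & idx <= length(si)
    hit[hit] <- variants$pos[vi][hit] <= segs$end[si][idx[hit]]
    for (cc in seg_cols) {
      variants[[cc]][vi[hit]] <- segs[[cc]][si[idx[hit]]]
    }
  }
  variants
}
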