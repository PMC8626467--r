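# Readers and writers for the tabular formats the pipeline touches.
# Variants come in as VCF 4.x (CHROM POS REF ALT + FORMAT AD/DP) or as TSV;
# copy-number segments, mutation clusters and sample metadata are TSV with
# the Battenberg-style column layout documented on each reader.

variant_cols <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "alt_count", "depth", "vaf",
  "gene", "is_coding"
)

validate_variants <- function(x, context = "variant table") {
  bad <- which(
    !is.finite(x$depth) | x$depth <= 0 |
      !is.finite(x$alt_count) | x$alt_count < 0 | x$alt_count > x$depth |
      !is.finite(x$pos) | x$pos < 1
  )
  if (length(bad)) {
    stop(
      context, ": invalid record at row ", bad[1],
      " (need depth > 0 and 0 <= alt_count <= depth)",
      call. = FALSE
    )
  }
  invisible(x)
}

#' Read somatic variants from VCF or TSV
#'
#' Reads one sample's somatic SNV/indel calls. VCF input uses a deliberately
#' small subset of the format: `CHROM`, `POS`, `REF`, `ALT` and the per-sample
#' `AD` (ref,alt allelic depths) or `AD`+`DP` FORMAT fields. Multi-allelic
#' records are rejected with an error rather than silently decomposed.
#' TSV input needs columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#' `alt_count`, `depth` and optionally `gene`, `is_coding` and a
#' pre-corrected `vaf` (e.g. from an indel-realignment VAF correction; when
#' absent, `vaf = alt_count / depth`).
#'
#' @param path Path to a `.vcf` file or a TSV file.
#' @param sample_id Sample identifier. Required for VCFs with more than one
#'   sample column; defaults to the VCF's single sample name or the TSV
#'   `sample` column.
#' @return Tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth`, `vaf`, `gene`, `is_coding`, sorted by
#'   (`chrom`, `pos`). Positions are 1-based; chromosome names have any
#'   `"chr"` prefix stripped.
#' @export
read_variants <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", path) || grepl("^##fileformat=VCF", first)) {
    out <- read_variants_vcf(path, sample_id)
  } else {
    out <- read_variants_tsv(path, sample_id)
  }
  validate_variants(out, context = path)
  dplyr::arrange(out, .data$sample_id, .data$chrom, .data$pos)
}

read_variants_vcf <- function(path, sample_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(), pos = numeric(),
      ref = character(), alt = character(), alt_count = integer(),
      depth = integer(), vaf = numeric(), gene = character(),
      is_coding = logical()
    ))
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop(
      "multi-allelic record at ", path, " line with POS ",
      fix$POS[grepl(",", fix$ALT, fixed = TRUE)][1],
      "; decompose upstream before reading",
      call. = FALSE
    )
  }
  samples <- colnames(v@gt)[-1]
  if (is.null(sample_id)) {
    if (length(samples) != 1) {
      stop("VCF has ", length(samples), " samples; supply sample_id",
        call. = FALSE
      )
    }
    sample_id <- samples[1]
  } else if (!sample_id %in% samples) {
    stop("sample ", sample_id, " not in VCF", call. = FALSE)
  }
  ad <- vcfR::extract.gt(v, element = "AD")[, sample_id]
  if (all(is.na(ad))) {
    stop("VCF lacks the AD depth field needed for read counts", call. = FALSE)
  }
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_n <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  alt_n <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, sample_id]))
  depth <- ifelse(is.na(dp), ref_n + alt_n, dp)
  if (anyNA(alt_n) || anyNA(depth)) {
    stop(
      "malformed AD/DP at ", path, " line with POS ",
      fix$POS[which(is.na(alt_n) | is.na(depth))[1]],
      call. = FALSE
    )
  }
  tibble::tibble(
    sample_id = sample_id,
    chrom = normalize_chrom(fix$CHROM),
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    alt_count = alt_n,
    depth = as.integer(depth),
    vaf = alt_n / depth,
    gene = NA_character_,
    is_coding = FALSE
  )
}

read_variants_tsv <- function(path, sample_id) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "chrom", "pos", "ref", "alt", "alt_count", "depth")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("variant TSV missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    sample_id = as.character(x$sample),
    chrom = normalize_chrom(x$chrom),
    pos = as.numeric(x$pos),
    ref = as.character(x$ref),
    alt = as.character(x$alt),
    alt_count = as.integer(x$alt_count),
    depth = as.integer(x$depth),
    vaf = if ("vaf" %in% names(x)) as.numeric(x$vaf) else x$alt_count / x$depth,
    gene = if ("gene" %in% names(x)) as.character(x$gene) else NA_character_,
    is_coding = if ("is_coding" %in% names(x)) as.logical(x$is_coding) else FALSE
  )
  if (!is.null(sample_id)) out <- dplyr::filter(out, .data$sample_id == !!sample_id)
  out
}

#' Read allele-specific copy-number segments
#'
#' Reads a Battenberg-style segment table: one row per segment per sample,
#' with up to two copy-number states (a clonal state, and optionally a second
#' subclonal state with its cell fraction). Expected TSV columns: `sample`,
#' `chrom`, `startpos`, `endpos`, `nMaj1`, `nMin1`, `frac1`, and optionally
#' `nMaj2`, `nMin2`, `frac2`. State fractions are renormalized to sum to 1;
#' overlapping segments within a sample are resolved deterministically by
#' keeping the first (by start) and dropping the overlap with a warning.
#'
#' @param path TSV path.
#' @return Tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_major_1`, `n_minor_1`, `frac_1`, `n_major_2`, `n_minor_2`, `frac_2`,
#'   sorted by (`sample_id`, `chrom`, `start`). Single-state segments carry
#'   `frac_2 = 0` and `NA` state-2 copy numbers.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "chrom", "startpos", "endpos", "nMaj1", "nMin1", "frac1")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("segment TSV missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    sample_id = as.character(x$sample),
    chrom = normalize_chrom(x$chrom),
    start = as.numeric(x$startpos),
    end = as.numeric(x$endpos),
    n_major_1 = as.numeric(x$nMaj1),
    n_minor_1 = as.numeric(x$nMin1),
    frac_1 = as.numeric(x$frac1),
    n_major_2 = if ("nMaj2" %in% names(x)) as.numeric(x$nMaj2) else NA_real_,
    n_minor_2 = if ("nMin2" %in% names(x)) as.numeric(x$nMin2) else NA_real_,
    frac_2 = if ("frac2" %in% names(x)) as.numeric(x$frac2) else NA_real_
  )
  validate_segments(out, context = path)
}

validate_segments <- function(out, context = "segment table") {
  if (any(out$end < out$start)) {
    stop(context, ": segment with end < start at row ",
      which(out$end < out$start)[1],
      call. = FALSE
    )
  }
  if (any(out$n_major_1 < 0 | out$n_minor_1 < 0, na.rm = TRUE)) {
    stop(context, ": negative copy number", call. = FALSE)
  }
  out$frac_2[is.na(out$frac_2)] <- 0
  no2 <- out$frac_2 == 0
  out$n_major_2[no2] <- NA_real_
  out$n_minor_2[no2] <- NA_real_
  tot <- out$frac_1 + out$frac_2
  if (any(!is.finite(tot) | tot <= 0)) {
    stop(context, ": state fractions must be positive", call. = FALSE)
  }
  out$frac_1 <- out$frac_1 / tot
  out$frac_2 <- out$frac_2 / tot
  out <- dplyr::arrange(out, .data$sample_id, .data$chrom, .data$start, .data$end)
  # deterministic overlap resolution: keep the earlier segment, drop the later
  keep <- rep(TRUE, nrow(out))
  grp <- paste(out$sample_id, out$chrom)
  last_end <- stats::ave(out$end, grp, FUN = function(e) dplyr::lag(cummax(e), default = -Inf))
  ov <- out$start <= last_end
  if (any(ov)) {
    warning(
      sum(ov), " overlapping segment(s) dropped (kept first by position)",
      call. = FALSE
    )
    keep[ov] <- FALSE
  }
  out[keep, , drop = FALSE]
}

#' Read a mutation-cluster table
#'
#' Reads per-sample mutation clusters (e.g. exported from a Dirichlet-process
#' clustering tool) with columns `sample`, `cluster`, `ccf_peak`,
#' `n_mutations`. The cluster whose peak lies closest to CCF 1 is flagged as
#' the clonal cluster of each sample.
#'
#' @param path TSV path.
#' @return Tibble with columns `sample_id`, `cluster`, `ccf_peak`,
#'   `n_mutations`, `is_clonal`.
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "cluster", "ccf_peak", "n_mutations")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("cluster TSV missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    sample_id = as.character(x$sample),
    cluster = as.character(x$cluster),
    ccf_peak = as.numeric(x$ccf_peak),
    n_mutations = as.integer(x$n_mutations)
  )
  if (any(out$ccf_peak <= 0 | out$ccf_peak > 1.5)) {
    stop("ccf_peak must lie in (0, 1.5]", call. = FALSE)
  }
  if (any(out$n_mutations < 1)) stop("n_mutations must be >= 1", call. = FALSE)
  out |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(is_clonal = dplyr::row_number(abs(.data$ccf_peak - 1)) == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$ccf_peak))
}

#' Read per-sample metadata
#'
#' Columns: `sample`, `group`, `subtype`, `purity`, `ploidy`, `depth`.
#'
#' @param path TSV path.
#' @return Tibble with columns `sample_id`, `group`, `subtype`, `purity`,
#'   `ploidy`, `mean_depth`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "group", "subtype", "purity", "ploidy", "depth")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("metadata TSV missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    sample_id = as.character(x$sample),
    group = as.character(x$group),
    subtype = as.character(x$subtype),
    purity = as.numeric(x$purity),
    ploidy = as.numeric(x$ploidy),
    mean_depth = as.numeric(x$depth)
  )
  if (any(out$purity <= 0 | out$purity > 1)) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  if (any(out$ploidy <= 0)) stop("ploidy must be > 0", call. = FALSE)
  dplyr::arrange(out, .data$sample_id)
}

#' Write a result table to TSV
#'
#' Tab-separated with header, fixed column order (as supplied) and
#' deterministic row order (rows sorted lexicographically over all columns),
#' so identical inputs always produce identical bytes.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- dplyr::arrange(table, dplyr::across(dplyr::everything()))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(table)
}

#' Write tables in the reader dialects
#'
#' Inverse writers for [read_variants()], [read_segments()],
#' [read_clusters()] and [read_sample_metadata()]: they emit exactly the
#' column layout the corresponding reader expects, so write-then-read
#' round-trips reproduce the in-memory values.
#'
#' @param variants,segments,clusters,metadata Tibbles in the package's
#'   internal column layout.
#' @param path Output TSV path.
#' @return The input, invisibly.
#' @name write_dialects
NULL

#' @rdname write_dialects
#' @export
write_variants_tsv <- function(variants, path) {
  out <- tibble::tibble(
    sample = variants$sample_id, chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt, alt_count = variants$alt_count,
    depth = variants$depth, vaf = variants$vaf, gene = variants$gene,
    is_coding = variants$is_coding
  )
  readr::write_tsv(dplyr::arrange(out, sample, chrom, pos), path, progress = FALSE)
  invisible(variants)
}

#' @rdname write_dialects
#' @export
write_segments_tsv <- function(segments, path) {
  out <- tibble::tibble(
    sample = segments$sample_id, chrom = segments$chrom,
    startpos = segments$start, endpos = segments$end,
    nMaj1 = segments$n_major_1, nMin1 = segments$n_minor_1,
    frac1 = segments$frac_1, nMaj2 = segments$n_major_2,
    nMin2 = segments$n_minor_2, frac2 = segments$frac_2
  )
  readr::write_tsv(dplyr::arrange(out, sample, chrom, startpos), path, progress = FALSE)
  invisible(segments)
}

#' @rdname write_dialects
#' @export
write_clusters_tsv <- function(clusters, path) {
  out <- tibble::tibble(
    sample = clusters$sample_id, cluster = clusters$cluster,
    ccf_peak = clusters$ccf_peak, n_mutations = clusters$n_mutations
  )
  readr::write_tsv(dplyr::arrange(out, sample, cluster), path, progress = FALSE)
  invisible(clusters)
}

#' @rdname write_dialects
#' @export
write_metadata_tsv <- function(metadata, path) {
  out <- tibble::tibble(
    sample = metadata$sample_id, group = metadata$group,
    subtype = metadata$subtype, purity = metadata$purity,
    ploidy = metadata$ploidy, depth = metadata$mean_depth
  )
  readr::write_tsv(dplyr::arrange(out, sample), path, progress = FALSE)
  invisible(metadata)
}
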