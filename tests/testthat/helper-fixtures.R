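# Shared fixtures built in code. All randomized helpers take an explicit
# seed so tests are reproducible.

toy_genome <- function() genome_model("toy")

# Minimal single-sample VCF with AD/DP fields.
write_test_vcf <- function(path, rows, sample = "S1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- vapply(rows, function(r) {
    paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "AD:DP",
      paste0(r$ref_n, ",", r$alt_n, ":", r$dp),
      sep = "\t"
    )
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# One-sample segment tibble in internal layout.
make_segments <- function(sample_id, states) {
  # states: list of list(chrom, start, end, maj, min, frac = 1, maj2, min2)
  purrr::map_dfr(states, function(s) {
    tibble::tibble(
      sample_id = sample_id, chrom = as.character(s$chrom),
      start = s$start, end = s$end,
      n_major_1 = s$maj, n_minor_1 = s$min,
      frac_1 = s$frac %||% 1,
      n_major_2 = s$maj2 %||% NA_real_,
      n_minor_2 = s$min2 %||% NA_real_,
      frac_2 = if (is.null(s$frac) || s$frac == 1) 0 else 1 - s$frac
    )
  })
}

make_meta <- function(sample_id, purity = 0.5, ploidy = 2, depth = 90,
                      group = "A", subtype = "ER+") {
  tibble::tibble(
    sample_id = sample_id, group = group, subtype = subtype,
    purity = purity, ploidy = ploidy, mean_depth = depth
  )
}

# Variants at given positions with binomial reads around an expected VAF.
make_variants <- function(sample_id, chrom, pos, alt_count, depth,
                          gene = NA_character_, is_coding = FALSE) {
  tibble::tibble(
    sample_id = sample_id, chrom = as.character(chrom), pos = pos,
    ref = "A", alt = "T", alt_count = as.integer(alt_count),
    depth = as.integer(depth), vaf = alt_count / depth,
    gene = gene, is_coding = is_coding
  )
}

# Exhaustive-search PCF oracle for small n: all 2^(n-1) breakpoint sets.
pcf_oracle <- function(y, gamma) {
  n <- length(y)
  best <- Inf
  best_sets <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    cost <- gamma * length(cuts)
    for (k in seq_len(length(bounds) - 1)) {
      seg <- y[(bounds[k] + 1):bounds[k + 1]]
      cost <- cost + sum((seg - mean(seg))^2)
    }
    if (cost < best - 1e-12) {
      best <- cost
      best_sets <- bounds
    }
  }
  list(cost = best, bounds = best_sets)
}

# Independent two-sided Fisher p via full hypergeometric enumeration.
fisher_oracle_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
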