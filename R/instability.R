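# Genomic instability: whole-genome duplication, PGA/PGAn, kataegis.
#
# Two WGD definitions coexist deliberately: the descriptive call compares
# the genome fraction in a balanced tetraploid 2:2 state with the diploid
# 1:1 fraction, while the event call used by the timing model simply asks
# whether mean ploidy exceeds 3 (a sample can satisfy one and not the other).

clonal_state <- function(segments) {
  # copy-number state of the dominant (clonal) component
  paste0(segments$n_major_1, ":", segments$n_minor_1)
}

#' Call whole-genome duplication from segment states
#'
#' WGD is called when the length-weighted fraction of the genome in a
#' balanced tetraploid 2:2 state exceeds the fraction in the diploid 1:1
#' state. Only clonal (single-state) segments count toward either fraction.
#'
#' @param segments Segment tibble for one sample.
#' @return Logical flag.
#' @export
call_wgd <- function(segments) {
  len <- segments$end - segments$start + 1
  clonal <- segments$frac_1 == 1
  st <- clonal_state(segments)
  sum(len[clonal & st == "2:2"]) > sum(len[clonal & st == "1:1"])
}

#' Call WGD as a timeable event
#'
#' For chronological ordering, WGD is treated as an event in samples whose
#' mean ploidy exceeds 3 (strict).
#'
#' @param ploidy Mean tumor ploidy, vectorized.
#' @return Logical vector.
#' @export
call_wgd_for_timing <- function(ploidy) ploidy > 3

#' Proportion of genome altered and breakpoint count
#'
#' PGA is the length-weighted fraction of the segment-covered genome whose
#' copy-number state differs from the sample baseline: 1:1 for non-WGD
#' samples and the balanced tetraploid 2:2 for WGD samples. Subclonal
#' (two-state) segments count as altered. `n_breakpoints` counts, per
#' chromosome, transitions between adjacent segments with differing states;
#' both results are invariant to the row order of the table.
#'
#' @param segments Segment tibble for one sample.
#' @param wgd Logical; baseline 2:2 when TRUE, 1:1 otherwise (see
#'   [call_wgd()]).
#' @return One-row tibble with `pga` and `n_breakpoints`.
#' @export
compute_pga <- function(segments, wgd = FALSE) {
  segments <- dplyr::arrange(segments, .data$chrom, .data$start)
  baseline <- if (wgd) "2:2" else "1:1"
  len <- segments$end - segments$start + 1
  st <- clonal_state(segments)
  altered <- st != baseline | segments$frac_1 < 1
  pga <- if (sum(len) > 0) sum(len[altered]) / sum(len) else 0
  state_key <- paste0(st, "/", ifelse(segments$frac_1 < 1,
    paste0(segments$n_major_2, ":", segments$n_minor_2, "@", segments$frac_1),
    ""
  ))
  nbp <- segments |>
    dplyr::mutate(key = state_key) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bp = sum(.data$key != dplyr::lag(.data$key), na.rm = TRUE)) |>
    dplyr::pull(.data$bp) |>
    sum()
  tibble::tibble(pga = pga, n_breakpoints = as.integer(nbp))
}

#' PGAn: geometric mean of PGA and breakpoint count
#'
#' `sqrt(pga * n_breakpoints)` — blends the length of copy-number change
#' (PGA) with its fragmentation (breakpoints), so that focal shattering and
#' broad arm-level change both register.
#'
#' @param pga Fraction in `[0, 1]`.
#' @param n_breakpoints Non-negative integer.
#' @return Numeric, vectorized.
#' @examples
#' compute_pgan(0.25, 100) # 5
#' @export
compute_pgan <- function(pga, n_breakpoints) sqrt(pga * n_breakpoints)

#' Exact piecewise constant fitting by dynamic programming
#'
#' Segments an ordered numeric signal into constant-mean pieces by exact
#' minimization of `sum of squared deviations + gamma * (number of
#' breakpoints)` over all segmentations (O(n^2) dynamic program, not a
#' heuristic).
#'
#' @param y Numeric signal, in order.
#' @param gamma Per-breakpoint penalty (>= 0).
#' @return Tibble with one row per segment: `start_idx`, `end_idx`, `mean`,
#'   `n`. Zero rows for empty input.
#' @export
pcf_segment <- function(y, gamma) {
  n <- length(y)
  if (n == 0) {
    return(tibble::tibble(
      start_idx = integer(), end_idx = integer(), mean = numeric(), n = integer()
    ))
  }
  if (n == 1) {
    return(tibble::tibble(start_idx = 1L, end_idx = 1L, mean = y, n = 1L))
  }
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    q <- cs2[j + 1] - cs2[i]
    q - s^2 / (j - i + 1)
  }
  f <- numeric(n + 1)
  prev <- integer(n)
  f[1] <- -gamma # first segment carries no breakpoint penalty
  for (j in seq_len(n)) {
    best <- Inf
    arg <- 1L
    for (i in seq_len(j)) {
      v <- f[i] + sse(i, j) + gamma
      if (v < best) {
        best <- v
        arg <- i
      }
    }
    f[j + 1] <- best
    prev[j] <- arg
  }
  ends <- integer(0)
  starts <- integer(0)
  j <- n
  while (j >= 1) {
    i <- prev[j]
    ends <- c(j, ends)
    starts <- c(i, starts)
    j <- i - 1L
  }
  tibble::tibble(
    start_idx = starts, end_idx = ends,
    mean = (cs[ends + 1] - cs[starts]) / (ends - starts + 1),
    n = ends - starts + 1L
  )
}

#' PCF segmentation of inter-mutation distances
#'
#' Computes log10 inter-mutation distances (each distance assigned to the
#' latter SNV of the pair) along one chromosome and segments them with
#' [pcf_segment()].
#'
#' @param positions Sorted SNV positions (bp) on one chromosome.
#' @param gamma PCF penalty on the log10 scale (default 8; see
#'   [detect_kataegis()]).
#' @return Tibble of segments over the distance sequence, with `mean_imd`
#'   (arithmetic mean of the raw distances) added; empty for < 2 positions.
#' @export
pcf_inter_mutation_distance <- function(positions, gamma = 8) {
  if (is.unsorted(positions, strictly = FALSE)) {
    stop("positions must be sorted", call. = FALSE)
  }
  if (length(positions) < 2) {
    return(tibble::tibble(
      start_idx = integer(), end_idx = integer(), mean = numeric(),
      n = integer(), mean_imd = numeric()
    ))
  }
  imd <- diff(positions)
  imd[imd < 1] <- 1 # co-located calls: floor at 1 bp for the log
  seg <- pcf_segment(log10(imd), gamma)
  seg$mean_imd <- vapply(
    seq_len(nrow(seg)),
    function(k) mean(imd[seg$start_idx[k]:seg$end_idx[k]]),
    numeric(1)
  )
  seg
}

#' Detect kataegis foci
#'
#' Localized hypermutation (kataegis) is detected per chromosome by
#' piecewise constant fitting of the log10 inter-mutation distance of all
#' SNVs: adjacent PCF segments whose mean inter-mutation distance is at most
#' `max_mean_imd` are merged, and a merged run qualifies as a focus when it
#' contains at least `min_snvs` consecutive SNVs (a segment of k distances
#' spans k + 1 SNVs). Indels are excluded; focus bounds are the first and
#' last SNV of the qualifying run.
#'
#' @param variants Variant tibble for one sample (SNVs are selected as
#'   single-base ref and alt).
#' @param gamma PCF penalty on log10 distances (default 8, calibrated on
#'   simulated cohorts so that minimum-size foci are isolated while a
#'   Poisson background yields none; see the methods vignette).
#' @param min_snvs Minimum consecutive SNVs per focus (default 6).
#' @param max_mean_imd Maximum mean inter-mutation distance within a focus
#'   (default 1000 bp).
#' @return Tibble: `sample_id`, `chrom`, `start`, `end`, `n_snvs`,
#'   `mean_imd`; zero rows when no focus qualifies.
#' @export
detect_kataegis <- function(variants, gamma = 8, min_snvs = 6,
                            max_mean_imd = 1000) {
  snv <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref != "-" & variants$alt != "-", , drop = FALSE]
  empty <- tibble::tibble(
    sample_id = character(), chrom = character(), start = numeric(),
    end = numeric(), n_snvs = integer(), mean_imd = numeric()
  )
  if (!nrow(snv)) return(empty)
  snv |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos) |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::group_map(function(g, key) {
      pos <- g$pos
      if (length(pos) < min_snvs) return(NULL)
      seg <- pcf_inter_mutation_distance(pos, gamma)
      if (!nrow(seg)) return(NULL)
      imd <- diff(pos)
      ok <- seg$mean_imd <= max_mean_imd
      cand <- list()
      if (any(ok)) {
        runs <- split(which(ok), cumsum(c(TRUE, diff(which(ok)) != 1)))
        cand <- lapply(runs, function(r) {
          c(seg$start_idx[r[1]], seg$end_idx[r[length(r)]])
        })
      }
      # a segment can absorb oversized flanking or interior distances and
      # fail the mean on their account alone: search it exhaustively for
      # qualifying sub-runs (>= min_snvs - 1 distances, mean <= threshold),
      # keeping maximal non-overlapping ones (longest first)
      for (k in which(!ok)) {
        i0 <- seg$start_idx[k]
        i1 <- seg$end_idx[k]
        len_min <- min_snvs - 1L
        if (i1 - i0 + 1 < len_min) next
        cs <- c(0, cumsum(imd[i0:i1]))
        # exact prefilter: a qualifying window of any length implies a
        # qualifying window of length len_min (min sliding mean <= mean)
        win <- (cs[(len_min + 1):length(cs)] - cs[seq_len(length(cs) - len_min)]) / len_min
        if (all(win > max_mean_imd)) next
        runs <- list()
        for (a in seq_len(i1 - i0 + 2 - len_min)) {
          for (b in seq(a + len_min - 1, i1 - i0 + 1)) {
            if ((cs[b + 1] - cs[a]) / (b - a + 1) <= max_mean_imd) {
              runs <- c(runs, list(c(i0 + a - 1L, i0 + b - 1L)))
            }
          }
        }
        if (length(runs)) {
          runs <- runs[order(-vapply(runs, function(r) r[2] - r[1], numeric(1)))]
          taken <- logical(0)
          sel <- list()
          for (r in runs) {
            if (!any(vapply(sel, function(s2) r[1] <= s2[2] && r[2] >= s2[1], logical(1)))) {
              sel <- c(sel, list(r))
            }
          }
          cand <- c(cand, sel)
        }
      }
      if (!length(cand)) return(NULL)
      foci <- purrr::map_dfr(cand, function(b) {
        tibble::tibble(
          sample_id = key$sample_id, chrom = key$chrom,
          start = pos[b[1]], end = pos[b[2] + 1],
          n_snvs = b[2] - b[1] + 2L, mean_imd = mean(imd[b[1]:b[2]])
        )
      })
      foci <- foci[foci$n_snvs >= min_snvs & foci$mean_imd <= max_mean_imd, , drop = FALSE]
      dplyr::distinct(dplyr::arrange(foci, .data$start))
    }) |>
    purrr::compact() |>
    purrr::list_rbind() |>
    (\(x) if (nrow(x)) x else empty)()
}

#' Per-sample genomic-instability metrics
#'
#' Combines the WGD calls, PGA, breakpoint count, PGAn and kataegis focus
#' count into one row per sample.
#'
#' @param variants Cohort variant tibble (for kataegis).
#' @param segments Cohort segment tibble.
#' @param metadata Sample metadata tibble (ploidy for the timing WGD call).
#' @param gamma Kataegis PCF penalty.
#' @return Tibble: `sample_id`, `wgd`, `wgd_for_timing`, `pga`,
#'   `n_breakpoints`, `pgan`, `n_kataegis_foci`.
#' @export
instability_metrics <- function(variants, segments, metadata, gamma = 8) {
  foci <- detect_kataegis(variants, gamma = gamma)
  metadata |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map_dfr(function(m) {
      seg <- dplyr::filter(segments, .data$sample_id == m$sample_id)
      wgd <- call_wgd(seg)
      pg <- compute_pga(seg, wgd = wgd)
      tibble::tibble(
        sample_id = m$sample_id,
        wgd = wgd,
        wgd_for_timing = call_wgd_for_timing(m$ploidy),
        pga = pg$pga,
        n_breakpoints = pg$n_breakpoints,
        pgan = compute_pgan(pg$pga, pg$n_breakpoints),
        n_kataegis_foci = sum(foci$sample_id == m$sample_id)
      )
    })
}
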