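# Recurrent copy-number calling by permutation.
#
# Per-sample segments are first reduced to typed events (Gain / LOH / HD),
# the cohort landscape is built on the union of observed breakpoints, and
# interval frequencies are compared with a null in which every event is
# re-placed uniformly at random along its own chromosome (length and
# chromosome preserved). The null statistic is the genome-wide maximum
# interval frequency per permutation, which controls the family-wise
# background before BH correction across intervals.

#' Derive typed CNA events from segments
#'
#' Classification per copy-number state: homozygous deletion (HD) when total
#' copy number is 0; LOH when the minor allele is 0 with total >= 1; Gain
#' when total exceeds the sample baseline ploidy (2, or 4 under WGD). A
#' segment can emit more than one event (e.g. 3+0 is both LOH and Gain).
#' Clonality follows the state fraction: the full-fraction state is clonal,
#' any second state subclonal.
#'
#' @param segments Segment tibble ([read_segments()] layout), any number of
#'   samples.
#' @param metadata Optional sample metadata; a logical `wgd` column fixes
#'   the Gain baseline per sample, otherwise [call_wgd()] is applied to each
#'   sample's segments.
#' @return Tibble: `sample_id`, `chrom`, `start`, `end`, `type`
#'   (`"Gain"|"LOH"|"HD"`), `clonality`.
#' @export
derive_events <- function(segments, metadata = NULL) {
  wgd_by_sample <- if (!is.null(metadata) && "wgd" %in% names(metadata)) {
    stats::setNames(metadata$wgd, metadata$sample_id)
  } else {
    segs_split <- split(segments, segments$sample_id)
    vapply(segs_split, call_wgd, logical(1))
  }
  state_events <- function(n_major, n_minor, clonality, base) {
    tot <- n_major + n_minor
    types <- character(0)
    if (!is.na(tot)) {
      if (tot == 0) types <- "HD"
      else {
        if (n_minor == 0) types <- c(types, "LOH")
        if (tot > base) types <- c(types, "Gain")
      }
    }
    types
  }
  out <- purrr::pmap_dfr(
    segments,
    function(sample_id, chrom, start, end, n_major_1, n_minor_1, frac_1,
             n_major_2, n_minor_2, frac_2, ...) {
      base <- if (isTRUE(wgd_by_sample[[sample_id]])) 4 else 2
      rows <- list()
      t1 <- state_events(n_major_1, n_minor_1, frac_1, base)
      if (length(t1)) {
        rows <- c(rows, list(tibble::tibble(
          sample_id = sample_id, chrom = chrom, start = start, end = end,
          type = t1, clonality = if (frac_1 == 1) "clonal" else "subclonal"
        )))
      }
      if (!is.na(frac_2) && frac_2 > 0) {
        t2 <- state_events(n_major_2, n_minor_2, frac_2, base)
        if (length(t2)) {
          rows <- c(rows, list(tibble::tibble(
            sample_id = sample_id, chrom = chrom, start = start, end = end,
            type = t2, clonality = "subclonal"
          )))
        }
      }
      purrr::list_rbind(rows)
    }
  )
  if (!nrow(out)) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(), start = numeric(),
      end = numeric(), type = character(), clonality = character()
    ))
  }
  dplyr::distinct(
    dplyr::arrange(out, .data$sample_id, .data$chrom, .data$start, .data$type)
  )
}

# Per-chromosome interval frequencies at the union of event boundaries.
# Counts distinct samples per interval; intervals with zero events dropped.
landscape_one_type <- function(events, n_samples) {
  if (!nrow(events)) {
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      n_samples_mut = integer(), freq = numeric()
    ))
  }
  events |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(g, key) {
      bp <- sort(unique(c(g$start, g$end + 1)))
      if (length(bp) < 2) return(NULL)
      iv_start <- bp[-length(bp)]
      iv_end <- bp[-1] - 1
      cnt <- vapply(seq_along(iv_start), function(k) {
        length(unique(g$sample_id[g$start <= iv_start[k] & g$end >= iv_end[k]]))
      }, integer(1))
      keep <- cnt > 0
      tibble::tibble(
        chrom = key$chrom, start = iv_start[keep], end = iv_end[keep],
        n_samples_mut = cnt[keep], freq = cnt[keep] / n_samples
      )
    }) |>
    purrr::compact() |>
    purrr::list_rbind()
}

#' Cohort frequency landscape of one CNA type
#'
#' Partitions the genome at the union of all observed event boundaries of
#' the given type and annotates each interval with the fraction of samples
#' harboring such an event there.
#'
#' @param events Output of [derive_events()].
#' @param genome A [genome_model()] (bounds checking).
#' @param type `"Gain"`, `"LOH"` or `"HD"`.
#' @param n_samples Cohort size (denominator of the frequency).
#' @return Tibble: `chrom`, `start`, `end`, `type`, `n_samples_mut`, `freq`.
#' @export
frequency_landscape <- function(events, genome, type, n_samples) {
  ev <- dplyr::filter(events, .data$type == !!type)
  if (any(!ev$chrom %in% genome$chrom_names)) {
    stop("event on a chromosome absent from the genome model", call. = FALSE)
  }
  out <- landscape_one_type(ev, n_samples)
  if (nrow(out)) out$type <- type else out$type <- character(0)
  dplyr::relocate(out, "chrom", "start", "end", "type")
}

# Genome-wide maximum distinct-sample overlap count for an event set.
max_overlap_count <- function(events) {
  if (!nrow(events)) return(0L)
  max(vapply(split(events, events$chrom), function(g) {
    # merge per sample so each sample counts once at any position
    pieces <- lapply(split(g, g$sample_id), function(s) {
      o <- order(s$start)
      st <- s$start[o]
      en <- s$end[o]
      merged_s <- st[1]
      merged_e <- en[1]
      if (length(st) > 1) {
        for (k in 2:length(st)) {
          last <- length(merged_e)
          if (st[k] <= merged_e[last] + 1) {
            merged_e[last] <- max(merged_e[last], en[k])
          } else {
            merged_s <- c(merged_s, st[k])
            merged_e <- c(merged_e, en[k])
          }
        }
      }
      cbind(merged_s, merged_e)
    })
    st <- unlist(lapply(pieces, function(p) p[, 1]), use.names = FALSE)
    en <- unlist(lapply(pieces, function(p) p[, 2]), use.names = FALSE)
    ev <- rbind(
      cbind(pos = st, d = 1),
      cbind(pos = en + 1, d = -1)
    )
    ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
    max(cumsum(ev[, 2]))
  }, numeric(1)))
}

#' Permutation test for recurrent CNA regions
#'
#' For each CNA type, compares the observed interval frequencies of the
#' cohort landscape with `n_perm` permutations in which every event is
#' independently re-placed uniformly at random along its own chromosome
#' (event length and chromosome assignment preserved). The null statistic is
#' the genome-wide maximum interval frequency of each permutation;
#' `p = (1 + #(null max >= observed)) / (n_perm + 1)`. BH correction is
#' applied across all intervals of all types.
#'
#' @param events Output of [derive_events()].
#' @param genome A [genome_model()].
#' @param n_samples Cohort size.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param fdr Significance threshold on q (default 0.05).
#' @return Tibble: `chrom`, `start`, `end`, `type`, `n_samples_mut`,
#'   `freq`, `p_perm`, `q`, `significant`.
#' @export
permutation_test <- function(events, genome, n_samples, n_perm = 1000,
                             seed = 1, fdr = 0.05) {
  stopifnot(n_perm >= 1)
  lens <- events$end - events$start + 1
  chr_len <- genome$chrom_lengths[events$chrom]
  if (any(lens > chr_len)) {
    stop("event longer than its chromosome", call. = FALSE)
  }
  types <- sort(unique(events$type))
  obs <- purrr::map_dfr(
    types,
    function(tp) frequency_landscape(events, genome, tp, n_samples)
  )
  if (!nrow(obs)) {
    obs$p_perm <- numeric(0)
    obs$q <- numeric(0)
    obs$significant <- logical(0)
    return(obs)
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  null_max <- withr_seed({
    sapply(types, function(tp) {
      ev <- events[events$type == tp, , drop = FALSE]
      len <- ev$end - ev$start + 1
      cl <- unname(genome$chrom_lengths[ev$chrom])
      replicate(n_perm, {
        new_start <- floor(stats::runif(nrow(ev), min = 1, max = cl - len + 2))
        perm <- ev
        perm$start <- new_start
        perm$end <- new_start + len - 1
        max_overlap_count(perm) / n_samples
      })
    }, simplify = FALSE)
  })
  obs$p_perm <- vapply(seq_len(nrow(obs)), function(k) {
    nm <- null_max[[obs$type[k]]]
    (1 + sum(nm >= obs$freq[k])) / (n_perm + 1)
  }, numeric(1))
  obs$q <- stats::p.adjust(obs$p_perm, method = "BH")
  obs$significant <- obs$q < fdr
  obs
}

#' Flag excluded recurrent regions
#'
#' Applies the post-hoc region exclusions: regions overlapping a configured
#' HLA interval (the genome model's excluded regions), regions entirely
#' within the terminal `telomere_buffer` bp of their chromosome, and
#' singleton regions supported by exactly one sample.
#'
#' @param regions Output of [permutation_test()].
#' @param genome A [genome_model()]; its `excluded_regions` provide the HLA
#'   (and any other) masks.
#' @param telomere_buffer Width of the terminal zone in bp (default 1 Mb).
#' @return `regions` with an `excluded_reason` column
#'   (`"none"|"HLA"|"telomeric"|"singleton"`; first matching rule wins).
#' @export
filter_regions <- function(regions, genome, telomere_buffer = 1e6) {
  if (!nrow(regions)) {
    regions$excluded_reason <- character(0)
    return(regions)
  }
  excl <- genome$excluded_regions
  reason <- rep("none", nrow(regions))
  if (nrow(excl)) {
    hit <- vapply(seq_len(nrow(regions)), function(k) {
      any(excl$chrom == regions$chrom[k] &
        excl$start <= regions$end[k] & excl$end >= regions$start[k])
    }, logical(1))
    reason[hit] <- excl$label[1]
  }
  chr_len <- unname(genome$chrom_lengths[regions$chrom])
  telo <- regions$end <= telomere_buffer |
    regions$start >= chr_len - telomere_buffer + 1
  reason[reason == "none" & telo] <- "telomeric"
  reason[reason == "none" & regions$n_samples_mut == 1] <- "singleton"
  regions$excluded_reason <- reason
  regions
}

#' Recurrent CNA analysis end to end
#'
#' [derive_events()] then [permutation_test()] then [filter_regions()].
#'
#' @inheritParams permutation_test
#' @inheritParams filter_regions
#' @param segments Cohort segment tibble.
#' @param metadata Sample metadata tibble.
#' @return The filtered region table.
#' @export
cna_recurrence <- function(segments, metadata, genome, n_perm = 1000,
                           seed = 1, fdr = 0.05, telomere_buffer = 1e6) {
  events <- derive_events(segments, metadata)
  regions <- permutation_test(
    events, genome,
    n_samples = dplyr::n_distinct(metadata$sample_id),
    n_perm = n_perm, seed = seed, fdr = fdr
  )
  filter_regions(regions, genome, telomere_buffer = telomere_buffer)
}
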