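# Synthetic tumor-cohort simulator.
#
# Generates complete cohorts — variants with binomial read counts,
# Battenberg-style segment tables, mutation clusters, metadata — plus truth
# tables, with the statistical structure the analysis modules assume:
# purity-diluted VAFs, clonal and subclonal CCF clusters obeying the sum
# rule, optional whole-genome duplication with pre/post-WGD multiplicities,
# typed CNA events with per-group prevalences, localized hypermutation
# (kataegis) runs, and optionally elevated hotspot bins.

#' Simulation configuration
#'
#' Builds a validated configuration list for [simulate_cohort()]. Defaults
#' describe a small two-group cohort on the toy genome at 90x depth with
#' purity uniform on 0.1-0.9, a 20% WGD rate and up to two subclones.
#'
#' @param groups Named integer vector: samples per group.
#' @param genome A [genome_model()].
#' @param depth_mean Mean sequencing depth (reads); per-variant depths are
#'   Poisson around it.
#' @param purity_range Uniform purity range.
#' @param wgd_probability Probability a sample carries WGD.
#' @param wgd_rel_time Relative time of WGD on the latent 0-1 axis; clonal
#'   events earlier than this are pre-WGD in WGD samples.
#' @param event_catalog Tibble of cohort events: `event_id`, `type`
#'   (`"Gain"|"LOH"|"HD"|"driver"`), `chrom`, `start`, `end`, `gene`
#'   (drivers), `true_rel_time` in `[0, 1]`, and either a numeric
#'   `prevalence` column or per-group columns `prev_<group>`.
#' @param clonal_prob_slope `P(clonal | t) = 1 - slope * t`: the monotone
#'   link between an event's latent time and its chance of being clonal in
#'   a sample.
#' @param max_subclones Maximum subclonal clusters per sample (chain
#'   phylogeny, so the CCF sum rule always holds).
#' @param subclone_ccf_range CCF range subclone peaks are drawn from.
#' @param clonal_mut_fraction Expected fraction of background SNVs in the
#'   clonal cluster.
#' @param pre_wgd_fraction Fraction of clonal background SNVs predating WGD
#'   (multiplicity 2) in WGD samples.
#' @param mutation_rate Background SNVs per Mb.
#' @param kataegis List: `n_foci_range`, `n_snvs_range`, `spacing_mean`
#'   (bp; inter-SNV spacings are 1 + Poisson(spacing_mean - 1)).
#' @param hotspot_bins Optional tibble: `chrom`, `start` (bin start, 100-kb
#'   grid), and `prev_<group>` columns — per-sample probability of carrying
#'   SNVs in that bin.
#' @param subtypes Character vector sampled uniformly for the metadata
#'   `subtype` column.
#' @return A list of class `somevo_sim_config`.
#' @export
sim_config <- function(groups = c(A = 3, B = 3),
                       genome = genome_model("toy"),
                       depth_mean = 90,
                       purity_range = c(0.1, 0.9),
                       wgd_probability = 0.2,
                       wgd_rel_time = 0.3,
                       event_catalog = default_event_catalog(),
                       clonal_prob_slope = 0.6,
                       max_subclones = 2,
                       subclone_ccf_range = c(0.15, 0.7),
                       clonal_mut_fraction = 0.6,
                       pre_wgd_fraction = 0.4,
                       mutation_rate = 5,
                       kataegis = list(
                         n_foci_range = c(0, 2),
                         n_snvs_range = c(6, 20),
                         spacing_mean = 300
                       ),
                       hotspot_bins = NULL,
                       subtypes = c("ER+", "HER2+", "TNBC")) {
  stopifnot(
    length(groups) >= 1, !is.null(names(groups)), all(groups >= 1),
    inherits(genome, "genome_model"),
    depth_mean > 0,
    purity_range[1] > 0, purity_range[2] <= 1,
    wgd_probability >= 0, wgd_probability <= 1,
    clonal_prob_slope >= 0, clonal_prob_slope <= 1,
    max_subclones >= 0, mutation_rate >= 0
  )
  if (!is.null(event_catalog) && nrow(event_catalog)) {
    prev_cols <- c("prevalence", paste0("prev_", names(groups)))
    if (!any(prev_cols %in% names(event_catalog))) {
      stop("event_catalog needs a prevalence or prev_<group> column",
        call. = FALSE
      )
    }
    pr <- unlist(event_catalog[intersect(prev_cols, names(event_catalog))])
    if (any(pr < 0 | pr > 1, na.rm = TRUE)) {
      stop("prevalences must lie in [0, 1]", call. = FALSE)
    }
    if (any(event_catalog$true_rel_time < 0 | event_catalog$true_rel_time > 1)) {
      stop("true_rel_time must lie in [0, 1]", call. = FALSE)
    }
    # CNA loci must be disjoint per chromosome for segment construction
    cna <- event_catalog[event_catalog$type != "driver", , drop = FALSE]
    if (nrow(cna) > 1) {
      cna <- cna[order(cna$chrom, cna$start), ]
      same <- cna$chrom[-1] == cna$chrom[-nrow(cna)]
      if (any(same & cna$start[-1] <= cna$end[-nrow(cna)])) {
        stop("CNA catalog loci must be disjoint within a chromosome",
          call. = FALSE
        )
      }
    }
  }
  if (diff(range(subclone_ccf_range)) < 0 || subclone_ccf_range[2] > 1) {
    stop("invalid subclone_ccf_range (sum-rule violation)", call. = FALSE)
  }
  structure(
    list(
      groups = groups, genome = genome, depth_mean = depth_mean,
      purity_range = purity_range, wgd_probability = wgd_probability,
      wgd_rel_time = wgd_rel_time, event_catalog = event_catalog,
      clonal_prob_slope = clonal_prob_slope, max_subclones = max_subclones,
      subclone_ccf_range = subclone_ccf_range,
      clonal_mut_fraction = clonal_mut_fraction,
      pre_wgd_fraction = pre_wgd_fraction, mutation_rate = mutation_rate,
      kataegis = kataegis, hotspot_bins = hotspot_bins, subtypes = subtypes
    ),
    class = "somevo_sim_config"
  )
}

#' Default event catalog on the toy genome
#'
#' Three CNA events and three driver mutations with staggered latent times
#' and moderate prevalences; used by the `"tiny"` fixture.
#'
#' @return Catalog tibble (see [sim_config()]).
#' @export
default_event_catalog <- function() {
  tibble::tibble(
    event_id = c("1p_LOH", "3q_Gain", "2_HD", "TP53_mut", "PIK3CA_mut", "GATA3_mut"),
    type = c("LOH", "Gain", "HD", "driver", "driver", "driver"),
    chrom = c("1", "3", "2", "1", "2", "3"),
    start = c(1e6, 6e6, 4e6, 5e6, 2e6, 2.5e6),
    end = c(3e6, 9e6, 4.5e6, 5e6, 2e6, 2.5e6),
    gene = c(NA, NA, NA, "TP53", "PIK3CA", "GATA3"),
    true_rel_time = c(0.10, 0.35, 0.60, 0.05, 0.45, 0.75),
    prevalence = c(0.9, 0.7, 0.4, 0.8, 0.5, 0.4)
  )
}

prev_for <- function(catalog_row, group) {
  col <- paste0("prev_", group)
  if (col %in% names(catalog_row) && !is.na(catalog_row[[col]])) {
    catalog_row[[col]]
  } else {
    catalog_row[["prevalence"]]
  }
}

random_bases <- function(n, exclude = NULL) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    pool <- if (is.null(exclude)) bases else setdiff(bases, exclude[i])
    sample(pool, 1)
  }, character(1))
}

#' Simulate a synthetic tumor cohort
#'
#' Draws a full cohort under `config`. Per sample: purity and WGD status
#' are drawn; catalog events are instantiated by group prevalence, assigned
#' clonal status with probability `1 - clonal_prob_slope * t` (earlier
#' events clonal more often) and, in WGD samples, classified pre/post-WGD
#' against `wgd_rel_time`; segment tables are laid down consistent with the
#' instantiated CNAs over a 1+1 (or 2+2 under WGD) baseline; background
#' SNVs are scattered uniformly and attached to the clonal or a subclonal
#' CCF cluster; kataegis runs of tightly spaced SNVs are injected; and each
#' variant's reads are drawn as
#' `alt ~ Binomial(depth, purity * m * ccf / (purity * nt + 2 * (1 - purity)))`
#' with Poisson depth. Variants drawing zero alt reads are dropped (they
#' would not be called). Identical seeds give identical cohorts.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `somevo_cohort`: tibbles `variants`, `segments`,
#'   `metadata`, `clusters` (true clusters, reader layout) and `truth`
#'   (list: `samples`, `events`, `kataegis`, `catalog`, `wccf`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "somevo_sim_config"))
  set.seed(seed)
  genome <- config$genome
  chrom_len <- genome$chrom_lengths
  genome_mb <- sum(chrom_len) / 1e6
  catalog <- config$event_catalog
  if (is.null(catalog)) catalog <- default_event_catalog()[0, ]

  sample_ids <- unlist(lapply(names(config$groups), function(g) {
    sprintf("%s%02d", g, seq_len(config$groups[[g]]))
  }))
  group_of <- rep(names(config$groups), config$groups)

  all_var <- list()
  all_seg <- list()
  all_meta <- list()
  all_clu <- list()
  truth_samples <- list()
  truth_events <- list()
  truth_kat <- list()

  for (si in seq_along(sample_ids)) {
    sid <- sample_ids[si]
    grp <- group_of[si]
    purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
    wgd <- stats::runif(1) < config$wgd_probability
    base_maj <- if (wgd) 2 else 1
    base_min <- if (wgd) 2 else 1

    # subclone chain: decreasing CCFs, always sum-rule-valid
    n_sub <- sample.int(config$max_subclones + 1, 1) - 1L
    sub_ccf <- numeric(0)
    if (n_sub > 0) {
      lo <- config$subclone_ccf_range[1]
      hi <- config$subclone_ccf_range[2]
      sub_ccf <- sort(stats::runif(n_sub, lo, hi), decreasing = TRUE)
      # enforce separation so clusters are identifiable
      for (k in seq_len(n_sub)[-1]) {
        sub_ccf[k] <- min(sub_ccf[k], sub_ccf[k - 1] - 0.15)
      }
      sub_ccf <- sub_ccf[sub_ccf >= lo]
      n_sub <- length(sub_ccf)
    }
    cluster_ids <- c("clonal", if (n_sub) paste0("sub", seq_len(n_sub)))
    cluster_ccf <- c(1, sub_ccf)

    # instantiate catalog events
    ev_rows <- list()
    if (nrow(catalog)) {
      for (r in seq_len(nrow(catalog))) {
        row <- catalog[r, ]
        if (stats::runif(1) >= prev_for(row, grp)) next
        t <- row$true_rel_time
        clonal <- stats::runif(1) < (1 - config$clonal_prob_slope * t)
        clu <- if (clonal || n_sub == 0) "clonal" else sample(paste0("sub", rep(seq_len(n_sub), 2)), 1)
        ccf <- cluster_ccf[match(clu, cluster_ids)]
        wgd_class <- if (!wgd || clu != "clonal") {
          if (wgd) "post_wgd" else "not_applicable"
        } else if (t < config$wgd_rel_time) "pre_wgd" else "post_wgd"
        ev_rows <- c(ev_rows, list(tibble::tibble(
          sample_id = sid, event_id = row$event_id, type = row$type,
          chrom = row$chrom, start = row$start, end = row$end,
          gene = row$gene,
          clonality = ifelse(clu == "clonal", "clonal", "subclonal"),
          cluster = clu, ccf = ccf, wgd_class = wgd_class,
          true_rel_time = t
        )))
      }
    }
    events <- purrr::list_rbind(ev_rows)

    # segments: baseline per chromosome, CNA events carved out
    cna_states <- function(type) {
      if (wgd) {
        switch(type,
          Gain = c(3, 2), LOH = c(2, 0), HD = c(0, 0)
        )
      } else {
        switch(type,
          Gain = c(2, 1), LOH = c(1, 0), HD = c(0, 0)
        )
      }
    }
    seg_rows <- list()
    for (ch in genome$chrom_names) {
      cna_here <- if (nrow(events)) {
        events[events$type != "driver" & events$chrom == ch, , drop = FALSE]
      } else {
        events
      }
      if (!is.null(cna_here) && nrow(cna_here)) {
        cna_here <- cna_here[order(cna_here$start), , drop = FALSE]
      }
      cursor <- 1
      if (!is.null(cna_here) && nrow(cna_here)) {
        for (r in seq_len(nrow(cna_here))) {
          e <- cna_here[r, ]
          if (e$start > cursor) {
            seg_rows <- c(seg_rows, list(tibble::tibble(
              sample_id = sid, chrom = ch, start = cursor, end = e$start - 1,
              n_major_1 = base_maj, n_minor_1 = base_min, frac_1 = 1,
              n_major_2 = NA_real_, n_minor_2 = NA_real_, frac_2 = 0
            )))
          }
          st <- cna_states(e$type)
          if (e$clonality == "clonal") {
            seg_rows <- c(seg_rows, list(tibble::tibble(
              sample_id = sid, chrom = ch, start = e$start, end = e$end,
              n_major_1 = st[1], n_minor_1 = st[2], frac_1 = 1,
              n_major_2 = NA_real_, n_minor_2 = NA_real_, frac_2 = 0
            )))
          } else {
            seg_rows <- c(seg_rows, list(tibble::tibble(
              sample_id = sid, chrom = ch, start = e$start, end = e$end,
              n_major_1 = st[1], n_minor_1 = st[2], frac_1 = e$ccf,
              n_major_2 = base_maj, n_minor_2 = base_min, frac_2 = 1 - e$ccf
            )))
          }
          cursor <- e$end + 1
        }
      }
      if (cursor <= chrom_len[[ch]]) {
        seg_rows <- c(seg_rows, list(tibble::tibble(
          sample_id = sid, chrom = ch, start = cursor, end = chrom_len[[ch]],
          n_major_1 = base_maj, n_minor_1 = base_min, frac_1 = 1,
          n_major_2 = NA_real_, n_minor_2 = NA_real_, frac_2 = 0
        )))
      }
    }
    segments <- purrr::list_rbind(seg_rows)
    seg_len <- segments$end - segments$start + 1
    ploidy <- sum(seg_len * effective_copy_number(segments)) / sum(seg_len)

    # background SNV loci with cluster assignment
    n_bg <- stats::rpois(1, config$mutation_rate * genome_mb)
    clu_weights <- c(
      config$clonal_mut_fraction,
      if (n_sub) rep((1 - config$clonal_mut_fraction) / n_sub, n_sub)
    )
    clu_weights <- clu_weights / sum(clu_weights)
    bg <- NULL
    if (n_bg > 0) {
      chrom_bg <- sample(genome$chrom_names, n_bg,
        replace = TRUE, prob = unname(chrom_len) / sum(chrom_len)
      )
      pos_bg <- floor(stats::runif(n_bg, 1, unname(chrom_len[chrom_bg]) + 1))
      clu_bg <- sample(cluster_ids, n_bg, replace = TRUE, prob = clu_weights)
      bg <- tibble::tibble(
        chrom = chrom_bg, pos = pos_bg, cluster = clu_bg,
        ccf = cluster_ccf[match(clu_bg, cluster_ids)],
        gene = NA_character_, is_coding = FALSE,
        pre_wgd = wgd & clu_bg == "clonal" &
          stats::runif(n_bg) < config$pre_wgd_fraction
      )
    }

    # kataegis runs (clonal, single-copy)
    kat <- NULL
    kr <- config$kataegis
    sample_range <- function(rng) {
      v <- seq(rng[1], rng[2])
      if (length(v) == 1) v else sample(v, 1)
    }
    n_foci <- if (is.null(kr)) 0 else sample_range(kr$n_foci_range)
    if (n_foci > 0) {
      kat <- purrr::map_dfr(seq_len(n_foci), function(f) {
        ch <- sample(genome$chrom_names, 1)
        n_snv <- sample_range(kr$n_snvs_range)
        gaps <- 1 + stats::rpois(n_snv - 1, kr$spacing_mean - 1)
        start <- floor(stats::runif(1, 1, chrom_len[[ch]] - sum(gaps) - 1))
        tibble::tibble(
          chrom = ch, pos = start + c(0, cumsum(gaps)), focus = f,
          cluster = "clonal", ccf = 1, gene = NA_character_,
          is_coding = FALSE, pre_wgd = FALSE
        )
      })
      truth_kat <- c(truth_kat, list(
        kat |>
          dplyr::group_by(.data$focus) |>
          dplyr::summarise(
            chrom = .data$chrom[1], start = min(.data$pos), end = max(.data$pos),
            n_snvs = dplyr::n(), .groups = "drop"
          ) |>
          dplyr::mutate(sample_id = sid)
      ))
    }

    # hotspot-bin SNVs
    hot <- NULL
    hb <- config$hotspot_bins
    if (!is.null(hb) && nrow(hb)) {
      hot <- purrr::map_dfr(seq_len(nrow(hb)), function(r) {
        p <- hb[[paste0("prev_", grp)]][r]
        if (is.na(p) || stats::runif(1) >= p) return(NULL)
        k <- sample.int(3, 1)
        tibble::tibble(
          chrom = as.character(hb$chrom[r]),
          pos = floor(stats::runif(k, hb$start[r], hb$start[r] + 1e5)),
          cluster = "clonal", ccf = 1, gene = NA_character_,
          is_coding = FALSE, pre_wgd = FALSE
        )
      })
    }

    # driver SNVs from instantiated events
    drv <- NULL
    if (nrow(events)) {
      de <- events[events$type == "driver", , drop = FALSE]
      if (nrow(de)) {
        drv <- tibble::tibble(
          chrom = de$chrom, pos = de$start, cluster = de$cluster,
          ccf = de$ccf, gene = de$gene, is_coding = TRUE,
          pre_wgd = de$wgd_class == "pre_wgd"
        )
      }
    }

    loci <- dplyr::bind_rows(
      bg,
      if (!is.null(kat)) dplyr::select(kat, -"focus"),
      hot, drv
    )
    variants <- NULL
    if (!is.null(loci) && nrow(loci)) {
      loci <- join_segments(
        dplyr::mutate(loci, sample_id = sid, vaf = NA_real_), segments
      )
      nt <- effective_copy_number(loci)
      n_major_max <- pmax(loci$n_major_1, dplyr::coalesce(loci$n_major_2, 0))
      m <- ifelse(loci$pre_wgd & n_major_max >= 2, 2, 1)
      m <- pmin(m, pmax(n_major_max, 1))
      p_vaf <- ifelse(nt > 0,
        purity * m * loci$ccf / (purity * nt + 2 * (1 - purity)),
        0
      )
      depth_reads <- pmax(stats::rpois(nrow(loci), config$depth_mean), 1L)
      alt_reads <- stats::rbinom(nrow(loci), depth_reads, pmin(p_vaf, 1))
      ref_base <- random_bases(nrow(loci))
      variants <- tibble::tibble(
        sample_id = sid, chrom = loci$chrom, pos = loci$pos,
        ref = ref_base, alt = random_bases(nrow(loci), exclude = ref_base),
        alt_count = alt_reads, depth = as.integer(depth_reads),
        vaf = alt_reads / depth_reads,
        gene = loci$gene, is_coding = loci$is_coding,
        true_cluster = loci$cluster, true_ccf = loci$ccf,
        true_multiplicity = as.integer(m)
      )
      variants <- variants[variants$alt_count > 0, , drop = FALSE]
      variants <- dplyr::arrange(variants, .data$chrom, .data$pos)
    }

    # true cluster table with realized mutation counts
    counts <- if (!is.null(variants) && nrow(variants)) {
      table(factor(variants$true_cluster, levels = cluster_ids))
    } else {
      stats::setNames(rep(0L, length(cluster_ids)), cluster_ids)
    }
    clu_tbl <- tibble::tibble(
      sample_id = sid, cluster = cluster_ids,
      ccf_peak = cluster_ccf, n_mutations = as.integer(counts),
      is_clonal = cluster_ids == "clonal"
    )
    clu_tbl <- clu_tbl[clu_tbl$n_mutations > 0 | clu_tbl$is_clonal, , drop = FALSE]
    clu_tbl$n_mutations <- pmax(clu_tbl$n_mutations, 1L)

    all_var <- c(all_var, list(variants))
    all_seg <- c(all_seg, list(segments))
    all_clu <- c(all_clu, list(clu_tbl))
    all_meta <- c(all_meta, list(tibble::tibble(
      sample_id = sid, group = grp,
      subtype = sample(config$subtypes, 1),
      purity = purity, ploidy = ploidy, mean_depth = config$depth_mean
    )))
    truth_samples <- c(truth_samples, list(tibble::tibble(
      sample_id = sid, group = grp, purity = purity, ploidy = ploidy,
      wgd = wgd, n_subclones = n_sub,
      wccf = compute_wccf(clu_tbl)
    )))
    if (!is.null(events) && nrow(events)) {
      truth_events <- c(truth_events, list(events))
    }
  }

  out <- list(
    variants = purrr::list_rbind(purrr::compact(all_var)),
    segments = purrr::list_rbind(all_seg),
    metadata = purrr::list_rbind(all_meta),
    clusters = purrr::list_rbind(all_clu),
    truth = list(
      samples = purrr::list_rbind(truth_samples),
      events = purrr::list_rbind(truth_events),
      kataegis = purrr::list_rbind(truth_kat),
      catalog = catalog
    ),
    config = config,
    seed = seed
  )
  class(out) <- "somevo_cohort"
  out
}

#' @export
print.somevo_cohort <- function(x, ...) {
  cat("<somevo_cohort>", nrow(x$metadata), "samples,",
    nrow(x$variants), "variants,", nrow(x$segments), "segments (seed",
    paste0(x$seed, ")\n")
  )
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the TSV dialects the readers consume (`variants.tsv`,
#' `segments.tsv`, `metadata.tsv`, `clusters.tsv`) plus `truth_*.tsv`
#' tables.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "somevo_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variants_tsv(
    dplyr::select(cohort$variants, dplyr::all_of(variant_cols)),
    file.path(dir, "variants.tsv")
  )
  write_segments_tsv(cohort$segments, file.path(dir, "segments.tsv"))
  write_metadata_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_clusters_tsv(cohort$clusters, file.path(dir, "clusters.tsv"))
  readr::write_tsv(cohort$truth$samples, file.path(dir, "truth_samples.tsv"),
    progress = FALSE
  )
  if (!is.null(cohort$truth$events) && nrow(cohort$truth$events)) {
    readr::write_tsv(cohort$truth$events, file.path(dir, "truth_events.tsv"),
      progress = FALSE
    )
  }
  if (!is.null(cohort$truth$kataegis) && nrow(cohort$truth$kataegis)) {
    readr::write_tsv(cohort$truth$kataegis, file.path(dir, "truth_kataegis.tsv"),
      progress = FALSE
    )
  }
  invisible(dir)
}

#' Named cohort fixtures
#'
#' Small preset cohorts used by the test-suite and documentation:
#' `"tiny"` (6 samples, toy genome, default catalog), `"recovery"` (60
#' samples, 8 events with latent times spread over 0-1 and observation
#' probabilities 0.3-0.9, built for timing-order recovery) and `"null"`
#' (20 samples, no catalog events, no kataegis — uniform background only).
#'
#' @param name Preset id.
#' @param seed Integer seed.
#' @return A [simulate_cohort()] result.
#' @export
make_fixture <- function(name = c("tiny", "recovery", "null"), seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(),
    recovery = sim_config(
      groups = c(A = 60),
      wgd_probability = 0.3,
      mutation_rate = 2,
      # the full-range linear link: with the default 0.6 slope the
      # clonal-fraction separation between adjacent latent times is below
      # binomial noise at these prevalences, and no estimator can recover
      # the order; this preset exists to exercise order recovery
      clonal_prob_slope = 1.0,
      kataegis = list(n_foci_range = c(0, 0), n_snvs_range = c(6, 6), spacing_mean = 300),
      event_catalog = tibble::tibble(
        event_id = paste0("E", 1:8),
        type = c("LOH", "driver", "Gain", "driver", "HD", "driver", "Gain", "driver"),
        chrom = c("1", "1", "2", "2", "3", "3", "1", "2"),
        start = c(1e6, 4e6, 1e6, 3.5e6, 1e6, 4e6, 6e6, 6e6),
        end = c(2e6, 4e6, 2e6, 3.5e6, 2e6, 4e6, 7e6, 6e6),
        gene = c(NA, "G2", NA, "G4", NA, "G6", NA, "G8"),
        true_rel_time = (seq_len(8) - 0.5) / 8,
        prevalence = c(0.9, 0.7, 0.8, 0.5, 0.6, 0.4, 0.7, 0.3)
      )
    ),
    null = sim_config(
      groups = c(A = 10, B = 10),
      wgd_probability = 0,
      event_catalog = default_event_catalog()[0, ],
      kataegis = list(n_foci_range = c(0, 0), n_snvs_range = c(6, 6), spacing_mean = 300),
      mutation_rate = 5
    )
  )
  simulate_cohort(cfg, seed = seed)
}
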