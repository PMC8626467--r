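# One-command pipeline: chains all analysis stages over a cohort (from
# disk or freshly simulated), writes every stage table as TSV plus a run
# manifest (package version, seeds, parameters, input checksums). All
# randomness flows from one master seed, split per stage, so a single
# number reproduces a run.

#' Assemble a timed-event table from pipeline results
#'
#' Builds the per-sample event table the timing model consumes: coding
#' driver mutations become `<gene>_mut` events with clonality, CCF and
#' pre/post-WGD class from the CCF calls; copy-number events overlapping
#' significantly recurrent regions become `<chrom>_<type>` events, with the
#' aberrant-state cell fraction as the CCF of subclonal CNAs. Subclonal
#' events are grouped into clusters by rounded CCF.
#'
#' @param ccf_tbl Output of [ccf_calls()].
#' @param cna_events Output of [derive_events()].
#' @param regions Output of [cna_recurrence()]/[filter_regions()]; only
#'   significant, non-excluded regions anchor CNA events.
#' @param segments Segment tibble (cell fractions of subclonal CNAs).
#' @return Event tibble for [estimate_timing()].
#' @export
build_event_table <- function(ccf_tbl, cna_events, regions, segments) {
  drv <- ccf_tbl |>
    dplyr::filter(.data$is_coding, !is.na(.data$gene)) |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      event_id = paste0(.data$gene, "_mut"),
      clonality = .data$status,
      ccf = .data$ccf,
      wgd_class = .data$timing_class,
      cluster = ifelse(.data$status == "subclonal",
        sprintf("ccf%.2f", round(.data$ccf, 2)), NA_character_
      )
    ) |>
    dplyr::distinct(.data$sample_id, .data$event_id, .keep_all = TRUE)
  cna <- NULL
  sig <- regions[regions$significant & regions$excluded_reason == "none", , drop = FALSE]
  if (nrow(sig) && nrow(cna_events)) {
    hits <- purrr::map_dfr(seq_len(nrow(sig)), function(k) {
      ov <- cna_events$type == sig$type[k] &
        cna_events$chrom == sig$chrom[k] &
        cna_events$start <= sig$end[k] & cna_events$end >= sig$start[k]
      if (!any(ov)) return(NULL)
      ev <- cna_events[ov, , drop = FALSE]
      ev$event_id <- paste0(sig$chrom[k], "_", sig$type[k])
      ev
    })
    if (nrow(hits)) {
      # cell fraction of the aberrant state for subclonal CNAs
      frac <- purrr::map_dbl(seq_len(nrow(hits)), function(k) {
        seg <- segments[segments$sample_id == hits$sample_id[k] &
          segments$chrom == hits$chrom[k] &
          segments$start <= hits$end[k] & segments$end >= hits$start[k], ]
        if (!nrow(seg)) return(1)
        min(seg$frac_1[1], 1)
      })
      cna <- hits |>
        dplyr::mutate(
          ccf = ifelse(.data$clonality == "clonal", 1, frac),
          wgd_class = "not_applicable",
          cluster = ifelse(.data$clonality == "subclonal",
            sprintf("ccf%.2f", round(.data$ccf, 2)), NA_character_
          )
        ) |>
        dplyr::distinct(.data$sample_id, .data$event_id, .keep_all = TRUE) |>
        dplyr::select(
          "sample_id", "event_id", "clonality", "ccf", "wgd_class", "cluster"
        )
    }
  }
  dplyr::bind_rows(drv, cna)
}

#' Run the full somatic-evolution pipeline
#'
#' Stages, in dependency order: CCF/clonality, purity QC, instability and
#' kataegis, CNA recurrence, hotspot scan (when two group labels exist),
#' ITH (wCCF), event-table assembly and timing, and the somatic-interaction
#' scan. Each stage's table is written to `out_dir`; a `manifest.yaml`
#' records versions, seeds, parameters and input checksums. Any stage
#' failure halts with an error naming the stage; tables already written
#' are preserved.
#'
#' @param config Path to a YAML file or a named list. Recognized fields:
#'   `out_dir` (required); either `simulate` (list: `preset`, `seed`) or
#'   `inputs` (list of paths: `variants`, `segments`, `metadata`, optional
#'   `clusters`); `params` (optional list: `seed`, `n_perm`, `n_iter`,
#'   `gamma`, `fdr_cna`, `fdr_hotspot`, `min_nrpcc`, `telomere_buffer`,
#'   `genome` one of `"toy"`/`"grch37"`, `group_a`, `group_b`); `stages`
#'   (optional character vector to restrict which stages run).
#' @return Invisibly, a list of all stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params %||% list()
  seed <- p$seed %||% 1L
  genome <- genome_model(p$genome %||% "toy")
  stages <- config$stages %||% c(
    "ccf", "purity", "instability", "recurrence", "hotspots", "ith",
    "timing", "interactions"
  )
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  # inputs
  input_files <- character(0)
  if (!is.null(config$simulate)) {
    cohort <- stage("simulate", make_fixture(
      config$simulate$preset %||% "tiny",
      seed = config$simulate$seed %||% seed
    ))
    variants <- cohort$variants[, variant_cols]
    segments <- cohort$segments
    metadata <- cohort$metadata
    clusters <- cohort$clusters
  } else {
    inp <- config$inputs
    if (is.null(inp$variants) || is.null(inp$segments) || is.null(inp$metadata)) {
      stop("config$inputs must name variants, segments and metadata paths",
        call. = FALSE
      )
    }
    input_files <- unlist(inp)
    variants <- stage("read_variants", read_variants(inp$variants))
    segments <- stage("read_segments", read_segments(inp$segments))
    metadata <- stage("read_metadata", read_sample_metadata(inp$metadata))
    clusters <- if (!is.null(inp$clusters)) {
      stage("read_clusters", read_clusters(inp$clusters))
    } else {
      NULL
    }
  }

  res <- list()
  emit <- function(tbl, file) {
    write_results(tbl, file.path(out_dir, file))
  }

  if ("ccf" %in% stages) {
    res$ccf <- stage("ccf", ccf_calls(variants, segments, metadata))
    emit(res$ccf, "ccf_calls.tsv")
  }
  if ("purity" %in% stages) {
    res$purity <- stage("purity", purity_qc(variants, segments, metadata,
      min_nrpcc = p$min_nrpcc %||% 10
    ))
    emit(res$purity, "purity_qc.tsv")
  }
  if ("instability" %in% stages) {
    res$instability <- stage(
      "instability",
      instability_metrics(variants, segments, metadata, gamma = p$gamma %||% 8)
    )
    emit(res$instability, "instability.tsv")
    res$kataegis <- stage("instability", detect_kataegis(variants, gamma = p$gamma %||% 8))
    emit(res$kataegis, "kataegis_foci.tsv")
  }
  if ("recurrence" %in% stages) {
    res$cna_events <- stage("recurrence", derive_events(segments, metadata))
    res$regions <- stage("recurrence", {
      r <- permutation_test(res$cna_events, genome,
        n_samples = dplyr::n_distinct(metadata$sample_id),
        n_perm = p$n_perm %||% 1000, seed = seed + 1L,
        fdr = p$fdr_cna %||% 0.05
      )
      filter_regions(r, genome, telomere_buffer = p$telomere_buffer %||% 1e6)
    })
    emit(res$regions, "cna_recurrence.tsv")
  }
  groups <- unique(metadata$group)
  if ("hotspots" %in% stages && length(groups) >= 2) {
    ga <- p$group_a %||% groups[1]
    gb <- p$group_b %||% groups[2]
    res$hotspots <- stage("hotspots", hotspot_scan(
      variants, metadata, genome, ga, gb,
      fdr = p$fdr_hotspot %||% 0.1
    ))
    emit(res$hotspots, "hotspots.tsv")
  }
  if ("ith" %in% stages) {
    res$ith <- stage("ith", {
      if (!is.null(clusters)) {
        ith_analysis(metadata = metadata, clusters = clusters,
          min_nrpcc = p$min_nrpcc %||% 10
        )
      } else {
        ith_analysis(res$ccf, metadata, min_nrpcc = p$min_nrpcc %||% 10)
      }
    })
    emit(res$ith, "ith_wccf.tsv")
  }
  if ("timing" %in% stages && !is.null(res$ccf) && !is.null(res$regions)) {
    res$event_table <- stage("timing", build_event_table(
      res$ccf, res$cna_events, res$regions, segments
    ))
    if (nrow(res$event_table)) {
      wgd_samples <- metadata$sample_id[call_wgd_for_timing(metadata$ploidy)]
      res$timing <- stage("timing", estimate_timing(
        res$event_table,
        wgd_samples = intersect(wgd_samples, res$event_table$sample_id),
        n_iter = p$n_iter %||% 1000, seed = seed + 2L
      ))
      emit(res$timing$summary, "timing.tsv")
      emit(res$event_table, "event_table.tsv")
    }
  }
  if ("interactions" %in% stages && !is.null(res$event_table) &&
    nrow(res$event_table)) {
    incidence <- res$event_table |>
      dplyr::distinct(.data$sample_id, .data$event_id) |>
      dplyr::mutate(present = 1L) |>
      tidyr::pivot_wider(
        names_from = "event_id", values_from = "present", values_fill = 0L
      )
    full <- tidyr::complete(
      incidence,
      sample_id = metadata$sample_id
    )
    full[is.na(full)] <- 0L
    if (ncol(full) >= 3) {
      res$interactions <- stage(
        "interactions",
        somatic_interactions(full, fdr = p$fdr_cna %||% 0.05)
      )
      emit(res$interactions, "interactions.tsv")
    }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("somevo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    params = p,
    stages = stages,
    inputs = if (length(input_files)) {
      as.list(tools::md5sum(input_files))
    } else {
      list(simulated = config$simulate %||% "none")
    },
    outputs = list.files(out_dir, pattern = "\\.tsv$")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
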