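#' Run the full MeDIP-chip DMR pipeline
#'
#' Executes the stages in order: biweight scaling, windowed KS P scores, raw
#' peak calling per replicate, replicate consensus per sample, cross-sample
#' partition into presence-pattern regions, T-DMR classification across
#' tissues at the adult stage, DS-DMR classification across stages within
#' each tissue, location-category annotation, summary tabulation (with
#' concordance-adjusted counts), cross-tissue DS-DMR overlap and CpGi/shore
#' density. Every sample must have at least two replicates (consensus is
#' defined as the region shared between two biological replicates). With no
#' non-adult stages the DS-DMR stages are skipped with a warning.
#'
#' @param signal Unscaled long signal tibble (`tissue`, `stage`, `replicate`,
#'   `probe_id`, `log2_ratio`).
#' @param layout Probe layout ([as_probe_layout()]).
#' @param genes,cpgis Annotation tibbles.
#' @param config A [medip_config()].
#' @param tiling_regions Optional tiling-region intervals for the two
#'   tiling-only location categories.
#' @param strict_tiling Passed to [assign_location()].
#' @param tdmr_stage Stage whose samples define the tissue comparison
#'   (default `"AD"`).
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written as TSV/BED plus a `manifest.json` recording configuration hash
#'   and per-stage record counts.
#' @return An object of class `medip_result`; see [glance.medip_result()].
#' @export
run_medip_pipeline <- function(signal, layout, genes, cpgis,
                               config = medip_config(),
                               tiling_regions = NULL, strict_tiling = FALSE,
                               tdmr_stage = "AD", out_dir = NULL) {
  need <- c("tissue", "stage", "replicate", "probe_id", "log2_ratio")
  if (!all(need %in% names(signal))) {
    abort(sprintf("signal needs columns %s", paste(need, collapse = ", ")))
  }
  design <- distinct(signal, .data$tissue, .data$stage, .data$replicate) |>
    dplyr::count(.data$tissue, .data$stage)
  if (any(design$n < 2)) {
    bad <- design[design$n < 2, ]
    abort(sprintf("sample %s:%s has %d replicate(s); two are required",
                  bad$tissue[1], bad$stage[1], bad$n[1]))
  }

  scaled <- scale_tracks(signal, c = config$biweight_c)
  pscores <- pscore_tracks(scaled, layout, config)

  rep_groups <- pscores |>
    group_by(.data$tissue, .data$stage, .data$replicate) |>
    group_split()
  raw_peaks <- bind_rows(map(rep_groups, call_peaks, layout = layout, config = config))

  sample_groups <- split(raw_peaks, paste(raw_peaks$tissue, raw_peaks$stage, sep = ":"))
  consensus <- bind_rows(map(sample_groups, function(g) {
    reps <- sort(unique(g$replicate))
    consensus_peaks(filter(g, .data$replicate == reps[1]),
                    filter(g, .data$replicate == reps[2]),
                    layout, config)
  }))
  if (nrow(consensus) == 0) {
    consensus <- tibble(chrom = character(), start = numeric(), end = numeric(),
                        n_probes = integer(), tissue = character(), stage = character())
  }

  concordance <- distinct(signal, .data$tissue, .data$stage) |>
    mutate(conc = pmap(list(.data$tissue, .data$stage), function(tt, ss) {
      reps <- sort(unique(signal$replicate[signal$tissue == tt & signal$stage == ss]))
      a_sig <- filter(scaled, .data$tissue == tt, .data$stage == ss, .data$replicate == reps[1])
      b_sig <- filter(scaled, .data$tissue == tt, .data$stage == ss, .data$replicate == reps[2])
      a_ps <- filter(pscores, .data$tissue == tt, .data$stage == ss, .data$replicate == reps[1])
      b_ps <- filter(pscores, .data$tissue == tt, .data$stage == ss, .data$replicate == reps[2])
      tibble(r_log2 = replicate_concordance(a_sig, b_sig, "log2_ratio")$r,
             r_pscore = replicate_concordance(a_ps, b_ps, "pscore")$r)
    })) |>
    tidyr::unnest("conc")

  annotate <- function(records) {
    assign_location(records, genes, cpgis, config,
                    tiling_regions = tiling_regions, strict_tiling = strict_tiling)
  }

  ## ---- T-DMRs: tissues compared at the adult stage ----
  tdmr <- NULL
  tissues <- sort(unique(signal$tissue))
  if (tdmr_stage %in% unique(signal$stage) && length(tissues) >= 2) {
    cons_t <- consensus |> filter(.data$stage == tdmr_stage) |>
      mutate(sample = .data$tissue)
    raw_t <- raw_peaks |> filter(.data$stage == tdmr_stage) |>
      mutate(sample = .data$tissue)
    rec <- partition_regions(cons_t, raw_t, layout, config, samples = tissues) |>
      classify_tdmr(tissues = tissues) |>
      annotate()
    tdmr <- list(records = rec,
                 table = tabulate_dmrs(rec, mode = "tdmr", universe = tissues))
  } else {
    warn("T-DMR stage skipped: need >= 2 tissues at the adult stage")
  }

  ## ---- DS-DMRs: stages compared within each tissue ----
  dsdmr <- NULL
  stages <- intersect(ALL_STAGES, unique(signal$stage))
  if (length(stages) >= 2) {
    ds_records <- bind_rows(map(tissues, function(tt) {
      cons_s <- consensus |> filter(.data$tissue == tt) |> mutate(sample = .data$stage)
      raw_s <- raw_peaks |> filter(.data$tissue == tt) |> mutate(sample = .data$stage)
      partition_regions(cons_s, raw_s, layout, config, samples = stages) |>
        classify_dsdmr(stages = stages) |>
        annotate() |>
        mutate(tissue = tt)
    }))
    tables <- lapply(setNames(tissues, tissues), function(tt) {
      tab <- tabulate_dmrs(filter(ds_records, .data$tissue == tt),
                           mode = "dsdmr", universe = stages)
      conc_t <- concordance |> filter(.data$tissue == tt) |>
        select(stage = "stage", r = "r_pscore")
      if (all(conc_t$r > 0)) tab <- adjust_counts(tab, conc_t)
      tab
    })
    grand <- tabulate_dmrs(ds_records, mode = "dsdmr", universe = stages)
    ds_sets <- ds_records |>
      filter(.data$dmr_class != "common", !.data$is_flagged) |>
      select(all_of(c("tissue", "chrom", "start", "end")))
    overlap <- if (length(unique(ds_sets$tissue)) >= 2 && nrow(ds_sets) > 0) {
      cross_tissue_overlap(ds_sets)
    } else NULL
    shores <- shore_density(filter(ds_records, .data$dmr_class != "common"),
                            cpgis, config)
    dsdmr <- list(records = ds_records, tables = tables, grand_table = grand,
                  overlap = overlap, shore_density = shores)
  } else {
    warn("DS-DMR stage skipped: fewer than two developmental stages")
  }

  res <- structure(list(
    pscores = pscores, raw_peaks = raw_peaks, consensus = consensus,
    concordance = concordance, tdmr = tdmr, dsdmr = dsdmr,
    config = config, layout_n = nrow(layout)
  ), class = "medip_result")

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

list_cols_to_chr <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) df[[nm]] <- map_chr(df[[nm]], paste, collapse = "+")
  }
  df
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(list_cols_to_chr(as_tibble(df)), file.path(out_dir, name))
  }
  w(res$raw_peaks, "raw_peaks.tsv")
  w(res$consensus, "consensus_peaks.tsv")
  w(res$concordance, "concordance.tsv")
  counts <- list(n_raw_peaks = nrow(res$raw_peaks),
                 n_consensus = nrow(res$consensus))
  if (!is.null(res$tdmr)) {
    w(res$tdmr$records, "tdmr_records.tsv")
    w(res$tdmr$table, "tdmr_table.tsv")
    bed <- res$tdmr$records |>
      mutate(name = .data$pattern, score = 0)
    write_bed(bed[c("chrom", "start", "end", "name", "score")],
              file.path(out_dir, "tdmr.bed"))
    counts$n_tdmr_records <- nrow(res$tdmr$records)
  }
  if (!is.null(res$dsdmr)) {
    w(res$dsdmr$records, "dsdmr_records.tsv")
    w(res$dsdmr$grand_table, "dsdmr_grand_table.tsv")
    for (tt in names(res$dsdmr$tables)) {
      w(res$dsdmr$tables[[tt]], sprintf("dsdmr_table_%s.tsv", tt))
    }
    if (!is.null(res$dsdmr$overlap)) {
      w(tidy(res$dsdmr$overlap), "dsdmr_overlap_per_tissue.tsv")
      w(glance(res$dsdmr$overlap), "dsdmr_overlap_totals.tsv")
    }
    w(res$dsdmr$shore_density, "dsdmr_shore_density.tsv")
    counts$n_dsdmr_records <- nrow(res$dsdmr$records)
  }
  manifest <- list(
    tool = "medipdmr",
    version = as.character(utils::packageVersion("medipdmr")),
    config = unclass(res$config),
    config_hash = rlang::hash(unclass(res$config)),
    n_probes = res$layout_n,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.medip_result <- function(x, ...) {
  cat("<medip_result>\n")
  print(glance(x))
  invisible(x)
}

#' Pipeline result summary
#'
#' @param x A `medip_result`.
#' @param ... Unused.
#' @return One-row tibble of stage-level counts and headline totals.
#' @export
#' @method glance medip_result
glance.medip_result <- function(x, ...) {
  tibble(
    n_probes = x$layout_n,
    n_raw_peaks = nrow(x$raw_peaks),
    n_consensus = nrow(x$consensus),
    n_tdmr = if (!is.null(x$tdmr)) {
      sum(x$tdmr$records$dmr_class != "common" & !x$tdmr$records$is_flagged)
    } else NA_integer_,
    n_dsdmr = if (!is.null(x$dsdmr)) {
      sum(x$dsdmr$records$dmr_class != "common" & !x$dsdmr$records$is_flagged)
    } else NA_integer_,
    mean_r_log2 = mean(x$concordance$r_log2),
    mean_r_pscore = mean(x$concordance$r_pscore)
  )
}

#' Tidy pipeline components
#'
#' @param x A `medip_result`.
#' @param what One of `"tdmr"`, `"dsdmr"`, `"consensus"`, `"raw_peaks"`,
#'   `"concordance"`.
#' @param ... Unused.
#' @return The requested component as a tibble (list-columns flattened to
#'   `+`-joined strings).
#' @export
#' @method tidy medip_result
tidy.medip_result <- function(x, what = c("tdmr", "dsdmr", "consensus",
                                          "raw_peaks", "concordance"), ...) {
  what <- match.arg(what)
  out <- switch(what,
    tdmr = if (is.null(x$tdmr)) NULL else x$tdmr$records,
    dsdmr = if (is.null(x$dsdmr)) NULL else x$dsdmr$records,
    consensus = x$consensus,
    raw_peaks = x$raw_peaks,
    concordance = x$concordance)
  if (is.null(out)) abort(sprintf("component '%s' was not computed", what))
  list_cols_to_chr(as_tibble(out))
}

#' @importFrom dplyr count
#' @importFrom purrr pmap
NULL
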