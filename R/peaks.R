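## Probe count inside an interval = probes whose centre lies in [start, end).
## Used uniformly for raw peaks, consensus intersections and partition atoms.
count_probes_in <- function(x, layout) {
  if (nrow(x) == 0) return(integer(0))
  vapply(seq_len(nrow(x)), function(i) {
    sum(layout$chrom == x$chrom[i] &
          layout$center >= x$start[i] & layout$center < x$end[i])
  }, integer(1))
}

#' Call raw methylation peaks from a P-score track
#'
#' Searches for maximal runs of at least `min_consecutive_probes` consecutive
#' probes (array order within a chromosome) with P score at or above
#' `pscore_threshold`. A run becomes a peak spanning the first qualifying
#' probe's start to the last qualifying probe's end; peaks within `merge_bp`
#' of each other are then merged (see [merge_peaks()]). Runs can optionally be
#' broken across uncovered gaps larger than `max_probe_gap_bp`.
#'
#' @param pscores P-score tibble from [windowed_ks_pscore()] (one replicate).
#' @param layout Probe layout covering the track.
#' @param config A [medip_config()].
#' @return Peak tibble `chrom`, `start`, `end`, `n_probes`, `max_pscore`,
#'   `mean_pscore`, sorted, plus any sample label columns of `pscores`.
#' @export
call_peaks <- function(pscores, layout, config = medip_config()) {
  keys <- intersect(c("tissue", "stage", "replicate"), names(pscores))
  dat <- layout |>
    left_join(select(pscores, all_of(c("probe_id", "pscore"))), by = "probe_id")
  if (anyNA(dat$pscore)) abort("call_peaks: pscores do not cover the layout")

  peaks <- list()
  for (chr in unique(dat$chrom)) {
    d <- dat[dat$chrom == chr, ]
    qual <- d$pscore >= config$pscore_threshold
    if (is.finite(config$max_probe_gap_bp) && nrow(d) > 1) {
      gap_break <- c(FALSE, diff(d$center) > config$max_probe_gap_bp)
    } else {
      gap_break <- rep(FALSE, nrow(d))
    }
    run_id <- cumsum(!qual | gap_break)
    for (r in unique(run_id[qual])) {
      sel <- which(qual & run_id == r)
      if (length(sel) < config$min_consecutive_probes) next
      peaks[[length(peaks) + 1]] <- tibble(
        chrom = chr,
        start = d$start[sel[1]],
        end = d$end[sel[length(sel)]],
        n_probes = length(sel),
        max_pscore = max(d$pscore[sel]),
        mean_pscore = mean(d$pscore[sel])
      )
    }
  }
  out <- if (length(peaks)) bind_rows(peaks) else {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           n_probes = integer(), max_pscore = numeric(), mean_pscore = numeric())
  }
  out <- merge_peaks(arrange(out, .data$chrom, .data$start), config$merge_bp)
  for (k in keys) out[[k]] <- if (nrow(out)) pscores[[k]][1] else pscores[[k]][0]
  out
}

#' Merge nearby peaks
#'
#' Iteratively merges peaks whose edge-to-edge distance is at most `merge_bp`
#' (inclusive: a 500-bp gap merges at the default) until no pair remains
#' within range. The merged interval is the convex hull; `n_probes` is summed,
#' `max_pscore` is the maximum and `mean_pscore` the probe-weighted mean.
#'
#' @param peaks Peak tibble sorted by (`chrom`, `start`).
#' @param merge_bp Merge distance in bp.
#' @return Peak tibble with pairwise gaps `> merge_bp`.
#' @export
merge_peaks <- function(peaks, merge_bp = 500) {
  if (nrow(peaks) <= 1) return(peaks)
  peaks <- arrange(peaks, .data$chrom, .data$start)
  grp <- integer(nrow(peaks))
  grp[1] <- 1L
  cur_end <- peaks$end[1]
  for (i in 2:nrow(peaks)) {
    same <- peaks$chrom[i] == peaks$chrom[i - 1] &&
      (peaks$start[i] - cur_end) <= merge_bp
    grp[i] <- if (same) grp[i - 1] else grp[i - 1] + 1L
    cur_end <- if (same) max(cur_end, peaks$end[i]) else peaks$end[i]
  }
  has_stats <- all(c("n_probes", "max_pscore", "mean_pscore") %in% names(peaks))
  out <- peaks |>
    mutate(.grp = grp) |>
    group_by(.data$.grp)
  if (has_stats) {
    out <- out |>
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), n_probes = sum(.data$n_probes),
                max_pscore = max(.data$max_pscore),
                mean_pscore = sum(.data$mean_pscore * .data$n_probes) /
                  sum(.data$n_probes), .groups = "drop")
  } else {
    out <- out |>
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), .groups = "drop")
  }
  out |> select(-any_of(".grp")) |> arrange(.data$chrom, .data$start)
}

#' Replicate-consensus methylation peaks
#'
#' A methylation peak of a sample is the region shared between its two
#' biological replicates: overlapping raw peaks are intersected pairwise,
#' intersections with fewer than `min_subpeak_probes` probes are dropped, and
#' the surviving intersections are unioned into disjoint consensus peaks.
#'
#' @param rep1,rep2 Raw-peak tibbles of the two replicates of one sample.
#' @param layout Probe layout (for the probe-count floor).
#' @param config A [medip_config()].
#' @return Consensus tibble `chrom`, `start`, `end`, `n_probes`, sorted;
#'   `tissue`/`stage` columns are carried over from `rep1` when present.
#' @export
consensus_peaks <- function(rep1, rep2, layout, config = medip_config()) {
  keys <- intersect(c("tissue", "stage"), names(rep1))
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_probes = integer())
  if (nrow(rep1) == 0 || nrow(rep2) == 0) {
    out <- empty
  } else {
    g1 <- as_granges(rep1); g2 <- as_granges(rep2)
    hits <- GenomicRanges::findOverlaps(g1, g2)
    if (length(hits) == 0) {
      out <- empty
    } else {
      pi <- IRanges::pintersect(g1[S4Vectors::queryHits(hits)],
                                g2[S4Vectors::subjectHits(hits)])
      inter <- granges_tbl(pi)
      inter <- inter[count_probes_in(inter, layout) >= config$min_subpeak_probes, ]
      out <- iv_union(inter)
      out$n_probes <- count_probes_in(out, layout)
      out <- out[out$n_probes >= config$min_subpeak_probes, ]
    }
  }
  for (k in keys) out[[k]] <- if (nrow(out)) rep1[[k]][1] else rep1[[k]][0]
  out
}

#' @importFrom dplyr any_of
NULL
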