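#' Windowed one-sided KS P scores
#'
#' For each probe, a fixed-length window (default 750 bp total span) is placed
#' around the probe's centre; window members are the probes of the same
#' chromosome whose centres lie within `window_bp / 2` of the focal centre.
#' A one-sided Kolmogorov-Smirnov statistic
#' `D+ = max_x (ECDF_background(x) - ECDF_window(x))` (clamped at 0) tests
#' whether the window's scaled log2 ratios are drawn from a significantly more
#' positive distribution than the background — by default the rest of the
#' array, i.e. every probe not in the window, across all chromosomes. The
#' asymptotic one-sided p-value `exp(-2 D+^2 m n / (m + n))` is clipped to
#' `[ks_pvalue_floor, 1]` and reported as the P score `-log10 p`. Windows with
#' fewer than `min_window_probes` probes score 0.
#'
#' ECDFs are right-continuous step functions and `D+` is the maximum over all
#' pooled data points, so ties are handled deterministically.
#'
#' @param track Scaled signal tibble for one replicate (`probe_id`,
#'   `log2_ratio`), as returned by [scale_tracks()]. Unscaled input errors.
#' @param layout Probe layout tibble (see [as_probe_layout()]).
#' @param config A [medip_config()].
#' @return Tibble `probe_id`, `chrom`, `start`, `end`, `pscore`, in layout
#'   order, plus the sample label columns of `track` if present.
#' @export
windowed_ks_pscore <- function(track, layout, config = medip_config()) {
  if (!isTRUE(attr(track, "medip_scaled"))) {
    abort("windowed_ks_pscore: track must be scaled (see scale_tracks())")
  }
  keys <- intersect(c("tissue", "stage", "replicate"), names(track))
  if (length(keys) && nrow(distinct(track[keys])) > 1) {
    abort("windowed_ks_pscore: one replicate track at a time")
  }
  dat <- left_join(layout, select(track, all_of(c("probe_id", "log2_ratio"))),
                   by = "probe_id")
  if (anyNA(dat$log2_ratio)) abort("track does not cover the probe layout")

  vals <- dat$log2_ratio
  n_tot <- length(vals)
  sv <- sort(vals)
  half <- config$window_bp / 2

  pscore <- numeric(n_tot)
  for (chr in unique(dat$chrom)) {
    idx <- which(dat$chrom == chr)
    centers <- dat$center[idx]
    # windows via two pointers on sorted centers (layout is sorted)
    lo <- findInterval(centers - half, centers, left.open = TRUE) + 1L
    hi <- findInterval(centers + half, centers)
    for (k in seq_along(idx)) {
      win_idx <- idx[lo[k]:hi[k]]
      m <- length(win_idx)
      if (m < config$min_window_probes) next
      w <- sort(vals[win_idx])
      all_le <- findInterval(w, sv)
      all_lt <- findInterval(w, sv, left.open = TRUE)
      win_le <- findInterval(w, w)
      win_lt <- findInterval(w, w, left.open = TRUE)
      if (config$ks_background == "exclude") {
        n <- n_tot - m
        if (n <= 0) next
        dplus <- max(0, (all_le - win_le) / n - win_le / m,
                     (all_lt - win_lt) / n - win_lt / m)
      } else {
        n <- n_tot
        dplus <- max(0, all_le / n - win_le / m, all_lt / n - win_lt / m)
      }
      p <- exp(-2 * dplus^2 * m * n / (m + n))
      p <- min(max(p, config$ks_pvalue_floor), 1)
      pscore[idx[k]] <- -log10(p)
    }
  }
  out <- dat |>
    select(all_of(c("probe_id", "chrom", "start", "end"))) |>
    mutate(pscore = pscore)
  for (k in keys) out[[k]] <- track[[k]][1]
  out
}

#' Score many replicate tracks
#'
#' Applies [windowed_ks_pscore()] to each (tissue, stage, replicate) group of a
#' long signal tibble.
#'
#' @param signal Scaled signal tibble covering one or more replicates.
#' @param layout Probe layout.
#' @param config A [medip_config()].
#' @return Long P-score tibble with sample label columns.
#' @export
pscore_tracks <- function(signal, layout, config = medip_config()) {
  if (!isTRUE(attr(signal, "medip_scaled"))) {
    abort("pscore_tracks: signal must be scaled (see scale_tracks())")
  }
  keys <- intersect(c("tissue", "stage", "replicate"), names(signal))
  groups <- signal |> group_by(across(all_of(keys))) |> group_split()
  bind_rows(map(groups, function(g) {
    attr(g, "medip_scaled") <- TRUE
    windowed_ks_pscore(g, layout, config)
  }))
}
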