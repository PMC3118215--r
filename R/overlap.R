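#' Cross-tissue overlap of DS-DMRs
#'
#' Determines how many stage-specific DMRs are tissue-unique. A region is
#' tissue-unique when it overlaps no DS-DMR of any other tissue; overlapping
#' regions are clustered by transitive (single-linkage) overlap across
#' tissues. Two accountings are reported: the with-multiplicity total (every
#' tissue's region counted once, the starred totals of the dual accounting)
#' and the de-duplicated total (unique regions plus one per multi-tissue
#' cluster).
#'
#' @param dsdmr_sets Tibble with columns `tissue`, `chrom`, `start`, `end`:
#'   each tissue's DS-DMR intervals (regions within a tissue should be
#'   disjoint).
#' @return An object of class `medip_overlap`: list with
#'   `per_tissue` (tibble `tissue`, `n`, `unique`, `multi`, `tdmr_pct`) and
#'   scalars `total_with_multiplicity`, `total_dedup`, `unique_total`,
#'   `multi_occurrences`, `multi_clusters`, `common_all`, `unique_fraction`
#'   (unique / de-duplicated total) and `unique_pct` (the same as a
#'   one-decimal percentage). [tidy()] returns the per-tissue table,
#'   [glance()] the totals.
#' @export
cross_tissue_overlap <- function(dsdmr_sets) {
  need <- c("tissue", "chrom", "start", "end")
  if (!all(need %in% names(dsdmr_sets))) {
    abort("cross_tissue_overlap: needs columns tissue, chrom, start, end")
  }
  tissues <- unique(dsdmr_sets$tissue)
  if (length(tissues) < 2) abort("cross_tissue_overlap: need >= 2 tissues")
  x <- arrange(as_tibble(dsdmr_sets), .data$chrom, .data$start, .data$end)
  assert_intervals(x, "DS-DMR set")

  # single-linkage components by sweep: a new component starts where the next
  # interval does not overlap the running maximum end
  n <- nrow(x)
  comp <- integer(n)
  cur <- 0L
  max_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(n)) {
    if (x$chrom[i] != last_chrom || x$start[i] >= max_end) {
      cur <- cur + 1L
      max_end <- x$end[i]
      last_chrom <- x$chrom[i]
    } else {
      max_end <- max(max_end, x$end[i])
    }
    comp[i] <- cur
  }
  x$component <- comp

  comp_tissues <- tapply(x$tissue, comp, function(t) length(unique(t)))
  comp_all <- tapply(x$tissue, comp, function(t) length(unique(t)) == length(tissues))
  x$n_tissues_in_comp <- as.integer(comp_tissues[as.character(comp)])
  x$is_unique <- x$n_tissues_in_comp == 1L
  # a region is also tissue-specific (a T-DMR) unless its cluster spans all tissues
  x$is_tdmr <- !as.logical(comp_all[as.character(comp)])

  per_tissue <- x |>
    group_by(tissue = .data$tissue) |>
    summarise(n = n(),
              unique = sum(.data$is_unique),
              multi = sum(!.data$is_unique),
              tdmr_pct = round(100 * sum(.data$is_tdmr) / n(), 1),
              .groups = "drop") |>
    arrange(match(.data$tissue, tissues))

  multi_comp <- unique(comp[!x$is_unique])
  res <- list(
    per_tissue = per_tissue,
    regions = x,
    total_with_multiplicity = n,
    total_dedup = sum(x$is_unique) + length(multi_comp),
    unique_total = sum(x$is_unique),
    multi_occurrences = sum(!x$is_unique),
    multi_clusters = length(multi_comp),
    common_all = sum(comp_all),
    unique_fraction = sum(x$is_unique) / (sum(x$is_unique) + length(multi_comp))
  )
  res$unique_pct <- round(100 * res$unique_fraction, 1)
  structure(res, class = "medip_overlap")
}

#' @export
print.medip_overlap <- function(x, ...) {
  cat("<medip_overlap>\n")
  print(x$per_tissue)
  cat(sprintf("Total: %d*/%d** (* with multiplicity, ** de-duplicated)\n",
              x$total_with_multiplicity, x$total_dedup))
  cat(sprintf("Tissue-unique: %d (%.1f%%); multi-tissue: %d*/%d**\n",
              x$unique_total, x$unique_pct, x$multi_occurrences, x$multi_clusters))
  invisible(x)
}

#' @export
#' @method tidy medip_overlap
tidy.medip_overlap <- function(x, ...) x$per_tissue

#' @export
#' @method glance medip_overlap
glance.medip_overlap <- function(x, ...) {
  tibble(total_with_multiplicity = x$total_with_multiplicity,
         total_dedup = x$total_dedup,
         unique_total = x$unique_total,
         multi_occurrences = x$multi_occurrences,
         multi_clusters = x$multi_clusters,
         common_all = x$common_all,
         unique_pct = x$unique_pct)
}
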