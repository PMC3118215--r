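#' Build DMR records realizing exact pattern-by-category counts
#'
#' Emits disjoint dummy regions so that table arithmetic (pattern totals,
#' per-category percentages, group sums) can be exercised against known
#' counts. Each requested (pattern, location category) cell yields `count`
#' records on a synthetic chromosome, 1-kb regions separated by 1-kb gaps.
#'
#' @param count_spec Tibble with columns `pattern` (present samples joined by
#'   `+`, or `"common"` for the all-samples pattern), `location_category` and
#'   `count` (non-negative).
#' @param universe Sample universe the patterns live in.
#' @param chrom Chromosome name for the dummy regions.
#' @return DMR-record tibble compatible with [classify_tdmr()] /
#'   [classify_dsdmr()] and [tabulate_dmrs()].
#' @export
fixture_from_counts <- function(count_spec, universe, chrom = "chrF") {
  if (nrow(count_spec) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_probes = integer(), present = list(), absent = list(),
                  ambiguous = list(), pattern = character(),
                  is_flagged = logical(), location_category = character()))
  }
  if (any(count_spec$count < 0)) abort("fixture_from_counts: negative count")
  rows <- list()
  pos <- 0
  for (i in seq_len(nrow(count_spec))) {
    pat <- count_spec$pattern[i]
    members <- if (identical(pat, "common")) universe else
      strsplit(pat, "+", fixed = TRUE)[[1]]
    if (!all(members %in% universe)) {
      abort(sprintf("fixture_from_counts: pattern '%s' outside universe", pat))
    }
    pres <- universe[universe %in% members]
    abs_set <- setdiff(universe, members)
    cnt <- count_spec$count[i]
    if (cnt == 0) next
    for (k in seq_len(cnt)) {
      rows[[length(rows) + 1]] <- tibble(
        chrom = chrom, start = pos, end = pos + 1000,
        n_probes = 2L,
        present = list(pres),
        absent = list(abs_set),
        ambiguous = list(character(0)),
        pattern = paste(pres, collapse = "+"),
        is_flagged = FALSE,
        location_category = count_spec$location_category[i]
      )
      pos <- pos + 2000
    }
  }
  bind_rows(rows)
}

#' Build per-tissue interval sets realizing an overlap structure
#'
#' Constructs DS-DMR interval sets whose cross-tissue overlap report has
#' exactly the requested per-tissue unique counts and multi-tissue cluster
#' composition: each unique region is a 1-kb slot owned by one tissue, each
#' cluster is one slot shared (identical coordinates) by its member tissues.
#' Slots are separated by 1-kb gaps so transitive overlap never bridges them.
#'
#' @param unique_counts Named integer vector: tissue -> number of
#'   tissue-unique regions.
#' @param cluster_spec Tibble with columns `tissues` (member tissues joined by
#'   `+`) and `n` (number of such clusters).
#' @param chrom Chromosome name.
#' @return Tibble `tissue`, `chrom`, `start`, `end` for
#'   [cross_tissue_overlap()].
#' @export
fixture_overlap_sets <- function(unique_counts, cluster_spec, chrom = "chrF") {
  rows <- list()
  pos <- 0
  for (tt in names(unique_counts)) {
    n <- unique_counts[[tt]]
    if (n == 0) next
    starts <- pos + seq(0, by = 2000, length.out = n)
    rows[[length(rows) + 1]] <- tibble(tissue = tt, chrom = chrom,
                                       start = starts, end = starts + 1000)
    pos <- max(starts) + 2000
  }
  for (i in seq_len(nrow(cluster_spec))) {
    members <- strsplit(cluster_spec$tissues[i], "+", fixed = TRUE)[[1]]
    n <- cluster_spec$n[i]
    if (n == 0) next
    starts <- pos + seq(0, by = 2000, length.out = n)
    for (m in members) {
      rows[[length(rows) + 1]] <- tibble(tissue = m, chrom = chrom,
                                         start = starts, end = starts + 1000)
    }
    pos <- max(starts) + 2000
  }
  bind_rows(rows)
}
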