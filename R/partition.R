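#' Partition consensus peaks across samples into presence-pattern atoms
#'
#' The genome is cut at every consensus-peak boundary of every sample, so that
#' one part of a larger overlapping peak can be identified as a common region
#' and another part as a unique region (sub-peak splitting). For each atomic
#' interval each sample is:
#'
#' * **present** — covered by that sample's consensus peaks;
#' * **absent** — overlapping no raw peak of either replicate of that sample
#'   (the raw-peak veto: a region only counts as unmethylated in a sample when
#'   not even an individual replicate shows a peak there);
#' * **ambiguous** — some raw-peak overlap but no consensus coverage.
#'
#' Adjacent atoms with identical status vectors are merged back, atoms with
#' fewer than `min_subpeak_probes` probes are dropped, and atoms present in no
#' sample are never emitted. Records with a non-empty ambiguous set are
#' flagged; downstream tabulation excludes them from headline counts.
#'
#' @param consensus Tibble of consensus peaks with columns `sample`, `chrom`,
#'   `start`, `end` (all samples together).
#' @param raw Tibble of raw replicate peaks with columns `sample`,
#'   `replicate`, `chrom`, `start`, `end`.
#' @param layout Probe layout.
#' @param config A [medip_config()].
#' @param samples Sample universe (character); defaults to the samples seen in
#'   `raw`. Consensus samples outside the universe error.
#' @return DMR-record tibble: `chrom`, `start`, `end`, `n_probes`, list-columns
#'   `present`, `absent`, `ambiguous`, the `pattern` string (present samples
#'   joined by `+` in universe order) and `is_flagged`.
#' @export
partition_regions <- function(consensus, raw, layout, config = medip_config(),
                              samples = NULL) {
  samples <- samples %||% unique(raw$sample)
  if (!all(consensus$sample %in% samples)) {
    abort("partition_regions: consensus contains samples outside the universe")
  }
  if (!all(raw$sample %in% samples)) {
    abort("partition_regions: raw peaks contain samples outside the universe")
  }
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_probes = integer(), present = list(), absent = list(),
                  ambiguous = list(), pattern = character(), is_flagged = logical())
  if (nrow(consensus) == 0) return(empty)

  cons_by <- split(consensus, consensus$sample)
  raw_by <- split(raw, raw$sample)

  atoms <- list()
  for (chr in sort(unique(consensus$chrom))) {
    cc <- consensus[consensus$chrom == chr, ]
    bounds <- sort(unique(c(cc$start, cc$end)))
    cand <- tibble(chrom = chr, start = head(bounds, -1), end = tail(bounds, -1))
    cand <- cand[iv_overlaps_any(cand, cc), ]
    if (nrow(cand)) atoms[[chr]] <- cand
  }
  atoms <- bind_rows(atoms)
  if (nrow(atoms) == 0) return(empty)

  # status per sample: 2 = present, 0 = absent, 1 = ambiguous
  status <- matrix(0L, nrow(atoms), length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    cs <- cons_by[[s]]
    rs <- raw_by[[s]]
    pres <- if (!is.null(cs) && nrow(cs)) iv_overlaps_any(atoms, cs) else rep(FALSE, nrow(atoms))
    rawhit <- if (!is.null(rs) && nrow(rs)) iv_overlaps_any(atoms, rs) else rep(FALSE, nrow(atoms))
    status[, s] <- if_else(pres, 2L, if_else(rawhit, 1L, 0L))
  }

  # merge contiguous atoms with identical status vectors
  key <- apply(status, 1, paste, collapse = ",")
  newgrp <- c(TRUE, atoms$chrom[-1] != atoms$chrom[-nrow(atoms)] |
                atoms$start[-1] != atoms$end[-nrow(atoms)] |
                key[-1] != key[-nrow(atoms)])
  grp <- cumsum(newgrp)
  keep <- !duplicated(grp)
  merged <- tibble(
    chrom = atoms$chrom[keep],
    start = tapply(atoms$start, grp, min)[as.character(unique(grp))],
    end = tapply(atoms$end, grp, max)[as.character(unique(grp))]
  )
  merged$start <- as.numeric(merged$start); merged$end <- as.numeric(merged$end)
  st <- status[keep, , drop = FALSE]

  merged$n_probes <- count_probes_in(merged, layout)
  ok <- merged$n_probes >= config$min_subpeak_probes
  merged <- merged[ok, , drop = FALSE]
  st <- st[ok, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)

  merged$present <- map(seq_len(nrow(merged)), function(i) samples[st[i, ] == 2L])
  merged$absent <- map(seq_len(nrow(merged)), function(i) samples[st[i, ] == 0L])
  merged$ambiguous <- map(seq_len(nrow(merged)), function(i) samples[st[i, ] == 1L])
  merged <- merged[lengths(merged$present) > 0, , drop = FALSE]
  merged$pattern <- map_chr(merged$present, paste, collapse = "+")
  merged$is_flagged <- lengths(merged$ambiguous) > 0
  arrange(as_tibble(merged), .data$chrom, .data$start)
}
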