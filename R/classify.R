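ALL_STAGES <- c("E15", "NB", "AD")
UNME_AD_PATTERNS <- c("E15", "NB", "E15+NB")
ME_AD_PATTERNS <- c("AD", "NB+AD", "E15+AD")

#' Classify tissue-specific DMRs (T-DMRs)
#'
#' A T-DMR is a region methylated in one or more tissues but unmethylated in
#' at least one other. Records whose absent set is empty (and with no
#' ambiguous member) are common methylated regions, not T-DMRs; records
#' present in exactly one tissue are tissue-unique; the rest are multi-tissue
#' T-DMRs. Records with any ambiguous member keep their class but are flagged
#' and excluded from headline counts downstream.
#'
#' @param records DMR-record tibble from [partition_regions()] whose sample
#'   universe is a set of tissues.
#' @param tissues Tissue universe (defaults to the samples seen in `records`).
#' @return `records` with a `dmr_class` column (`"common"`, `"unique"`,
#'   `"multi"`).
#' @export
classify_tdmr <- function(records, tissues = NULL) {
  tissues <- tissues %||% sort(unique(unlist(records$present)))
  check_universe(records, tissues, "classify_tdmr")
  records |>
    mutate(dmr_class = dmr_class_of(.data$present, .data$absent, .data$ambiguous))
}

#' Classify developmental-stage-specific DMRs (DS-DMRs)
#'
#' Within one tissue, a DS-DMR is methylated at one or more of the stages
#' E15 (embryonic day 15), NB (newborn) and AD (adult) but unmethylated in at
#' least one stage: 6 differential patterns plus the common pattern. DS-DMRs
#' are further grouped by adult status: patterns `E15`, `NB`, `E15+NB`
#' (methylated early, unmethylated in adult) are `UnMe-AD` — candidate
#' developmental demethylation; patterns `AD`, `NB+AD`, `E15+AD` are `Me-AD` —
#' candidate de novo methylation.
#'
#' @param records DMR-record tibble from [partition_regions()] whose sample
#'   universe is the three stages of one tissue.
#' @param stages Stage universe, default `c("E15", "NB", "AD")`.
#' @return `records` with `dmr_class` and `stage_group` (`"UnMe-AD"`,
#'   `"Me-AD"`, `"common"`, `"other"`).
#' @export
classify_dsdmr <- function(records, stages = ALL_STAGES) {
  check_universe(records, stages, "classify_dsdmr")
  records |>
    mutate(
      dmr_class = dmr_class_of(.data$present, .data$absent, .data$ambiguous),
      stage_group = dplyr::case_when(
        .data$dmr_class == "common" ~ "common",
        .data$pattern %in% UNME_AD_PATTERNS ~ "UnMe-AD",
        .data$pattern %in% ME_AD_PATTERNS ~ "Me-AD",
        TRUE ~ "other"
      )
    )
}

dmr_class_of <- function(present, absent, ambiguous) {
  dplyr::case_when(
    lengths(absent) == 0 & lengths(ambiguous) == 0 ~ "common",
    lengths(present) == 1 ~ "unique",
    TRUE ~ "multi"
  )
}

check_universe <- function(records, universe, who) {
  seen <- unique(unlist(c(records$present, records$absent, records$ambiguous)))
  if (!all(seen %in% universe)) {
    abort(sprintf("%s: records mention samples outside the universe (%s)",
                  who, paste(setdiff(seen, universe), collapse = ", ")))
  }
  invisible(records)
}

#' Enumerate presence-pattern labels
#'
#' All `2^k - 1` non-empty presence patterns over a sample universe, in
#' canonical order: singletons first (universe order), then larger subsets.
#' Differential patterns (those excluding at least one sample) number
#' `2^k - 2`: 14 for four tissues, 6 for three stages.
#'
#' @param universe Character vector of sample labels.
#' @param differential_only Drop the all-samples (common) pattern.
#' @return Character vector of `+`-joined pattern labels.
#' @export
pattern_universe <- function(universe, differential_only = FALSE) {
  k <- length(universe)
  if (k == 0) return(character(0))
  pats <- unlist(lapply(seq_len(k), function(sz) {
    combn(universe, sz, FUN = paste, collapse = "+")
  }))
  if (differential_only) pats <- pats[pats != paste(universe, collapse = "+")]
  pats
}

#' @importFrom utils combn
NULL
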