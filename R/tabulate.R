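LOCATION_CATEGORIES <- c("CpGi_promoter", "nonCpGi_promoter", "intragenic_CpGi",
                         "intergenic_CpGi", "nonCpGi_intragenic", "nonCpGi_intergenic")

#' Summarise DMR records into a pattern-by-location count table
#'
#' Produces the pattern-level summary used for the headline DMR tables: one
#' row per differential presence pattern with its total count and per
#' location-category counts and percentages (percentages of that row's total,
#' one decimal), followed by group rows (`Total unique`, `Total multi`,
#' `Total DMRs`, and for stage mode `UnMe-AD` / `Me-AD`) and a separate
#' `Common` row. Records flagged ambiguous are excluded.
#'
#' @param records Classified, location-annotated DMR records (columns
#'   `pattern`, `dmr_class`, `location_category`; `stage_group` in dsdmr
#'   mode; optional `is_flagged`).
#' @param mode `"tdmr"` (tissue patterns) or `"dsdmr"` (stage patterns).
#' @param universe Sample universe defining pattern order; defaults to the
#'   three stages in dsdmr mode and the sorted tissues seen otherwise.
#' @param categories Location-category column order.
#' @return Tibble with columns `row`, `row_type` (`"pattern"`, `"group"`,
#'   `"total"`, `"common"`), `total`, then `n_<category>` and `pct_<category>`
#'   pairs.
#' @export
tabulate_dmrs <- function(records, mode = c("tdmr", "dsdmr"), universe = NULL,
                          categories = LOCATION_CATEGORIES) {
  mode <- match.arg(mode)
  universe <- universe %||%
    (if (mode == "dsdmr") ALL_STAGES else sort(unique(unlist(records$present))))
  if (!"location_category" %in% names(records)) {
    abort("tabulate_dmrs: records must be location-annotated (assign_location)")
  }
  if ("is_flagged" %in% names(records)) {
    records <- filter(records, !.data$is_flagged)
  }
  cats <- categories[categories %in% unique(records$location_category) |
                       categories %in% LOCATION_CATEGORIES[1:4]]

  count_block <- function(df) {
    n <- nrow(df)
    cn <- unname(vapply(cats, function(cc) sum(df$location_category == cc), numeric(1)))
    pct <- if (n > 0) round(100 * cn / n, 1) else rep(0, length(cats))
    out <- tibble(total = n)
    for (i in seq_along(cats)) {
      out[[paste0("n_", cats[i])]] <- cn[i]
      out[[paste0("pct_", cats[i])]] <- pct[i]
    }
    out
  }

  diff_pats <- pattern_universe(universe, differential_only = TRUE)
  diff <- filter(records, .data$dmr_class != "common")
  common <- filter(records, .data$dmr_class == "common")

  rows <- list()
  for (p in diff_pats) {
    rows[[length(rows) + 1]] <- bind_cols(
      tibble(row = p, row_type = "pattern"),
      count_block(filter(diff, .data$pattern == p)))
  }
  uniq <- filter(diff, lengths(.data$present) == 1)
  multi <- filter(diff, lengths(.data$present) > 1)
  rows[[length(rows) + 1]] <- bind_cols(tibble(row = "Total unique", row_type = "group"),
                                        count_block(uniq))
  rows[[length(rows) + 1]] <- bind_cols(tibble(row = "Total multi", row_type = "group"),
                                        count_block(multi))
  rows[[length(rows) + 1]] <- bind_cols(tibble(row = "Total DMRs", row_type = "total"),
                                        count_block(diff))
  if (mode == "dsdmr" && "stage_group" %in% names(records)) {
    for (g in c("UnMe-AD", "Me-AD")) {
      rows[[length(rows) + 1]] <- bind_cols(
        tibble(row = g, row_type = "group"),
        count_block(filter(diff, .data$stage_group == g)))
    }
  }
  rows[[length(rows) + 1]] <- bind_cols(tibble(row = "Common", row_type = "common"),
                                        count_block(common))
  out <- bind_rows(rows)
  attr(out, "medip_mode") <- mode
  attr(out, "medip_universe") <- universe
  out
}

#' Adjust pattern counts for unequal replicate concordance
#'
#' Samples with lower replicate Pearson coefficients yield fewer consensus
#' peaks, so raw pattern counts are underestimates. This rescales each
#' differential pattern's count as if every stage had the best Pearson
#' coefficient in that tissue: the per-stage factor is
#' `f_s = r_best / r_s` (on P-score concordance), a single-stage pattern's
#' count is multiplied by `f_s`, a multi-stage pattern's count by the
#' geometric mean of its member factors, and the result is rounded. The best
#' stage's factor is 1, so its counts are unchanged. The rule is this
#' package's declared convention, not a canonical published formula.
#'
#' @param summary_table Output of [tabulate_dmrs()] in dsdmr mode.
#' @param concordance Tibble with columns `stage` and `r` (P-score replicate
#'   Pearson coefficient per stage). All `r` must be positive.
#' @return `summary_table` with an `adjusted` column (`NA` for the common
#'   row); group and total rows are the sums of their adjusted pattern rows.
#' @export
adjust_counts <- function(summary_table, concordance) {
  if (!all(c("stage", "r") %in% names(concordance))) {
    abort("adjust_counts: concordance needs columns stage, r")
  }
  if (any(!is.finite(concordance$r)) || any(concordance$r <= 0)) {
    abort("adjust_counts: Pearson coefficients must be positive")
  }
  r <- setNames(concordance$r, concordance$stage)
  r_best <- max(r)
  factor_of <- function(pattern) {
    members <- strsplit(pattern, "+", fixed = TRUE)[[1]]
    if (!all(members %in% names(r))) {
      abort(sprintf("adjust_counts: no concordance for stage(s) %s",
                    paste(setdiff(members, names(r)), collapse = ", ")))
    }
    exp(mean(log(r_best / r[members])))
  }
  out <- summary_table
  out$adjusted <- NA_real_
  is_pat <- out$row_type == "pattern"
  out$adjusted[is_pat] <- round(out$total[is_pat] *
                                  vapply(out$row[is_pat], factor_of, numeric(1)))
  # group/total rows: sums of their member pattern rows
  pat <- out[is_pat, ]
  set_sum <- function(row_name, sel) {
    if (row_name %in% out$row) out$adjusted[out$row == row_name] <<- sum(pat$adjusted[sel])
  }
  singletons <- !grepl("+", pat$row, fixed = TRUE)
  set_sum("Total unique", singletons)
  set_sum("Total multi", !singletons)
  set_sum("Total DMRs", rep(TRUE, nrow(pat)))
  set_sum("UnMe-AD", pat$row %in% UNME_AD_PATTERNS)
  set_sum("Me-AD", pat$row %in% ME_AD_PATTERNS)
  out |> dplyr::relocate("adjusted", .after = "total")
}

#' @importFrom dplyr bind_cols
NULL
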