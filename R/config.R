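#' Pipeline configuration
#'
#' Collects every tunable numeric constant of the peak-calling and DMR
#' classification pipeline in one place. Defaults are the analysis constants of
#' the MeDIP promoter + CpG-island array protocol: a 750-bp scoring window, a
#' P-score cut of 2 (p <= 0.01), at least 2 consecutive qualifying probes per
#' peak, 500-bp peak merging, TSS +/- 1 kb promoters, 500-bp CpG-island
#' proximity, a 2-kb intergenic clearance, and 2-kb CpG-island shores.
#'
#' @param window_bp Total span (bp) of the KS scoring window centred on each
#'   probe; probes whose centre lies within `window_bp / 2` of the focal
#'   probe's centre are in the window.
#' @param pscore_threshold Minimum P score (-log10 p) for a probe to qualify
#'   for a peak.
#' @param min_consecutive_probes Minimum run length of qualifying probes for a
#'   raw peak.
#' @param merge_bp Peaks with an edge-to-edge gap less than or equal to this
#'   are merged.
#' @param promoter_flank_bp Promoter half-width: promoter = TSS +/- this many
#'   bp, strand-aware.
#' @param cpgi_proximity_bp "Near a CpG island" means edge-to-edge distance
#'   less than or equal to this.
#' @param intergenic_min_bp A CpG island counts as intergenic when it is more
#'   than this many bp from every gene span.
#' @param shore_bp Width of the CpG-island shore flank on each side.
#' @param min_window_probes Windows with fewer probes than this score P = 0.
#' @param min_subpeak_probes Consensus intersections and partition atoms with
#'   fewer probes than this are dropped.
#' @param ks_pvalue_floor Lower clip for the asymptotic KS p-value; caps the
#'   P score at `-log10(ks_pvalue_floor)`.
#' @param max_probe_gap_bp Probe runs are broken where the genomic gap between
#'   consecutive probe centres exceeds this (default unlimited).
#' @param ks_background Either `"exclude"` (background = all array probes not
#'   in the window) or `"all"` (background = every probe, window included).
#' @param biweight_c Tuning constant of the Tukey biweight location estimate.
#'
#' @return A list of class `medip_config`.
#' @export
#' @examples
#' cfg <- medip_config()
#' cfg$window_bp
medip_config <- function(window_bp = 750L,
                         pscore_threshold = 2,
                         min_consecutive_probes = 2L,
                         merge_bp = 500L,
                         promoter_flank_bp = 1000L,
                         cpgi_proximity_bp = 500L,
                         intergenic_min_bp = 2000L,
                         shore_bp = 2000L,
                         min_window_probes = 2L,
                         min_subpeak_probes = 2L,
                         ks_pvalue_floor = 1e-300,
                         max_probe_gap_bp = Inf,
                         ks_background = c("exclude", "all"),
                         biweight_c = 5.0) {
  ks_background <- match.arg(ks_background)
  cfg <- list(
    window_bp = window_bp,
    pscore_threshold = pscore_threshold,
    min_consecutive_probes = as.integer(min_consecutive_probes),
    merge_bp = merge_bp,
    promoter_flank_bp = promoter_flank_bp,
    cpgi_proximity_bp = cpgi_proximity_bp,
    intergenic_min_bp = intergenic_min_bp,
    shore_bp = shore_bp,
    min_window_probes = as.integer(min_window_probes),
    min_subpeak_probes = as.integer(min_subpeak_probes),
    ks_pvalue_floor = ks_pvalue_floor,
    max_probe_gap_bp = max_probe_gap_bp,
    ks_background = ks_background,
    biweight_c = biweight_c
  )
  dists <- c("window_bp", "merge_bp", "promoter_flank_bp", "cpgi_proximity_bp",
             "intergenic_min_bp", "shore_bp")
  for (d in dists) {
    if (!is.numeric(cfg[[d]]) || length(cfg[[d]]) != 1L || cfg[[d]] <= 0) {
      abort(sprintf("`%s` must be a single positive number", d))
    }
  }
  if (cfg$pscore_threshold <= 0) abort("`pscore_threshold` must be > 0")
  if (cfg$ks_pvalue_floor <= 0 || cfg$ks_pvalue_floor >= 1) {
    abort("`ks_pvalue_floor` must be in (0, 1)")
  }
  structure(cfg, class = "medip_config")
}

#' @export
print.medip_config <- function(x, ...) {
  cat("<medip_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
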