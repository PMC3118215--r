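#' Simulation configuration
#'
#' Describes a complete synthetic MeDIP-chip experiment emulating a promoter
#' plus CpG-island array design: four tissues at three developmental stages
#' with two biological replicates each, probes tiling promoters (TSS +/- 1 kb),
#' CpG islands (+/- 500 bp) and optional contiguous tiling regions at ~100-bp
#' spacing, and ground-truth methylated regions whose probe log2 ratios are
#' shifted by `mu_me`. Replicate correlation is controlled by a shared-signal
#' plus independent-noise decomposition: each probe's per-sample value is
#' `shared + noise` with `sd(shared) = sigma * sqrt(rho)` and
#' `sd(noise) = sigma * sqrt(1 - rho)`, so background probes correlate at
#' `rho = replicate_corr_target` between replicates.
#'
#' @param seed Integer seed; all generator output is reproducible given it.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_genes Total genes, spread over chromosomes.
#' @param cpgi_promoter_fraction Fraction of genes given a promoter CpG
#'   island (default 0.685, the CpGi-promoter share of an mm8 RefSeq promoter
#'   set).
#' @param intragenic_cpgi_fraction,n_intergenic_cpgi Additional islands in
#'   gene bodies and far from genes.
#' @param probe_spacing_bp,probe_length_bp Probe tiling geometry.
#' @param tiling_regions Optional interval tibble of contiguous tiling
#'   regions; `NULL` places one 60-kb region on the first chromosome.
#' @param tissues,stages,n_replicates Sample design.
#' @param n_truth_regions Ground-truth methylated regions to draw.
#' @param pattern_distribution Probabilities over truth pattern types
#'   `common` (all samples), `tissue_unique` (one tissue, all stages),
#'   `stage_within_tissue` (one tissue, a proper non-empty stage subset) and
#'   `multi_tissue` (2-3 tissues, all stages).
#' @param mu_me Mean log2-ratio shift inside methylated regions.
#' @param sigma Total per-probe noise SD.
#' @param replicate_corr_target Target background replicate Pearson
#'   correlation.
#' @return A list of class `medip_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 4e6,
                       n_genes = 200L,
                       cpgi_promoter_fraction = 0.685,
                       intragenic_cpgi_fraction = 0.15,
                       n_intergenic_cpgi = 10L,
                       probe_spacing_bp = 100L,
                       probe_length_bp = 50L,
                       tiling_regions = NULL,
                       tissues = c("brain", "heart", "liver", "testis"),
                       stages = c("E15", "NB", "AD"),
                       n_replicates = 2L,
                       n_truth_regions = 200L,
                       pattern_distribution = c(common = 0.10,
                                                tissue_unique = 0.30,
                                                stage_within_tissue = 0.40,
                                                multi_tissue = 0.20),
                       mu_me = 1.5,
                       sigma = 0.4,
                       replicate_corr_target = 0.85) {
  if (abs(sum(pattern_distribution) - 1) > 1e-8) {
    abort("pattern_distribution must sum to 1")
  }
  if (mu_me < 0) abort("mu_me must be >= 0")
  if (sigma <= 0) abort("sigma must be > 0")
  if (replicate_corr_target <= 0 || replicate_corr_target > 1) {
    abort("replicate_corr_target must be in (0, 1]")
  }
  structure(as.list(environment()), class = "medip_sim_config")
}

sample_key <- function(tissue, stage) paste(tissue, stage, sep = ":")

#' Generate a synthetic annotation and probe layout
#'
#' Places non-overlapping genes, gives a configured fraction a promoter CpG
#' island (plus intragenic and intergenic islands), and tiles probes over
#' promoters, island neighbourhoods and tiling regions. Deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `cpgis`, `probes` (a probe layout),
#'   `tiling_regions` and `covered` (the probe-covered intervals).
#' @export
generate_annotation <- function(config = sim_config()) {
  set.seed(config$seed)
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
  genes <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    chr <- paste0("chr", ci)
    nc <- n_per[ci]
    if (nc == 0) next
    slot <- config$chrom_length / nc
    if (slot < 12000) abort("generate_annotation: gene density infeasible for chrom_length")
    for (k in seq_len(nc)) {
      gi <- gi + 1L
      len <- round(stats::runif(1, 4000, min(20000, slot - 5000)))
      start <- round(slot * (k - 1) + stats::runif(1, 2500, slot - len - 2500))
      genes[[gi]] <- tibble(
        gene_id = sprintf("G%04d", gi),
        name = sprintf("Gene%04d", gi),
        chrom = chr, strand = sample(c("+", "-"), 1),
        tx_start = start, tx_end = start + len
      )
    }
  }
  genes <- bind_rows(genes) |>
    mutate(tss = if_else(.data$strand == "+", .data$tx_start, .data$tx_end - 1)) |>
    arrange(.data$chrom, .data$tx_start)

  # promoter CpG islands
  has_cpgi <- stats::runif(nrow(genes)) < config$cpgi_promoter_fraction
  cpgis <- list()
  for (i in which(has_cpgi)) {
    w <- round(stats::runif(1, 600, 1200))
    center <- genes$tss[i] + round(stats::runif(1, -200, 200))
    cpgis[[length(cpgis) + 1]] <- tibble(
      id = sprintf("CpGi_prom_%s", genes$gene_id[i]),
      chrom = genes$chrom[i],
      start = max(center - w / 2, 0), end = center + w / 2
    )
  }
  # intragenic islands, in the body well clear of the promoter window
  flank <- 1000
  for (i in seq_len(nrow(genes))) {
    body_lo <- if (genes$strand[i] == "+") genes$tss[i] + flank + 600 else genes$tx_start[i]
    body_hi <- if (genes$strand[i] == "+") genes$tx_end[i] else genes$tss[i] - flank - 600
    if (body_hi - body_lo < 2000) next
    if (stats::runif(1) >= config$intragenic_cpgi_fraction) next
    w <- round(stats::runif(1, 400, 800))
    start <- round(stats::runif(1, body_lo, body_hi - w))
    cpgis[[length(cpgis) + 1]] <- tibble(
      id = sprintf("CpGi_body_%s", genes$gene_id[i]),
      chrom = genes$chrom[i], start = start, end = start + w
    )
  }
  # intergenic islands, > 2 kb + margin from every gene span
  spans <- select(genes, all_of(c("chrom", "tx_start", "tx_end"))) |>
    rename(start = "tx_start", end = "tx_end")
  placed <- 0L
  attempt <- 0L
  while (placed < config$n_intergenic_cpgi && attempt < 50 * config$n_intergenic_cpgi) {
    attempt <- attempt + 1L
    chr <- paste0("chr", sample.int(config$n_chromosomes, 1))
    w <- round(stats::runif(1, 400, 800))
    start <- round(stats::runif(1, 5000, config$chrom_length - 5000 - w))
    cand <- tibble(chrom = chr, start = start, end = start + w)
    if (min(iv_nearest_distance(cand, spans)) <= config$intergenic_min_margin %||% 3000) next
    placed <- placed + 1L
    cand$id <- sprintf("CpGi_inter_%03d", placed)
    cpgis[[length(cpgis) + 1]] <- cand[, c("id", "chrom", "start", "end")]
  }
  cpgis <- bind_rows(cpgis) |> arrange(.data$chrom, .data$start)

  tiling <- config$tiling_regions %||%
    tibble(chrom = "chr1", start = 5e5 + 20000, end = 5e5 + 80000)

  promoters <- tibble(chrom = genes$chrom, start = pmax(genes$tss - flank, 0),
                      end = genes$tss + flank)
  around_cpgi <- tibble(chrom = cpgis$chrom, start = pmax(cpgis$start - 500, 0),
                        end = cpgis$end + 500)
  covered <- iv_union(bind_rows(promoters, around_cpgi, tiling))

  probes <- list()
  for (i in seq_len(nrow(covered))) {
    centers <- seq(covered$start[i] + config$probe_length_bp / 2,
                   covered$end[i] - config$probe_length_bp / 2,
                   by = config$probe_spacing_bp)
    if (length(centers) == 0) next
    probes[[i]] <- tibble(
      chrom = covered$chrom[i],
      start = centers - config$probe_length_bp / 2,
      end = centers + config$probe_length_bp / 2,
      region_id = i
    )
  }
  probes <- bind_rows(probes) |>
    arrange(.data$chrom, .data$start) |>
    mutate(probe_id = sprintf("P_%s_%09d", .data$chrom, as.integer(.data$start)))
  layout <- as_probe_layout(probes[, c("probe_id", "chrom", "start", "end")])
  layout$region_id <- probes$region_id[match(layout$probe_id, probes$probe_id)]

  list(genes = genes, cpgis = cpgis, probes = layout,
       tiling_regions = tiling, covered = covered)
}

draw_pattern <- function(config) {
  type <- sample(names(config$pattern_distribution), 1,
                 prob = config$pattern_distribution)
  tissues <- config$tissues; stages <- config$stages
  if (type == "common") {
    tt <- tissues; ss <- stages
  } else if (type == "tissue_unique") {
    tt <- sample(tissues, 1); ss <- stages
  } else if (type == "stage_within_tissue") {
    tt <- sample(tissues, 1)
    sz <- sample(length(stages) - 1, 1)
    ss <- sample(stages, sz)
  } else {
    tt <- sample(tissues, sample(2:3, 1)); ss <- stages
  }
  sort(as.vector(outer(tt, ss, sample_key)))
}

#' Draw ground-truth methylated regions
#'
#' Truth regions are runs of 8-15 consecutive probes (about 0.75-1.5 kb,
#' snapped to probe boundaries so truth/call comparison is exact). The scoring
#' window spans 750 bp, so regions at least one window long are at the
#' method's detection resolution; shorter regions dilute every window that
#' covers them and are systematically missed. Consecutive truth regions are
#' separated by at least 14 unselected probes (1.4 kb, more than
#' `merge_bp + window_bp`) so that boundary bleed of the windowed score can
#' never bridge two regions across the 500-bp peak merge. Each region
#' receives a (tissue, stage) presence pattern drawn from
#' `config$pattern_distribution`.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config The same [sim_config()].
#' @return Truth tibble: `chrom`, `start`, `end`, `n_probes`, list-column
#'   `samples` (present sample keys `tissue:stage`) and `pattern`.
#' @export
simulate_truth <- function(annotation, config = sim_config()) {
  set.seed(config$seed + 10000L)
  probes <- annotation$probes
  cand <- list()
  for (rid in unique(probes$region_id)) {
    p <- probes[probes$region_id == rid, ]
    i <- 1L
    while (i + 7 <= nrow(p)) {
      k <- sample(8:15, 1)
      j <- min(i + k - 1, nrow(p))
      if (j - i + 1 >= 8) {
        cand[[length(cand) + 1]] <- tibble(
          chrom = p$chrom[1], start = p$start[i], end = p$end[j],
          n_probes = j - i + 1L)
      }
      i <- j + 1L + 14L
    }
  }
  cand <- bind_rows(cand)
  if (nrow(cand) < config$n_truth_regions) {
    abort(sprintf("simulate_truth: only %d candidate slots for %d truth regions",
                  nrow(cand), config$n_truth_regions))
  }
  truth <- cand[sort(sample.int(nrow(cand), config$n_truth_regions)), ]
  truth$samples <- map(seq_len(nrow(truth)), function(i) draw_pattern(config))
  truth$pattern <- map_chr(truth$samples, paste, collapse = "+")
  arrange(truth, .data$chrom, .data$start)
}

#' Simulate replicate signal tracks
#'
#' Probe value = shared component + replicate noise. The shared component has
#' mean `mu_me` at probes whose centre lies in a truth region containing the
#' sample and 0 elsewhere, with SD `sigma * sqrt(rho)`; replicate noise has SD
#' `sigma * sqrt(1 - rho)`, so background replicate correlation is `rho`.
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param annotation Output of [generate_annotation()].
#' @param config The same [sim_config()].
#' @return Unscaled long signal tibble (`tissue`, `stage`, `replicate`,
#'   `probe_id`, `log2_ratio`).
#' @export
simulate_tracks <- function(truth, annotation, config = sim_config()) {
  set.seed(config$seed + 20000L)
  layout <- annotation$probes
  rho <- config$replicate_corr_target
  sd_shared <- config$sigma * sqrt(rho)
  sd_rep <- config$sigma * sqrt(1 - rho)

  # probe -> truth region containing its centre (truth regions are disjoint)
  truth_idx <- rep(NA_integer_, nrow(layout))
  if (nrow(truth)) {
    gr_p <- GenomicRanges::GRanges(layout$chrom,
                                   IRanges::IRanges(floor(layout$center) + 1,
                                                    floor(layout$center) + 1))
    hit <- GenomicRanges::findOverlaps(gr_p, as_granges(truth))
    truth_idx[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  }

  out <- list()
  for (tt in config$tissues) {
    for (ss in config$stages) {
      key <- sample_key(tt, ss)
      in_sample <- !is.na(truth_idx) &
        map_lgl(truth$samples[pmax(truth_idx, 1)], function(s) key %in% s) &
        !is.na(truth_idx)
      mu <- if_else(in_sample, config$mu_me, 0)
      shared <- stats::rnorm(nrow(layout), mean = mu, sd = sd_shared)
      for (r in seq_len(config$n_replicates)) {
        out[[length(out) + 1]] <- tibble(
          tissue = tt, stage = ss, replicate = r,
          probe_id = layout$probe_id,
          log2_ratio = shared + stats::rnorm(nrow(layout), 0, sd_rep)
        )
      }
    }
  }
  bind_rows(out)
}

#' Simulate a complete experiment
#'
#' @param config A [sim_config()].
#' @return List: `annotation` (genes, cpgis, probes, tiling_regions), `truth`,
#'   `signal` (unscaled long tibble) and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  annotation <- generate_annotation(config)
  truth <- simulate_truth(annotation, config)
  signal <- simulate_tracks(truth, annotation, config)
  list(annotation = annotation, truth = truth, signal = signal, config = config)
}

#' Analytic replicate correlation of the generative model
#'
#' For a sample whose methylated probe fraction is `p`, the between-replicate
#' Pearson correlation implied by the generator is
#' `(p (1 - p) mu^2 + rho sigma^2) / (p (1 - p) mu^2 + sigma^2)`:
#' the shared variance (mixture-mean variance plus shared noise) over the
#' total per-replicate variance.
#'
#' @param p Fraction of probes methylated in the sample.
#' @param config A [sim_config()].
#' @return Correlation in `[0, 1]`.
#' @export
analytic_replicate_correlation <- function(p, config = sim_config()) {
  sig2 <- config$sigma^2
  mix <- p * (1 - p) * config$mu_me^2
  (mix + config$replicate_corr_target * sig2) / (mix + sig2)
}

#' Match detected DMR records against ground truth
#'
#' A detected record matches a truth region when their reciprocal overlap is
#' at least `min_overlap` in both directions. Reports region-level recall
#' (matched truth / truth), precision (matched detected / detected) and
#' pattern accuracy (matched truth whose best-matching record's presence
#' pattern equals the truth pattern, among matched truth).
#'
#' @param detected Tibble `chrom`, `start`, `end`, `pattern`.
#' @param truth Tibble `chrom`, `start`, `end`, `pattern` (patterns in the
#'   same label universe as `detected`).
#' @param min_overlap Reciprocal overlap threshold.
#' @return One-row tibble: `n_truth`, `n_detected`, `recall`, `precision`,
#'   `pattern_accuracy`.
#' @export
evaluate_recovery <- function(detected, truth, min_overlap = 0.5) {
  if (nrow(truth) == 0 || nrow(detected) == 0) {
    return(tibble(n_truth = nrow(truth), n_detected = nrow(detected),
                  recall = 0, precision = 0, pattern_accuracy = NA_real_))
  }
  gt <- as_granges(truth); gd <- as_granges(detected)
  hits <- GenomicRanges::findOverlaps(gt, gd)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(gt[qh], gd[sh]))
  wt <- truth$end[qh] - truth$start[qh]
  wd <- detected$end[sh] - detected$start[sh]
  good <- ov >= min_overlap * wt & ov >= min_overlap * wd
  qh <- qh[good]; sh <- sh[good]; ov <- ov[good]
  truth_matched <- unique(qh)
  det_matched <- unique(sh)
  # best-matching record per matched truth region
  pat_ok <- vapply(truth_matched, function(ti) {
    cand <- sh[qh == ti]
    best <- cand[which.max(ov[qh == ti])]
    identical(sort(strsplit(detected$pattern[best], "+", fixed = TRUE)[[1]]),
              sort(strsplit(truth$pattern[ti], "+", fixed = TRUE)[[1]]))
  }, logical(1))
  tibble(
    n_truth = nrow(truth), n_detected = nrow(detected),
    recall = length(truth_matched) / nrow(truth),
    precision = length(det_matched) / nrow(detected),
    pattern_accuracy = if (length(truth_matched)) mean(pat_ok) else NA_real_
  )
}
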