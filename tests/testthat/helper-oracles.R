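# Independent oracles: deliberately brute-force, sharing no code with the
# package internals (no GenomicRanges, no findInterval tricks).

# per-base boolean mask over [0, size) for one chromosome's intervals
mask_of <- function(iv, size) {
  m <- logical(size)
  for (i in seq_len(nrow(iv))) {
    if (iv$start[i] < size) {
      m[(iv$start[i] + 1):min(iv$end[i], size)] <- TRUE
    }
  }
  m
}

# union length via mask popcount, per chromosome
oracle_union_bp <- function(iv, size = 1e5) {
  sum(vapply(unique(iv$chrom), function(ch) {
    sum(mask_of(iv[iv$chrom == ch, ], size))
  }, numeric(1)))
}

# one-sided D+ by direct evaluation of both right-continuous ECDFs at every
# pooled data point
oracle_dplus <- function(win, bg) {
  pts <- sort(unique(c(win, bg)))
  f_bg <- vapply(pts, function(x) mean(bg <= x), numeric(1))
  f_win <- vapply(pts, function(x) mean(win <= x), numeric(1))
  max(0, f_bg - f_win)
}

oracle_pscore <- function(win, bg, floor = 1e-300) {
  m <- length(win); n <- length(bg)
  d <- oracle_dplus(win, bg)
  p <- exp(-2 * d^2 * m * n / (m + n))
  -log10(min(max(p, floor), 1))
}

# exhaustive permutation p-value for D+ (total size small)
oracle_exact_p <- function(win, bg) {
  pooled <- c(win, bg)
  m <- length(win)
  obs <- oracle_dplus(win, bg)
  picks <- combn(length(pooled), m)
  hits <- 0
  for (j in seq_len(ncol(picks))) {
    w <- pooled[picks[, j]]
    b <- pooled[-picks[, j]]
    if (oracle_dplus(w, b) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(picks)
}

# brute-force run enumeration peak caller: qualifying runs, then transitive
# merge by per-base dilation
oracle_call_peaks <- function(probes, pscores, threshold = 2, min_run = 2,
                              merge_bp = 500) {
  stopifnot(length(unique(probes$chrom)) == 1)
  qual <- pscores >= threshold
  peaks <- list()
  i <- 1
  while (i <= length(qual)) {
    if (!qual[i]) { i <- i + 1; next }
    j <- i
    while (j < length(qual) && qual[j + 1]) j <- j + 1
    if (j - i + 1 >= min_run) {
      peaks[[length(peaks) + 1]] <- c(probes$start[i], probes$end[j])
    }
    i <- j + 1
  }
  if (!length(peaks)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  oracle_dilate_merge(
    data.frame(chrom = probes$chrom[1],
               start = vapply(peaks, `[`, numeric(1), 1),
               end = vapply(peaks, `[`, numeric(1), 2)),
    merge_bp)
}

# transitive-closure merge oracle: dilate each interval by merge_bp/2 on a
# base mask, take connected runs, then shrink back to the hull of members
oracle_dilate_merge <- function(peaks, merge_bp, size = 2e5) {
  out <- list()
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, ]
    half <- merge_bp / 2
    m <- logical(size + merge_bp + 10)
    for (i in seq_len(nrow(p))) {
      lo <- max(floor(p$start[i] - half), 0)
      hi <- ceiling(p$end[i] + half)
      m[(lo + 1):hi] <- TRUE
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      lo <- starts[k] - 1; hi <- ends[k]
      members <- p$start >= lo & p$end <= hi
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(p$start[members]), end = max(p$end[members]))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# iterated-weighted-mean biweight oracle, coded independently
oracle_biweight <- function(x, c = 5) {
  m <- median(x)
  s <- median(abs(x - m))
  if (s == 0) return(m)
  for (it in 1:50) {
    u <- (x - m) / (c * s)
    keep <- abs(u) < 1
    w <- ifelse(keep, (1 - u^2)^2, 0)
    m2 <- sum(w * x) / sum(w)
    if (abs(m2 - m) < 1e-9) break
    m <- m2
  }
  m2
}

# tiny deterministic layout: n probes, fixed spacing, one chromosome
toy_layout <- function(n, spacing = 100, chrom = "chr1", start0 = 0) {
  as_probe_layout(tibble::tibble(
    probe_id = sprintf("%s_p%04d", chrom, seq_len(n)),
    chrom = chrom,
    start = start0 + (seq_len(n) - 1) * spacing,
    end = start0 + (seq_len(n) - 1) * spacing + 50
  ))
}

scaled_track <- function(layout, values) {
  tr <- tibble::tibble(probe_id = layout$probe_id, log2_ratio = values)
  attr(tr, "medip_scaled") <- TRUE
  tr
}

# independent per-rule location predicates for the priority-order oracle
oracle_location <- function(dmr, genes, cpgis, flank = 1000, prox = 500,
                            far = 2000) {
  dist1 <- function(a_start, a_end, b_start, b_end) max(0, max(a_start, b_start) - min(a_end, b_end))
  promoters <- data.frame(chrom = genes$chrom,
                          start = genes$tss - flank, end = genes$tss + flank)
  in_prom <- any(promoters$chrom == dmr$chrom &
                   promoters$start < dmr$end & promoters$end > dmr$start)
  near_cpgi_idx <- which(cpgis$chrom == dmr$chrom &
                           mapply(dist1, dmr$start, dmr$end, cpgis$start, cpgis$end) <= prox)
  rule1 <- in_prom && length(near_cpgi_idx) > 0
  rule2 <- in_prom && length(near_cpgi_idx) == 0
  cpgi_ok3 <- cpgi_ok4 <- FALSE
  for (ci in near_cpgi_idx) {
    in_body <- FALSE
    min_gene_d <- Inf
    for (gi in seq_len(nrow(genes))) {
      if (genes$chrom[gi] != cpgis$chrom[ci]) next
      p_lo <- genes$tss[gi] - flank; p_hi <- genes$tss[gi] + flank
      # body pieces of this gene
      pieces <- rbind(c(genes$tx_start[gi], min(genes$tx_end[gi], p_lo)),
                      c(max(genes$tx_start[gi], p_hi), genes$tx_end[gi]))
      for (r in 1:2) {
        if (pieces[r, 1] < pieces[r, 2] &&
            pieces[r, 1] < cpgis$end[ci] && pieces[r, 2] > cpgis$start[ci]) {
          in_body <- TRUE
        }
      }
      min_gene_d <- min(min_gene_d,
                        dist1(cpgis$start[ci], cpgis$end[ci],
                              genes$tx_start[gi], genes$tx_end[gi]))
    }
    if (in_body) cpgi_ok3 <- TRUE
    if (min_gene_d > far) cpgi_ok4 <- TRUE
  }
  in_span <- any(genes$chrom == dmr$chrom &
                   genes$tx_start < dmr$end & genes$tx_end > dmr$start)
  if (rule1) "CpGi_promoter"
  else if (rule2) "nonCpGi_promoter"
  else if (cpgi_ok3) "intragenic_CpGi"
  else if (cpgi_ok4) "intergenic_CpGi"
  else if (in_span) "nonCpGi_intragenic"
  else "nonCpGi_intergenic"
}
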