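#' Assign each DMR a genomic location category
#'
#' Each DMR receives exactly one category, tested in priority order:
#'
#' 1. **CpGi_promoter** — the DMR overlaps an annotated promoter (TSS +/-
#'    `promoter_flank_bp`, strand-aware) *and* lies within
#'    `cpgi_proximity_bp` of some CpG island;
#' 2. **nonCpGi_promoter** — overlaps a promoter with no CpG island within
#'    `cpgi_proximity_bp` of the DMR;
#' 3. **intragenic_CpGi** — within `cpgi_proximity_bp` of a CpG island that
#'    itself overlaps a gene body (the gene span excluding that gene's
#'    promoter window);
#' 4. **intergenic_CpGi** — within `cpgi_proximity_bp` of a CpG island that is
#'    more than `intergenic_min_bp` from every gene span;
#' 5. **nonCpGi_intragenic** / 6. **nonCpGi_intergenic** — fallback by
#'    gene-span overlap. These two arose for tiling-array regions; with
#'    `strict_tiling = TRUE` they are only emitted inside the declared
#'    `tiling_regions` and other fall-through DMRs get `NA`.
#'
#' All distances are edge-to-edge ([iv_distance()]). Matching gene and CpGi
#' ids for the winning rule are recorded as list-columns. Assignments do not
#' depend on annotation record order.
#'
#' @param dmrs Interval tibble of DMRs.
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @param cpgis CpG-island tibble ([read_cpg_islands()]).
#' @param config A [medip_config()].
#' @param tiling_regions Optional interval tibble of tiling regions.
#' @param strict_tiling Restrict categories 5/6 to tiling regions.
#' @return `dmrs` with `location_category`, `associated_gene_ids`,
#'   `associated_cpgi_ids`.
#' @export
assign_location <- function(dmrs, genes, cpgis, config = medip_config(),
                            tiling_regions = NULL, strict_tiling = FALSE) {
  nd <- nrow(dmrs)
  out <- as_tibble(dmrs)
  if (nd == 0) {
    out$location_category <- character(0)
    out$associated_gene_ids <- list()
    out$associated_cpgi_ids <- list()
    return(out)
  }
  promoters <- tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = genes$tss - config$promoter_flank_bp,
    end = genes$tss + config$promoter_flank_bp
  )
  spans <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                  start = genes$tx_start, end = genes$tx_end)
  # gene bodies: each gene's span minus its own promoter window (at most two
  # pieces per gene; plain arithmetic, the promoter is a single interval)
  left <- tibble(chrom = spans$chrom, start = spans$start,
                 end = pmin(spans$end, promoters$start), gene_id = spans$gene_id)
  right <- tibble(chrom = spans$chrom, start = pmax(spans$start, promoters$end),
                  end = spans$end, gene_id = spans$gene_id)
  body_tbl <- bind_rows(left, right)
  body_tbl <- body_tbl[body_tbl$start < body_tbl$end, , drop = FALSE]

  gd <- as_granges(out[c("chrom", "start", "end")])

  # hit lists: for each DMR, ids of annotation features matching a predicate
  hit_ids <- function(ref, ids, maxgap = -1L) {
    res <- vector("list", nd)
    for (i in seq_len(nd)) res[[i]] <- character(0)
    if (nrow(ref) == 0) return(res)
    h <- GenomicRanges::findOverlaps(gd, as_granges(ref), maxgap = maxgap)
    if (length(h)) {
      sp <- split(ids[S4Vectors::subjectHits(h)], S4Vectors::queryHits(h))
      for (q in names(sp)) res[[as.integer(q)]] <- unique(sp[[q]])
    }
    res
  }

  prom_hits <- hit_ids(promoters, promoters$gene_id)
  span_hits <- hit_ids(spans, spans$gene_id)
  near_cpgi <- hit_ids(cpgis, cpgis$id, maxgap = config$cpgi_proximity_bp)

  # CpGi properties (independent of the DMR)
  if (nrow(cpgis)) {
    cpgi_gene_dist <- iv_nearest_distance(cpgis[c("chrom", "start", "end")],
                                          spans[c("chrom", "start", "end")])
    cpgi_in_body <- iv_overlaps_any(cpgis[c("chrom", "start", "end")], body_tbl)
    cpgi_intergenic <- cpgi_gene_dist > config$intergenic_min_bp
    body_ids <- cpgis$id[cpgi_in_body]
    inter_ids <- cpgis$id[cpgi_intergenic]
    # genes whose body each body-CpGi overlaps (for association records)
    cpgi_body_genes <- map(which(cpgi_in_body), function(i) {
      hit <- iv_overlaps_any(body_tbl, cpgis[i, c("chrom", "start", "end")])
      unique(body_tbl$gene_id[hit])
    })
    names(cpgi_body_genes) <- body_ids
  } else {
    body_ids <- inter_ids <- character(0)
    cpgi_body_genes <- list()
  }

  in_tiling <- if (!is.null(tiling_regions) && nrow(tiling_regions) > 0) {
    iv_overlaps_any(out[c("chrom", "start", "end")], tiling_regions)
  } else rep(FALSE, nd)

  category <- character(nd)
  gene_ids <- vector("list", nd)
  cpgi_ids <- vector("list", nd)
  for (i in seq_len(nd)) {
    near <- near_cpgi[[i]]
    if (length(prom_hits[[i]]) && length(near)) {
      category[i] <- "CpGi_promoter"
      gene_ids[[i]] <- prom_hits[[i]]; cpgi_ids[[i]] <- near
    } else if (length(prom_hits[[i]])) {
      category[i] <- "nonCpGi_promoter"
      gene_ids[[i]] <- prom_hits[[i]]; cpgi_ids[[i]] <- character(0)
    } else {
      near_body <- near[near %in% body_ids]
      near_inter <- near[near %in% inter_ids]
      if (length(near_body)) {
        category[i] <- "intragenic_CpGi"
        cpgi_ids[[i]] <- near_body
        gene_ids[[i]] <- unique(unlist(cpgi_body_genes[near_body]))
      } else if (length(near_inter)) {
        category[i] <- "intergenic_CpGi"
        cpgi_ids[[i]] <- near_inter; gene_ids[[i]] <- character(0)
      } else {
        category[i] <- if (length(span_hits[[i]])) "nonCpGi_intragenic" else "nonCpGi_intergenic"
        gene_ids[[i]] <- span_hits[[i]]; cpgi_ids[[i]] <- character(0)
        if (strict_tiling && !in_tiling[i]) category[i] <- NA_character_
      }
    }
  }
  out$location_category <- category
  out$associated_gene_ids <- gene_ids
  out$associated_cpgi_ids <- cpgi_ids
  out
}

#' DMR density in CpG islands versus CpG-island shores
#'
#' Shores are the `shore_bp` flanks on each side of each CpG island, taken as
#' a union and with any island base removed, so islands and shores partition
#' disjoint base sets. Density is reported per bp of compartment both in
#' DMR-bp terms (overlap bp / compartment bp) and in count terms (number of
#' DMRs touching the compartment / compartment bp).
#'
#' @param dmrs Interval tibble of DMRs.
#' @param cpgis CpG-island tibble.
#' @param config A [medip_config()].
#' @return One-row tibble: `island_bp`, `shore_bp`, `island_dmr_bp`,
#'   `shore_dmr_bp`, `island_density`, `shore_density`, `island_count_density`,
#'   `shore_count_density`. Densities are `NaN` for an empty compartment.
#' @export
shore_density <- function(dmrs, cpgis, config = medip_config()) {
  islands <- iv_union(cpgis[c("chrom", "start", "end")])
  flanks <- bind_rows(
    tibble(chrom = islands$chrom, start = pmax(islands$start - config$shore_bp, 0),
           end = islands$start),
    tibble(chrom = islands$chrom, start = islands$end,
           end = islands$end + config$shore_bp)
  )
  flanks <- flanks[flanks$start < flanks$end, ]
  shores <- iv_setdiff(flanks, islands)

  comp_stats <- function(comp) {
    bp <- sum(comp$end - comp$start)
    if (bp == 0 || nrow(dmrs) == 0) {
      return(list(bp = bp, dmr_bp = 0,
                  dens = if (bp == 0) NaN else 0,
                  cdens = if (bp == 0) NaN else 0))
    }
    # unique DMR base-pairs in the compartment (overlapping DMRs not double-counted)
    dmr_bp <- sum(iv_overlap_bp(iv_union(dmrs[c("chrom", "start", "end")]), comp))
    n_hit <- sum(iv_overlaps_any(dmrs[c("chrom", "start", "end")], comp))
    list(bp = bp, dmr_bp = dmr_bp, dens = dmr_bp / bp, cdens = n_hit / bp)
  }
  isl <- comp_stats(islands)
  sho <- comp_stats(shores)
  tibble(island_bp = isl$bp, shore_bp = sho$bp,
         island_dmr_bp = isl$dmr_bp, shore_dmr_bp = sho$dmr_bp,
         island_density = isl$dens, shore_density = sho$dens,
         island_count_density = isl$cdens, shore_count_density = sho$cdens)
}
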