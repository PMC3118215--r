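lay300 <- toy_layout(300, spacing = 100)

cons_row <- function(sample, start, end, chrom = "chr1") {
  tibble::tibble(sample = sample, chrom = chrom, start = start, end = end)
}

test_that("partitioning splits overlapping peaks into presence atoms", {
  cfg <- medip_config()
  cons <- dplyr::bind_rows(cons_row("A", 0, 1000), cons_row("B", 500, 1500))
  raw <- dplyr::bind_rows(
    dplyr::mutate(cons_row("A", 0, 1000), replicate = 1L),
    dplyr::mutate(cons_row("A", 0, 1000), replicate = 2L),
    dplyr::mutate(cons_row("B", 500, 1500), replicate = 1L),
    dplyr::mutate(cons_row("B", 500, 1500), replicate = 2L))
  rec <- partition_regions(cons, raw, lay300, cfg, samples = c("A", "B"))
  expect_equal(rec$start, c(0, 500, 1000))
  expect_equal(rec$end, c(500, 1000, 1500))
  expect_equal(rec$pattern, c("A", "A+B", "B"))
  expect_equal(rec$is_flagged, rep(FALSE, 3))
  # conservation: atoms cover exactly the union of consensus bp
  expect_equal(sum(rec$end - rec$start), 1500)

  # single sample: atoms identical to its consensus peaks
  solo_raw <- dplyr::bind_rows(
    dplyr::mutate(cons_row("A", 200, 900), replicate = 1L),
    dplyr::mutate(cons_row("A", 200, 900), replicate = 2L))
  solo <- partition_regions(cons_row("A", 200, 900), solo_raw,
                            lay300, cfg, samples = "A")
  expect_equal(c(solo$start, solo$end), c(200, 900))
})

test_that("a lone-replicate raw peak makes a sample ambiguous, not absent", {
  cfg <- medip_config()
  cons <- cons_row("A", 0, 1000)
  raw <- dplyr::bind_rows(
    dplyr::mutate(cons_row("A", 0, 1000), replicate = 1L),
    dplyr::mutate(cons_row("A", 0, 1000), replicate = 2L),
    dplyr::mutate(cons_row("B", 300, 800), replicate = 1L))
  rec <- partition_regions(cons, raw, lay300, cfg, samples = c("A", "B"))
  amb <- rec[purrr::map_lgl(rec$ambiguous, ~ "B" %in% .x), ]
  expect_gt(nrow(amb), 0)
  expect_true(all(amb$is_flagged))
  # the flagged stretch is excluded from clean unique records
  clean_unique <- rec[rec$pattern == "A" & !rec$is_flagged, ]
  expect_true(all(clean_unique$end <= 300 | clean_unique$start >= 800))
})

test_that("partition conserves consensus coverage (mask oracle)", {
  set.seed(61)
  cfg <- medip_config(min_subpeak_probes = 1L)  # no floor: exact conservation
  lay <- toy_layout(1000, spacing = 100)
  for (rep in 1:5) {
    samples <- c("s1", "s2", "s3")
    cons <- dplyr::bind_rows(lapply(samples, function(s) {
      k <- sample(3:8, 1)
      st <- sort(sample(seq(0, 9e4, 1000), k))
      merge_peaks(tibble::tibble(sample = s, chrom = "chr1", start = st,
                                 end = st + sample(c(800, 1500, 3000), k, TRUE)), 0) |>
        dplyr::mutate(sample = s)
    }))
    raw <- dplyr::bind_rows(dplyr::mutate(cons, replicate = 1L),
                            dplyr::mutate(cons, replicate = 2L))
    rec <- partition_regions(cons[c("sample", "chrom", "start", "end")],
                             raw, lay, cfg, samples = samples)
    expect_equal(oracle_union_bp(rec, 1e5 + 3000),
                 oracle_union_bp(cons, 1e5 + 3000))
    # per-sample: bases where s is present equal s's consensus bases
    for (s in samples) {
      rs <- rec[purrr::map_lgl(rec$present, ~ s %in% .x), ]
      expect_equal(oracle_union_bp(rs, 1e5 + 3000),
                   oracle_union_bp(cons[cons$sample == s, ], 1e5 + 3000))
    }
  }
})

test_that("T-DMR classes follow the presence pattern", {
  tissues <- c("brain", "heart", "liver", "testis")
  spec <- tibble::tibble(
    pattern = c("common", "testis", "brain+heart"),
    location_category = "nonCpGi_promoter",
    count = c(1, 1, 1))
  rec <- classify_tdmr(fixture_from_counts(spec, tissues), tissues)
  expect_equal(rec$dmr_class, c("common", "unique", "multi"))
  expect_equal(rec$pattern[3], "brain+heart")
  expect_equal(rec$absent[[3]], c("liver", "testis"))
})

test_that("DS-DMR stage groups split into UnMe-AD and Me-AD", {
  stages <- c("E15", "NB", "AD")
  spec <- tibble::tibble(
    pattern = c("E15+NB", "AD", "E15+NB+AD", "E15", "NB+AD"),
    location_category = "CpGi_promoter", count = 1)
  rec <- classify_dsdmr(fixture_from_counts(spec, stages), stages)
  expect_equal(rec$dmr_class, c("multi", "unique", "common", "unique", "multi"))
  expect_equal(rec$stage_group, c("UnMe-AD", "Me-AD", "common", "UnMe-AD", "Me-AD"))
})

test_that("pattern universes are exhaustive: 14 tissue and 6 stage patterns", {
  tissues <- c("brain", "heart", "liver", "testis")
  expect_length(pattern_universe(tissues, differential_only = TRUE), 14)
  expect_length(pattern_universe(tissues), 15)
  expect_length(pattern_universe(c("E15", "NB", "AD"), differential_only = TRUE), 6)
  # every emitted region falls in exactly one class
  set.seed(71)
  for (rep in 1:20) {
    pres <- sample(tissues, sample(4, 1))
    pat <- paste(tissues[tissues %in% pres], collapse = "+")
    expect_equal(sum(pattern_universe(tissues) == pat), 1)
  }
})

test_that("classification is invariant to record order", {
  tissues <- c("brain", "heart", "liver", "testis")
  spec <- tibble::tibble(pattern = c("brain", "heart+liver", "common"),
                         location_category = "intragenic_CpGi", count = 2)
  rec <- fixture_from_counts(spec, tissues)
  shuffled <- rec[sample(nrow(rec)), ]
  a <- classify_tdmr(rec, tissues)
  b <- dplyr::arrange(classify_tdmr(shuffled, tissues), start)
  expect_equal(a$dmr_class, b$dmr_class)
})

test_that("count adjustment applies the r-ratio and geometric-mean rules", {
  stages <- c("E15", "NB", "AD")
  spec <- tibble::tibble(
    pattern = c("E15", "NB", "AD", "E15+NB", "NB+AD", "E15+AD"),
    location_category = "nonCpGi_promoter",
    count = c(100, 50, 80, 40, 70, 10))
  tab <- tabulate_dmrs(classify_dsdmr(fixture_from_counts(spec, stages), stages),
                       mode = "dsdmr", universe = stages)

  # equal coefficients: adjusted equals raw everywhere
  conc_eq <- tibble::tibble(stage = stages, r = 0.9)
  adj_eq <- adjust_counts(tab, conc_eq)
  pat <- adj_eq[adj_eq$row_type == "pattern", ]
  expect_equal(pat$adjusted, pat$total)

  # count 100 at r_best 0.9, r_s 0.75 -> 120
  conc <- tibble::tibble(stage = stages, r = c(0.75, 0.9, 0.9 / 1.30))
  adj <- adjust_counts(tab, conc)
  expect_equal(adj$adjusted[adj$row == "E15"], round(100 * 0.9 / 0.75))
  # multi-stage: geometric mean of member factors
  f_NB <- 1; f_AD <- 1.30
  expect_equal(adj$adjusted[adj$row == "NB+AD"], round(70 * sqrt(f_NB * f_AD)))
  expect_equal(adj$adjusted[adj$row == "Total DMRs"],
               sum(adj$adjusted[adj$row_type == "pattern"]))

  expect_error(adjust_counts(tab, tibble::tibble(stage = stages, r = c(0.9, -0.1, 0.8))),
               "positive")
})

test_that("tabulation sums and percentages are internally consistent", {
  tissues <- c("brain", "heart", "liver", "testis")
  empty_rec <- classify_tdmr(
    fixture_from_counts(tibble::tibble(pattern = character(),
                                       location_category = character(),
                                       count = numeric()), tissues),
    tissues)
  empty <- tabulate_dmrs(empty_rec, mode = "tdmr", universe = tissues)
  expect_true(all(empty$total == 0))

  set.seed(81)
  pats <- pattern_universe(tissues)
  cats <- c("CpGi_promoter", "nonCpGi_promoter", "intragenic_CpGi", "intergenic_CpGi")
  spec <- tidyr::expand_grid(pattern = pats, location_category = cats)
  spec$count <- sample(0:30, nrow(spec), replace = TRUE)
  spec$pattern[spec$pattern == paste(tissues, collapse = "+")] <- "common"
  tab <- tabulate_dmrs(classify_tdmr(fixture_from_counts(spec, tissues), tissues),
                       mode = "tdmr", universe = tissues)
  pat_rows <- tab[tab$row_type == "pattern", ]
  expect_equal(sum(pat_rows$total), tab$total[tab$row == "Total DMRs"])
  expect_equal(tab$total[tab$row == "Total unique"] + tab$total[tab$row == "Total multi"],
               tab$total[tab$row == "Total DMRs"])
  # row percentages sum to ~100
  pcts <- rowSums(as.matrix(pat_rows[grep("^pct_", names(pat_rows))]))
  expect_true(all(abs(pcts[pat_rows$total > 0] - 100) <= 0.2))
})

test_that("cross-tissue overlap separates unique from clustered regions", {
  # pairwise-disjoint sets: unique fraction 1
  sets <- fixture_overlap_sets(c(brain = 3, heart = 2, liver = 4),
                               tibble::tibble(tissues = character(), n = integer()))
  ov <- cross_tissue_overlap(sets)
  expect_equal(ov$unique_fraction, 1)
  expect_equal(ov$total_with_multiplicity, 9)
  expect_equal(ov$total_dedup, 9)

  # identical sets in all tissues: unique 0, one cluster per region
  base <- tibble::tibble(chrom = "chr1", start = c(0, 5000), end = c(1000, 6000))
  sets2 <- dplyr::bind_rows(lapply(c("brain", "heart"), function(t)
    dplyr::mutate(base, tissue = t)))
  ov2 <- cross_tissue_overlap(sets2)
  expect_equal(ov2$unique_total, 0)
  expect_equal(ov2$multi_clusters, 2)
  expect_equal(ov2$unique_fraction, 0)
  expect_equal(ov2$common_all, 2)
})
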