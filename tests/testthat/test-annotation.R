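mk_genes <- function(...) {
  g <- tibble::tibble(...)
  g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1)
  g$name <- g$gene_id
  g
}

test_that("location rules assign the four core categories", {
  cfg <- medip_config()
  genes <- mk_genes(gene_id = "G1", chrom = "chr1", strand = "+",
                    tx_start = 10000, tx_end = 30000)
  cpgis <- tibble::tibble(id = c("prom", "body", "inter"), chrom = "chr1",
                          start = c(9800, 15000, 60000),
                          end = c(10200, 15600, 60500))

  dmr <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e)

  # rule 1: inside promoter and within 500 bp of a CpGi
  expect_equal(assign_location(dmr(10050, 10150), genes, cpgis, cfg)$location_category,
               "CpGi_promoter")
  # rule 2: inside promoter, nearest CpGi 600 bp away
  cpg_far <- tibble::tibble(id = "far", chrom = "chr1", start = 11400, end = 11600)
  expect_equal(assign_location(dmr(10700, 10800), genes, cpg_far, cfg)$location_category,
               "nonCpGi_promoter")
  # rule 3: near an intragenic CpGi, outside the promoter
  expect_equal(assign_location(dmr(15700, 15900), genes, cpgis, cfg)$location_category,
               "intragenic_CpGi")
  # rule 4: near a CpGi > 2 kb from any gene
  expect_equal(assign_location(dmr(60600, 60900), genes, cpgis, cfg)$location_category,
               "intergenic_CpGi")
  # fall-through: in the gene body, no CpGi near
  expect_equal(assign_location(dmr(25000, 25400), genes, cpgis, cfg)$location_category,
               "nonCpGi_intragenic")
  expect_equal(assign_location(dmr(80000, 80400), genes, cpgis, cfg)$location_category,
               "nonCpGi_intergenic")
})

test_that("CpGi promoter outranks every other matching rule", {
  cfg <- medip_config()
  # DMR inside G1's promoter and within 500 bp of a CpGi lying in G2's body
  genes <- mk_genes(gene_id = c("G1", "G2"), chrom = "chr1", strand = "+",
                    tx_start = c(10000, 5000), tx_end = c(30000, 9500))
  cpgis <- tibble::tibble(id = "bodyG2", chrom = "chr1", start = 9100, end = 9400)
  d <- tibble::tibble(chrom = "chr1", start = 9600, end = 9900)
  got <- assign_location(d, genes, cpgis, cfg)
  expect_equal(got$location_category, "CpGi_promoter")
  expect_true("G1" %in% got$associated_gene_ids[[1]])
})

test_that("assignments match an independently coded rule oracle", {
  set.seed(91)
  cfg <- medip_config()
  for (rep in 1:4) {
    n_g <- 6
    starts <- sort(sample(seq(5000, 9e4, 1500), n_g))
    genes <- mk_genes(gene_id = sprintf("G%d", 1:n_g), chrom = "chr1",
                      strand = sample(c("+", "-"), n_g, replace = TRUE),
                      tx_start = starts, tx_end = starts + sample(3000:9000, n_g))
    n_c <- 5
    cs <- sample(seq(0, 9.5e4, 700), n_c)
    cpgis <- tibble::tibble(id = sprintf("C%d", 1:n_c), chrom = "chr1",
                            start = cs, end = cs + sample(300:900, n_c))
    ds <- sample(seq(0, 9.8e4, 350), 40)
    dmrs <- tibble::tibble(chrom = "chr1", start = ds, end = ds + 300)
    got <- assign_location(dmrs, genes, cpgis, cfg)$location_category
    want <- vapply(seq_len(nrow(dmrs)), function(i) {
      oracle_location(dmrs[i, ], genes, cpgis)
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("assignment ignores annotation record order", {
  set.seed(101)
  cfg <- medip_config()
  genes <- mk_genes(gene_id = sprintf("G%d", 1:4), chrom = "chr1",
                    strand = c("+", "-", "+", "-"),
                    tx_start = c(1e4, 3e4, 5e4, 7e4),
                    tx_end = c(1e4, 3e4, 5e4, 7e4) + 8000)
  cpgis <- tibble::tibble(id = sprintf("C%d", 1:4), chrom = "chr1",
                          start = c(9900, 33000, 49800, 90000),
                          end = c(10300, 33500, 50200, 90400))
  ds <- seq(8000, 9.2e4, 2000)
  dmrs <- tibble::tibble(chrom = "chr1", start = ds, end = ds + 400)
  a <- assign_location(dmrs, genes, cpgis, cfg)
  b <- assign_location(dmrs, genes[sample(4), ], cpgis[sample(4), ], cfg)
  expect_equal(a$location_category, b$location_category)
})

test_that("strict tiling mode restricts the two fall-through categories", {
  cfg <- medip_config()
  genes <- mk_genes(gene_id = "G1", chrom = "chr1", strand = "+",
                    tx_start = 10000, tx_end = 30000)
  cpgis <- tibble::tibble(id = "x", chrom = "chr1", start = 9800, end = 10200)
  tiling <- tibble::tibble(chrom = "chr1", start = 20000, end = 40000)
  dmrs <- tibble::tibble(chrom = "chr1", start = c(25000, 50000),
                         end = c(25400, 50400))
  strict <- assign_location(dmrs, genes, cpgis, cfg, tiling_regions = tiling,
                            strict_tiling = TRUE)
  expect_equal(strict$location_category, c("nonCpGi_intragenic", NA))
  loose <- assign_location(dmrs, genes, cpgis, cfg, tiling_regions = tiling)
  expect_equal(loose$location_category,
               c("nonCpGi_intragenic", "nonCpGi_intergenic"))
})

test_that("island and shore densities follow the mask oracle", {
  cfg <- medip_config()
  cpgis <- tibble::tibble(id = "c1", chrom = "chr1", start = 10000, end = 11000)

  none <- shore_density(tibble::tibble(chrom = character(), start = numeric(),
                                       end = numeric()), cpgis, cfg)
  expect_equal(none$island_density, 0)
  expect_equal(none$shore_density, 0)

  # one DMR exactly covering the only island, nothing in shores
  exact <- shore_density(tibble::tibble(chrom = "chr1", start = 10000, end = 11000),
                         cpgis, cfg)
  expect_equal(exact$island_density, 1)
  expect_equal(exact$shore_density, 0)
  expect_equal(exact$shore_bp, 4000)  # 2 kb each side, islands excluded

  # random DMRs on a 1e5-bp toy genome: densities equal the mask oracle
  set.seed(111)
  cs <- c(20000, 21500, 60000)
  cp <- tibble::tibble(id = sprintf("c%d", 1:3), chrom = "chr1",
                       start = cs, end = cs + c(800, 500, 1200))
  ds <- sample(seq(1.5e4, 7e4, 137), 60)
  dmrs <- tibble::tibble(chrom = "chr1", start = ds, end = ds + sample(100:900, 60, TRUE))
  got <- shore_density(dmrs, cp, cfg)

  size <- 1e5
  m_isl <- mask_of(cp, size)
  m_fl <- mask_of(tibble::tibble(chrom = "chr1",
                                 start = c(cs - 2000, cs + c(800, 500, 1200)),
                                 end = c(cs, cs + c(800, 500, 1200) + 2000)), size)
  m_sho <- m_fl & !m_isl
  m_dmr <- mask_of(dmrs, size)
  expect_equal(got$island_bp, sum(m_isl))
  expect_equal(got$shore_bp, sum(m_sho))
  expect_equal(got$island_density, sum(m_dmr & m_isl) / sum(m_isl))
  expect_equal(got$shore_density, sum(m_dmr & m_sho) / sum(m_sho))
})
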