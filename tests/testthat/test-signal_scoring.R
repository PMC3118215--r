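test_that("biweight mean handles degenerate and outlier cases", {
  expect_equal(biweight_mean(c(0.5, 0.5, 0.5)), 0.5)  # MAD = 0 branch
  expect_equal(biweight_mean(c(-1, 0, 1)), 0)          # symmetry
  x <- c(0, 0.1, -0.1, 0.05, 8.0)
  bw <- biweight_mean(x)
  expect_equal(bw, oracle_biweight(x), tolerance = 1e-9)
  expect_lt(abs(bw - median(x)), 0.15)   # robust: stays near the median
  expect_gt(abs(bw - mean(x)), 1)        # far from the outlier-dragged mean
  expect_error(biweight_mean(numeric(0)), "finite")
})

test_that("scaling centres each track at biweight zero and is shift-invariant", {
  lay <- toy_layout(50)
  base <- rnorm(50)
  mk <- function(v) tibble::tibble(tissue = "brain", stage = "AD", replicate = 1L,
                                   probe_id = lay$probe_id, log2_ratio = v)
  s1 <- scale_tracks(mk(base))
  s2 <- scale_tracks(mk(base + 3.7))
  expect_equal(s1$log2_ratio, s2$log2_ratio, tolerance = 1e-8)

  # already-centred track is unchanged
  centred <- base - biweight_mean(base)
  expect_equal(scale_tracks(mk(centred))$log2_ratio, centred, tolerance = 1e-8)

  # post-condition at n = 1000
  set.seed(11)
  v <- rnorm(1000, mean = 0.3, sd = 1)
  lay2 <- toy_layout(1000)
  sc <- scale_tracks(tibble::tibble(probe_id = lay2$probe_id, log2_ratio = v))
  expect_lt(abs(biweight_mean(sc$log2_ratio)), 1e-9)

  expect_error(scale_tracks(s1), "already scaled")
})

test_that("windowed KS P score matches the closed form and decision rules", {
  # 3 clustered probes at 2.0 vs 97 isolated probes at 0.0
  lay <- as_probe_layout(tibble::tibble(
    probe_id = sprintf("p%03d", 1:100), chrom = "chr1",
    start = c(0, 100, 200, seq(10000, by = 2000, length.out = 97)),
    end = c(0, 100, 200, seq(10000, by = 2000, length.out = 97)) + 50))
  tr <- scaled_track(lay, c(2, 2, 2, rep(0, 97)))
  ps <- windowed_ks_pscore(tr, lay, medip_config())
  expect_equal(ps$pscore[2], -log10(exp(-2 * 1^2 * 3 * 97 / 100)), tolerance = 1e-10)

  # isolated probes have windows of size 1 < min_window_probes -> P = 0
  expect_true(all(ps$pscore[4:100] == 0))

  # anti-enriched window (values at the background minimum) -> p ~ 1 -> P ~ 0
  set.seed(1)
  tr2 <- scaled_track(lay, c(-5, -5, -5, rnorm(97)))
  ps2 <- windowed_ks_pscore(tr2, lay, medip_config())
  expect_equal(ps2$pscore[1:3], rep(0, 3))

  expect_error(windowed_ks_pscore(tibble::tibble(probe_id = lay$probe_id,
                                                 log2_ratio = 0), lay),
               "scaled")
})

test_that("windowed KS agrees with the direct ECDF oracle on random tracks", {
  set.seed(5)
  cfg <- medip_config()
  for (rep in 1:3) {
    lay <- toy_layout(60)
    vals <- rnorm(60) + ifelse(seq_len(60) %in% 20:28, 1.2, 0)
    tr <- scaled_track(lay, vals)
    ps <- windowed_ks_pscore(tr, lay, cfg)
    for (i in c(1, 10, 24, 40, 60)) {
      win <- which(abs(lay$center - lay$center[i]) <= cfg$window_bp / 2)
      expect_equal(ps$pscore[i],
                   oracle_pscore(vals[win], vals[-win]),
                   tolerance = 1e-9, label = sprintf("probe %d", i))
    }
  }
})

test_that("P score is monotone in a window-wide positive offset", {
  set.seed(9)
  lay <- toy_layout(80)
  base <- rnorm(80)
  cfg <- medip_config()
  i <- 40
  win <- which(abs(lay$center - lay$center[i]) <= cfg$window_bp / 2)
  prev <- -Inf
  for (offset in c(0, 0.3, 0.8, 1.5, 3)) {
    v <- base
    v[win] <- v[win] + offset
    p <- windowed_ks_pscore(scaled_track(lay, v), lay, cfg)$pscore[i]
    expect_gte(p + 1e-12, prev)
    prev <- p
  }
})

test_that("pure-noise tracks rarely exceed the peak threshold", {
  cfg <- medip_config()
  fracs <- vapply(1:10, function(seed) {
    set.seed(seed)
    lay <- toy_layout(300)
    ps <- windowed_ks_pscore(scaled_track(lay, rnorm(300, 0, 0.4)), lay, cfg)
    mean(ps$pscore >= 2)
  }, numeric(1))
  expect_true(all(fracs <= 0.05))
})

test_that("asymptotic p ranks like the exact permutation p for small samples", {
  set.seed(13)
  m <- 4; n <- 8
  p_asym <- p_exact <- numeric(20)
  for (k in 1:20) {
    win <- rnorm(m, mean = runif(1, 0, 2))
    bg <- rnorm(n)
    d <- oracle_dplus(win, bg)
    p_asym[k] <- exp(-2 * d^2 * m * n / (m + n))
    p_exact[k] <- oracle_exact_p(win, bg)
  }
  # sorting by the asymptotic p never decreases the exact p (ties allowed)
  ord <- order(p_asym)
  expect_true(all(diff(p_exact[ord]) >= -1e-9))
})

test_that("replicate concordance recovers the analytic correlation", {
  lay <- toy_layout(30)
  a <- tibble::tibble(probe_id = lay$probe_id, log2_ratio = rnorm(30))
  expect_equal(replicate_concordance(a, a)$r, 1)
  b <- dplyr::mutate(a, log2_ratio = -log2_ratio)
  expect_equal(replicate_concordance(a, b)$r, -1)

  flat <- dplyr::mutate(a, log2_ratio = 0)
  expect_warning(r0 <- replicate_concordance(a, flat)$r, "zero variance")
  expect_true(is.nan(r0))

  # shared signal + independent noise: r -> var_s / (var_s + var_n)
  var_s <- 1; var_n <- 0.5
  target <- var_s / (var_s + var_n)
  rs <- vapply(1:10, function(seed) {
    set.seed(seed)
    s <- rnorm(5000, sd = sqrt(var_s))
    x <- tibble::tibble(probe_id = as.character(1:5000),
                        log2_ratio = s + rnorm(5000, sd = sqrt(var_n)))
    y <- tibble::tibble(probe_id = as.character(1:5000),
                        log2_ratio = s + rnorm(5000, sd = sqrt(var_n)))
    replicate_concordance(x, y)$r
  }, numeric(1))
  expect_true(all(abs(rs - target) <= 0.05))
})
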