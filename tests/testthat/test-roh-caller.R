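test_that("minimum-SNP formula reproduces hand-computed values and limits", {
  # ln(0.05 / 1e5) / ln(0.7) = 40.6775... -> 41 (hand arithmetic oracle)
  expect_equal(lencz_min_snps(0.05, 1000, 100, 0.3), 41L)
  # ln(0.05 / (50933 * 380)) / ln(0.65) = 45.90... -> 46
  expect_equal(lencz_min_snps(0.05, 50933, 380, 0.35), 46L)
  # het -> 1 drives the denominator to -Inf and the count to 1
  expect_equal(lencz_min_snps(0.05, 1000, 100, 1 - 1e-12), 1L)
  expect_error(lencz_min_snps(0.05, 1000, 100, 0), class = "rohscan_domain_error")
})

test_that("mean heterozygosity is the het share of non-missing calls", {
  expect_equal(mean_heterozygosity(make_panel(matrix(1L, 3, 4), "1", 1:4 * 100)), 1)
  g <- matrix(c(0L, 1L, NA, 2L), 2, 2)           # [0,NA; 1,2]
  expect_equal(mean_heterozygosity(make_panel(g, "1", c(100, 200))), 1 / 3)
  set.seed(3)
  for (k in 1:10) {
    g <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 5, 12)
    tally <- sum(g == 1, na.rm = TRUE) / sum(!is.na(g))
    expect_equal(
      mean_heterozygosity(make_panel(g, "1", (1:12) * 1000)), tally
    )
  }
})

test_that("an all-homozygous chromosome yields one segment spanning its SNPs", {
  m <- 60
  pos <- seq(1, 3e6, length.out = m)
  panel <- make_panel(matrix(0L, 1, m), "1", pos)
  params <- roh_params(window_snps = 50, min_snps_override = 20)
  seg <- detect_roh(panel, params)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, pos[1])
  expect_equal(seg$end_bp, pos[m])
  expect_equal(seg$n_snps, m)
})

test_that("an oversized gap splits a run into independently re-checked stretches", {
  pos <- c(seq(1e5, 2.0e6, by = 5e4), seq(3.3e6, 5.5e6, by = 5e4))
  m <- length(pos)
  panel <- make_panel(matrix(2L, 1, m), "1", pos)
  params <- roh_params(window_snps = 10, min_snps_override = 5,
                       max_gap_bp = 1e6, min_length_bp = 1e6)
  seg <- detect_roh(panel, params)
  expect_equal(nrow(seg), 2)
  expect_true(all(seg$end_bp[1] < 3.3e6, seg$start_bp[2] >= 3.3e6))
  # shrinking one stretch below the length floor drops just that stretch
  params2 <- roh_params(window_snps = 10, min_snps_override = 5,
                        max_gap_bp = 1e6, min_length_bp = 1.95e6)
  seg2 <- detect_roh(panel, params2)
  expect_equal(nrow(seg2), 1)
})

test_that("segment ends are trimmed to homozygous non-missing calls", {
  m <- 40
  pos <- (1:m) * 5e4
  g <- rep(0L, m)
  g[1] <- 1L; g[2] <- NA; g[m] <- NA
  panel <- make_panel(matrix(g, 1), "1", pos)
  seg <- detect_roh(panel, roh_params(window_snps = 10, min_snps_override = 5))
  expect_equal(seg$start_bp, pos[3])
  expect_equal(seg$end_bp, pos[m - 1])
})

test_that("detector equals the exhaustive-interval oracle on random panels", {
  params <- roh_params(window_snps = 10, min_snps_override = 8,
                       min_length_bp = 5e5)
  for (seed in 1:40) {
    panel <- random_small_panel(seed)
    got <- detect_roh(panel, params)
    want <- oracle_detect_roh(panel, params, 8)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE, info = paste("seed", seed))
  }
})

test_that("stricter length or count thresholds only ever drop segments", {
  panel <- random_small_panel(101)
  base <- roh_params(window_snps = 10, min_snps_override = 5, min_length_bp = 4e5)
  seg0 <- detect_roh(panel, base)
  for (p2 in list(
    roh_params(window_snps = 10, min_snps_override = 5, min_length_bp = 8e5),
    roh_params(window_snps = 10, min_snps_override = 12, min_length_bp = 4e5)
  )) {
    seg1 <- detect_roh(panel, p2)
    key0 <- paste(seg0$individual_id, seg0$chromosome, seg0$start_bp, seg0$end_bp)
    key1 <- paste(seg1$individual_id, seg1$chromosome, seg1$start_bp, seg1$end_bp)
    expect_true(all(key1 %in% key0))
  }
})

test_that("detection is deterministic and every segment passes the validator", {
  sim <- simulate_panel(sim_config(
    n_individuals = 15, chromosomes = sim_chromosomes(2, 4e7, 3e7),
    f_target = 0.08, tract_length_range_bp = c(2e6, 8e6),
    genotype_error_rate = 0.002, missing_rate = 0.01, seed = 77
  ))
  params <- roh_params()
  seg1 <- detect_roh(sim$panel, params)
  seg2 <- detect_roh(sim$panel, params)
  expect_identical(seg1, seg2)
  expect_true(validate_segments(seg1, sim$panel, params))
  expect_gt(nrow(seg1), 0)
})

test_that("planted tracts are recovered with boundary error within one spacing", {
  sim <- simulate_panel(sim_config(
    n_individuals = 5, chromosomes = sim_chromosomes(2, 5e7, 4e7),
    f_target = 0.10, tract_length_range_bp = c(4e6, 8e6), seed = 31
  ))
  seg <- detect_roh(sim$panel, roh_params())
  tr <- sim$truth$tracts
  for (k in seq_len(nrow(tr))) {
    hit <- seg[seg$individual_id == tr$individual_id[k] &
                 seg$chromosome == tr$chromosome[k] &
                 seg$end_bp >= tr$start_bp[k] & seg$start_bp <= tr$end_bp[k], ]
    expect_gte(nrow(hit), 1)
    covered <- sum(pmin(hit$end_bp, tr$end_bp[k]) -
                     pmax(hit$start_bp, tr$start_bp[k]) + 1)
    expect_gt(covered / (tr$end_bp[k] - tr$start_bp[k] + 1), 0.85)
  }
})

test_that("length classes follow the published half-open boundaries", {
  seg <- tibble::tibble(length_bp = c(3, 7, 12, 25) * 1e6)
  cs <- classify_roh(seg)
  expect_equal(cs$n_segments[cs$class != "all"], rep(1L, 4))
  expect_equal(cs$pct_of_number[cs$class != "all"], rep(25, 4))
  # boundary convention: a 5.0 Mb segment is 5-10 Mb
  expect_equal(as.character(roh_length_class(5e6)), "5-10")
  expect_equal(as.character(roh_length_class(4999999)), "1-5")
  # percentage columns sum to 100 over the four classes
  expect_equal(sum(cs$pct_of_number[cs$class != "all"]), 100)
  expect_equal(sum(cs$pct_of_length[cs$class != "all"]), 100)
})

test_that("chromosome coverage averages per-individual coverage", {
  lens <- tibble::tibble(chromosome = c("1", "2"), length_bp = c(1e8, 5e7))
  seg <- tibble::tibble(
    individual_id = c("a", "b"), chromosome = "1",
    start_bp = 1, end_bp = c(1e7, 3e7), n_snps = 100L,
    length_bp = c(1e7, 3e7)
  )
  cs <- chromosome_summary(seg, lens, n_individuals = 2)
  expect_equal(cs$coverage_pct[cs$chromosome == "1"], 20)
  expect_equal(cs$coverage_pct[cs$chromosome == "2"], 0)
  expect_equal(cs$n_segments[cs$chromosome == "2"], 0L)
  one <- chromosome_summary(seg[1, ], lens, n_individuals = 1)
  expect_equal(one$coverage_pct[one$chromosome == "1"], 10)
  expect_error(
    chromosome_summary(dplyr::mutate(seg, chromosome = "9"), lens, 2),
    class = "rohscan_lookup_error"
  )
})
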