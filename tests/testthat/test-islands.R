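test_that("per-SNP incidence counts individuals inside covering segments", {
  panel <- make_panel(matrix(0L, 1, 2), "1", c(150, 250))
  seg <- tibble::tibble(
    individual_id = "i01", chromosome = "1", start_bp = 100, end_bp = 200,
    n_snps = 2L, length_bp = 101
  )
  inc <- snp_roh_incidence(seg, panel)
  expect_equal(inc$fraction_in_roh, c(1, 0))
  expect_equal(inc$n_in_roh, c(1L, 0L))

  # overlapping segments of one individual count once
  seg2 <- dplyr::bind_rows(seg, dplyr::mutate(seg, start_bp = 120, end_bp = 180))
  inc2 <- snp_roh_incidence(seg2, panel)
  expect_equal(inc2$n_in_roh, c(1L, 0L))

  expect_error(
    snp_roh_incidence(dplyr::mutate(seg, chromosome = "5"), panel),
    class = "rohscan_validation_error"
  )
})

test_that("incidence equals a brute-force per-(individual, SNP) interval test", {
  set.seed(23)
  for (k in 1:10) {
    panel <- random_small_panel(k + 500, max_snps = 80, max_ind = 4)
    seg <- detect_roh(panel, roh_params(window_snps = 10, min_snps_override = 6,
                                        min_length_bp = 3e5))
    inc <- snp_roh_incidence(seg, panel)
    brute <- sapply(seq_len(n_snps(panel)), function(j) {
      pos <- panel$snps$position_bp[j]
      chrom <- panel$snps$chromosome[j]
      sum(vapply(panel$individuals$individual_id, function(id) {
        s <- seg[seg$individual_id == id & seg$chromosome == chrom, ]
        any(s$start_bp <= pos & pos <= s$end_bp)
      }, logical(1)))
    })
    expect_equal(inc$n_in_roh, as.integer(brute))
    # ordering invariance of the segment list
    inc_shuf <- snp_roh_incidence(seg[sample(nrow(seg)), ], panel)
    expect_equal(inc_shuf$fraction_in_roh, inc$fraction_in_roh)
  }
})

test_that("island threshold takes the top-percentile count with ties included", {
  inc <- tibble::tibble(
    snp_id = sprintf("s%03d", 1:100), chromosome = "1",
    position_bp = (1:100) * 1e5, n_in_roh = 0L,
    fraction_in_roh = (1:100) / 100
  )
  thr <- island_threshold(inc, 0.01)
  expect_equal(thr, 1)                                 # single largest value
  expect_equal(sum(inc$fraction_in_roh >= thr), 1)

  # tie at the cutoff: all tied SNPs become candidates
  inc2 <- inc
  inc2$fraction_in_roh[95:100] <- 0.95   # six-way tie at the very top
  thr2 <- island_threshold(inc2, 0.01)
  expect_equal(thr2, 0.95)
  expect_equal(sum(inc2$fraction_in_roh >= thr2), 6)

  inc0 <- dplyr::mutate(inc, fraction_in_roh = 0)
  expect_warning(thr0 <- island_threshold(inc0, 0.01), "degenerate")
  expect_equal(thr0, 0)
})

test_that("islands are maximal candidate runs with singletons dropped", {
  inc <- tibble::tibble(
    snp_id = sprintf("s%d", 1:4), chromosome = "1",
    position_bp = c(100, 200, 300, 400), n_in_roh = 0L,
    fraction_in_roh = c(0.9, 0.9, 0.1, 0.9)
  )
  isl <- detect_islands(inc, threshold = 0.5)
  expect_equal(nrow(isl), 1)                           # trailing singleton dropped
  expect_equal(isl$start_bp, 100)
  expect_equal(isl$end_bp, 200)
  expect_equal(isl$n_snps, 2L)
  expect_equal(isl$length_bp, 101)

  none <- detect_islands(dplyr::mutate(inc, fraction_in_roh = 0), threshold = 0.5)
  expect_equal(nrow(none), 0)
})

test_that("stricter top-fractions only shrink islands within looser ones", {
  set.seed(71)
  sim <- simulate_panel(sim_config(
    n_individuals = 30, chromosomes = sim_chromosomes(2, 4e7, 3e7),
    f_target = 0.10, tract_length_range_bp = c(3e6, 8e6), seed = 19
  ))
  seg <- detect_roh(sim$panel, roh_params())
  inc <- snp_roh_incidence(seg, sim$panel)
  loose <- detect_islands(inc, island_threshold(inc, 0.05))
  strict <- detect_islands(inc, island_threshold(inc, 0.01))
  for (k in seq_len(nrow(strict))) {
    within <- loose$chromosome == strict$chromosome[k] &
      loose$start_bp <= strict$start_bp[k] & loose$end_bp >= strict$end_bp[k]
    expect_true(any(within))
  }
})

test_that("gene annotation uses closed-interval 1 bp overlap", {
  isl <- tibble::tibble(
    chromosome = "1", start_bp = 100, end_bp = 200, length_bp = 101,
    n_snps = 5L, genes = list(character()), n_genes = 0L
  )
  genes <- tibble::tibble(
    chromosome = c("1", "1", "1", "2"),
    start_bp = c(50, 201, 200, 100), end_bp = c(150, 300, 250, 200),
    gene_id = c("OVL", "ADJ", "EDGE", "OTHER")
  )
  ann <- annotate_islands(isl, genes)
  expect_setequal(ann$genes[[1]], c("OVL", "EDGE"))    # [201,300] misses [100,200]
  expect_equal(ann$n_genes, 2L)

  # island with no overlapping genes keeps an explicit zero
  far <- dplyr::mutate(isl, start_bp = 1e6, end_bp = 2e6)
  ann2 <- annotate_islands(far, genes)
  expect_equal(ann2$n_genes, 0L)
  expect_equal(ann2$genes[[1]], character())

  expect_error(
    annotate_islands(isl, dplyr::mutate(genes, chromosome = paste0("chr", chromosome))),
    class = "rohscan_validation_error"
  )
})

test_that("GFF3 and BED gene models load into the annotation schema", {
  dir <- withr::local_tempdir()
  gff <- c(
    "##gff-version 3",
    "1\ttest\tgene\t500\t1500\t.\t+\t.\tID=gene1;Name=ABC1",
    "1\ttest\tmRNA\t500\t1500\t.\t+\t.\tID=rna1;Parent=gene1",
    "2\ttest\tgene\t100\t900\t.\t-\t.\tID=gene2"
  )
  writeLines(gff, file.path(dir, "g.gff3"))
  gm <- read_gene_models(file.path(dir, "g.gff3"))
  expect_equal(nrow(gm), 2)                            # mRNA filtered out
  expect_setequal(gm$gene_id, c("ABC1", "gene2"))
  expect_equal(gm$start_bp[gm$chromosome == "1"], 500)

  writeLines(c("1\t499\t1500\tABC1", "2\t99\t900\tDEF2"),
             file.path(dir, "g.bed"))
  gb <- read_gene_models(file.path(dir, "g.bed"))
  expect_equal(gb$start_bp, c(500, 100))               # 0-based -> 1-based
  expect_equal(gb$end_bp, c(1500, 900))
})
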