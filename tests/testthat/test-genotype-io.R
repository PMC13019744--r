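test_that("PED/MAP round-trips through the documented genotype encoding", {
  dir <- withr::local_tempdir()
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200", "1\ts3\t0\t300"),
             file.path(dir, "toy.map"))
  writeLines(c(
    "f1 id1 0 0 1 -9 A A A G 0 0",
    "f2 id2 0 0 2 -9 A A G G C C"
  ), file.path(dir, "toy.ped"))
  panel <- read_ped_map(file.path(dir, "toy.ped"), file.path(dir, "toy.map"))
  expect_equal(n_individuals(panel), 2)
  expect_equal(unname(panel$geno[1, ]), c(0L, 1L, NA))
  expect_equal(unname(panel$geno[2, ]), c(0L, 2L, 0L))
  expect_equal(panel$individuals$individual_id, c("id1", "id2"))

  # write -> read preserves the codes matrix exactly
  write_ped_map(panel, file.path(dir, "rt"))
  back <- read_ped_map(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_equal(unname(back$geno), unname(panel$geno))
})

test_that("MAP positions out of order are re-sorted with calls permuted to match", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tsB\t0\t100", "1\tsA\t0\t50"), file.path(dir, "o.map"))
  writeLines("f1 id1 0 0 0 -9 A G C C", file.path(dir, "o.ped"))
  panel <- read_ped_map(file.path(dir, "o.ped"), file.path(dir, "o.map"))
  expect_equal(panel$snps$snp_id, c("sA", "sB"))
  expect_equal(panel$snps$position_bp, c(50, 100))
  expect_equal(unname(panel$geno[1, ]), c(0L, 1L))  # sA was the second pair
})

test_that("malformed PED rows and duplicate SNP ids are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200", "1\ts3\t0\t300"),
             file.path(dir, "m.map"))
  writeLines("f1 id1 0 0 1 -9 A A G G C C A", file.path(dir, "m.ped"))
  expect_error(read_ped_map(file.path(dir, "m.ped"), file.path(dir, "m.map")),
               class = "rohscan_format_error", regexp = "row 1")
  writeLines(c("1\ts1\t0\t100", "1\ts1\t0\t200"), file.path(dir, "d.map"))
  writeLines("f1 id1 0 0 1 -9 A A G G", file.path(dir, "d.ped"))
  expect_error(read_ped_map(file.path(dir, "d.ped"), file.path(dir, "d.map")),
               class = "rohscan_validation_error")
})

test_that("PLINK binary filesets round-trip losslessly and share PED semantics", {
  dir <- withr::local_tempdir()
  set.seed(42)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 5 * 20, replace = TRUE), 5, 20)
  panel <- make_panel(g, "2", sort(sample(1:1e6, 20)))
  write_bed_bim_fam(panel, file.path(dir, "rt"))
  back <- read_bed_bim_fam(file.path(dir, "rt"))
  expect_equal(unname(back$geno), unname(panel$geno))
  expect_equal(back$snps$position_bp, panel$snps$position_bp)

  # same panel through PED/MAP and BED/BIM/FAM agrees genotype-state-wise;
  # PED allele labels follow the first-seen rule, so hom codes may swap
  # 0 <-> 2 per SNP while het/missing are format-invariant
  write_ped_map(panel, file.path(dir, "pm"))
  via_ped <- read_ped_map(file.path(dir, "pm.ped"), file.path(dir, "pm.map"))
  state <- function(g) ifelse(is.na(g), -1L, ifelse(g == 1L, 1L, 0L))
  expect_equal(state(unname(via_ped$geno)), state(unname(back$geno)))
  for (j in seq_len(n_snps(panel))) {
    expect_true(all(via_ped$geno[, j] == back$geno[, j], na.rm = TRUE) ||
                  all(via_ped$geno[, j] == 2L - back$geno[, j], na.rm = TRUE))
  }

  # single packed genotype byte decodes to a het
  one <- make_panel(matrix(1L, 1, 1), "1", 500)
  write_bed_bim_fam(one, file.path(dir, "one"))
  expect_equal(unname(read_bed_bim_fam(file.path(dir, "one"))$geno[1, 1]), 1L)
})

test_that("a .bed file with wrong magic bytes is refused", {
  dir <- withr::local_tempdir()
  panel <- make_panel(matrix(0L, 1, 2), "1", c(10, 20))
  write_bed_bim_fam(panel, file.path(dir, "bad"))
  raw <- readBin(file.path(dir, "bad.bed"), "raw", 100)
  raw[1] <- as.raw(0xff)
  writeBin(raw, file.path(dir, "bad.bed"))
  expect_error(read_bed_bim_fam(file.path(dir, "bad")),
               class = "rohscan_format_error", regexp = "magic")
})

test_that("VCF genotypes map to the internal codes and multiallelics are skipped", {
  dir <- withr::local_tempdir()
  vcf <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampleA\tsampleB",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1/1",
    "1\t200\tv2\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0",
    "1\t300\tv3\tT\tC\t.\tPASS\t.\tGT\t./.\t0/0"
  )
  writeLines(vcf, file.path(dir, "t.vcf"))
  panel <- read_vcf(file.path(dir, "t.vcf"))
  expect_equal(n_snps(panel), 2)                      # multiallelic skipped
  expect_equal(attr(panel, "skipped_records"), 1)
  expect_equal(unname(panel$geno[, 1]), c(1L, 2L))    # 0|1 het, 1/1 hom ALT
  expect_equal(unname(panel$geno[, 2]), c(NA_integer_, 0L))
})

test_that("report writer emits fixed-schema TSVs, including degenerate inputs", {
  dir <- withr::local_tempdir()
  empty <- tibble::tibble(
    individual_id = character(), chromosome = character(), start_bp = double(),
    end_bp = double(), n_snps = integer(), length_bp = double()
  )
  write_reports(list(segments = empty), dir)
  lines <- readLines(file.path(dir, "roh_segments.tsv"))
  expect_length(lines, 1)                             # header only
  expect_match(lines, "individual_id\tchromosome\tstart_bp")

  one <- tibble::tibble(
    individual_id = "id1", chromosome = "3", start_bp = 1e6, end_bp = 3.5e6 - 1,
    n_snps = 60L, length_bp = 2.5e6
  )
  write_reports(list(segments = one), dir)
  row <- read.table(file.path(dir, "roh_segments.tsv"), header = TRUE, sep = "\t")
  expect_equal(row$length_mb, 2.5)
  expect_equal(row$n_snps, 60)

  # an island without genes reports a zero count, and the BED is half-open
  isl <- tibble::tibble(
    chromosome = "7", start_bp = 5267872, end_bp = 7767750,
    length_bp = 7767750 - 5267872 + 1, n_snps = 75L,
    genes = list(character()), n_genes = 0L
  )
  write_reports(list(islands = isl), dir)
  tab <- read.table(file.path(dir, "islands.tsv"), header = TRUE, sep = "\t")
  expect_equal(tab$n_genes, 0)
  bed <- read.table(file.path(dir, "islands.bed"), sep = "\t")
  expect_equal(bed$V2, 5267871)                       # 0-based start
  expect_equal(bed$V3, 7767750)
})
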