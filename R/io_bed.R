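#' Read a PLINK binary fileset (BED/BIM/FAM, SNP-major)
#'
#' A1 in the BIM becomes allele A, A2 allele B. The packed 2-bit codes of
#' the SNP-major .bed layout are decoded as 00 = hom A1, 01 = missing,
#' 10 = het, 11 = hom A2.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_panel].
#' @export
read_bed_bim_fam <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste("missing file(s):", paste(missing, collapse = ", ")),
          class = "rohscan_io_error")
  }
  bim <- read.table(paths[2], header = FALSE, colClasses = "character")
  fam <- read.table(paths[3], header = FALSE, colClasses = "character")
  snps <- tibble(
    snp_id = bim[[2]], chromosome = bim[[1]],
    position_bp = as.double(bim[[4]]),
    allele_a = bim[[5]], allele_b = bim[[6]]
  )
  individuals <- tibble(
    individual_id = fam[[2]],
    sex = suppressWarnings(as.integer(fam[[5]]))
  )
  n <- nrow(individuals); m <- nrow(snps)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK .bed file (bad magic bytes)", class = "rohscan_format_error")
  }
  if (raw[3] != as.raw(0x01)) {
    abort(".bed file is not in SNP-major mode", class = "rohscan_format_error")
  }
  bps <- ceiling(n / 4)                      # bytes per SNP block
  if (length(raw) - 3L != bps * m) {
    abort(sprintf(".bed payload is %d bytes, expected %d (n=%d, m=%d)",
                  length(raw) - 3L, bps * m, n, m),
          class = "rohscan_format_error")
  }
  body <- raw[-(1:3)]
  # 2-bit fields, individual 1 in the lowest-order pair of each byte
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  two_bit <- bits[seq(1, 8, 2), , drop = FALSE] + 2L * bits[seq(2, 8, 2), , drop = FALSE]
  codes <- matrix(as.vector(two_bit), nrow = 4 * bps)[seq_len(n), , drop = FALSE]
  lookup <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
  geno <- matrix(lookup[codes + 1L], n, m)
  genotype_panel(geno, snps, individuals)
}

#' Write a panel as a PLINK binary fileset (SNP-major)
#'
#' @param panel A [genotype_panel].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_bed_bim_fam <- function(panel, prefix) {
  stop_if_not_panel(panel)
  snps <- panel$snps
  bim <- data.frame(snps$chromosome, snps$snp_id, 0,
                    format(snps$position_bp, scientific = FALSE, trim = TRUE),
                    snps$allele_a, snps$allele_b)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$individuals$individual_id,
                    panel$individuals$individual_id, 0, 0,
                    panel$individuals$sex, -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  g <- panel$geno
  n <- nrow(g); m <- ncol(g)
  enc <- matrix(1L, n, m)                    # 01 = missing
  enc[!is.na(g) & g == 0L] <- 0L
  enc[!is.na(g) & g == 1L] <- 2L
  enc[!is.na(g) & g == 2L] <- 3L
  bps <- ceiling(n / 4)
  padded <- matrix(0L, 4 * bps, m)
  padded[seq_len(n), ] <- enc
  bitvec <- integer(8 * bps * m)
  bitvec[seq(1, length(bitvec), 2)] <- as.vector(padded %% 2L)
  bitvec[seq(2, length(bitvec), 2)] <- as.vector(padded %/% 2L)
  body <- packBits(as.raw(bitvec), type = "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(body, con)
  invisible(prefix)
}
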