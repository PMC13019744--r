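#' Read a PLINK PED/MAP text file pair
#'
#' Each PED row carries six metadata columns (family, individual, father,
#' mother, sex, phenotype) followed by two allele columns per MAP row; a
#' `"0 0"` allele pair is a missing call. Allele A of each SNP is the first
#' non-missing allele encountered down the PED column (hom/het state, the
#' only thing downstream statistics use, does not depend on this labelling).
#'
#' @param ped_path,map_path Paths to the .ped and .map files.
#' @return A [genotype_panel].
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 4) abort("MAP file needs 4 columns", class = "rohscan_format_error")
  snps <- tibble(
    snp_id = map[[2]], chromosome = map[[1]],
    position_bp = as.double(map[[4]]),
    allele_a = NA_character_, allele_b = NA_character_
  )
  if (anyDuplicated(snps$snp_id)) {
    abort("duplicate snp_id in MAP file", class = "rohscan_validation_error")
  }
  m <- nrow(snps)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  nf <- lengths(fields)
  if (any(nf != want)) {
    bad <- which(nf != want)[1]
    abort(sprintf(
      "PED row %d has %d fields, expected %d (6 metadata + 2 x %d alleles)",
      bad, nf[bad], want, m
    ), class = "rohscan_format_error")
  }
  ped <- do.call(rbind, fields)
  individuals <- tibble(
    individual_id = ped[, 2],
    sex = suppressWarnings(as.integer(ped[, 5]))
  )
  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  geno <- matrix(NA_integer_, nrow(ped), m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- c(rbind(a1[, j], a2[, j]))          # alleles in PED order
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) > 2) {
      abort(sprintf("SNP %s has >2 alleles in PED", snps$snp_id[j]),
            class = "rohscan_format_error")
    }
    aa <- if (length(seen) >= 1) seen[1] else "0"
    ab <- if (length(seen) >= 2) seen[2] else "0"
    allele_a[j] <- aa; allele_b[j] <- ab
    g <- (a1[, j] != aa) + (a2[, j] != aa)     # counts of allele B
    g[is.na(a1[, j]) | is.na(a2[, j])] <- NA
    geno[, j] <- as.integer(g)
  }
  snps$allele_a <- allele_a
  snps$allele_b <- allele_b
  genotype_panel(geno, snps, individuals)
}

#' Write a panel as PLINK PED/MAP
#'
#' @param panel A [genotype_panel].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(panel, prefix) {
  stop_if_not_panel(panel)
  snps <- panel$snps
  map <- data.frame(snps$chromosome, snps$snp_id, 0,
                    format(snps$position_bp, scientific = FALSE, trim = TRUE))
  write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  g <- panel$geno
  n <- nrow(g); m <- ncol(g)
  aa <- matrix(rep(snps$allele_a, each = n), n, m)
  ab <- matrix(rep(snps$allele_b, each = n), n, m)
  h1 <- ifelse(is.na(g), "0", ifelse(g == 2L, ab, aa))
  h2 <- ifelse(is.na(g), "0", ifelse(g == 0L, aa, ab))
  body <- matrix("", n, 2L * m)
  body[, seq_len(m) * 2L - 1L] <- h1
  body[, seq_len(m) * 2L] <- h2
  meta <- cbind(panel$individuals$individual_id, panel$individuals$individual_id,
                "0", "0", as.character(panel$individuals$sex %||% 0L), "-9")
  writeLines(apply(cbind(meta, body), 1, paste, collapse = " "),
             paste0(prefix, ".ped"))
  invisible(prefix)
}
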