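#' Read genotypes from a VCF file
#'
#' Keeps biallelic records only (multiallelic ALT fields are skipped and
#' counted); GT values `0/0` map to hom-REF, `0/1`/`1/0` to het, `1/1` to
#' hom-ALT and `./.` to missing. The phasing separator is ignored.
#'
#' @param vcf_path Path to a VCF (plain or bgzipped).
#' @return A [genotype_panel]; the number of skipped non-biallelic records
#'   is attached as attribute `skipped_records`.
#' @export
read_vcf <- function(vcf_path) {
  stopifnot(file.exists(vcf_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fmt <- vcf@gt[, 1]
  if (nrow(vcf@gt) == 0 || !all(vapply(strsplit(fmt, ":"), function(k) "GT" %in% k, logical(1)))) {
    abort("VCF has no GT field", class = "rohscan_format_error")
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & !is.na(fix$ALT) & fix$ALT != "."
  n_skip <- sum(!biallelic)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  ids <- fix$ID
  auto_id <- is.na(ids) | ids == "."
  ids[auto_id] <- paste0(fix$CHROM[auto_id], ":", fix$POS[auto_id])
  snps <- tibble(
    snp_id = ids, chromosome = fix$CHROM,
    position_bp = as.double(fix$POS),
    allele_a = fix$REF, allele_b = fix$ALT
  )
  panel <- genotype_panel(t(code), snps, colnames(gt))
  attr(panel, "skipped_records") <- n_skip
  panel
}
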