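#' Genotype codes used throughout rohscan
#'
#' Genotypes are stored as an integer matrix (individuals x SNPs) with
#' `0` = homozygous for allele A, `1` = heterozygous, `2` = homozygous for
#' allele B and `NA` = missing call. Allele A/B identity is format-specific
#' (first-seen allele for PED input, A1/A2 for BIM, REF/ALT for VCF); all
#' downstream statistics depend only on the hom/het/missing state.
#'
#' @format Named integer vector with entries `hom_a`, `het`, `hom_b`.
#' @export
geno_codes <- c(hom_a = 0L, het = 1L, hom_b = 2L)

#' Construct a genotype panel
#'
#' The central container: an ordered individual table, an ordered SNP map and
#' a genotype-call matrix. SNPs are sorted by (chromosome, position) with
#' ties broken by SNP identifier; chromosome blocks are contiguous, numeric
#' labels ordered numerically before any non-numeric labels.
#'
#' @param geno Integer matrix, individuals x SNPs, values in \{0, 1, 2, NA\}
#'   (see [geno_codes]).
#' @param snps Data frame with columns `snp_id`, `chromosome`, `position_bp`
#'   and optionally `allele_a`, `allele_b`.
#' @param individuals Data frame with column `individual_id` and optionally
#'   `sex` (0 = unknown, 1 = male, 2 = female), or a character vector of ids.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, snps, individuals) {
  if (is.character(individuals)) {
    individuals <- tibble(individual_id = individuals)
  }
  individuals <- as_tibble(individuals)
  if (!"sex" %in% names(individuals)) individuals$sex <- 0L
  snps <- as_tibble(snps)
  stopifnot(
    all(c("snp_id", "chromosome", "position_bp") %in% names(snps)),
    "individual_id" %in% names(individuals)
  )
  if (!"allele_a" %in% names(snps)) snps$allele_a <- "A"
  if (!"allele_b" %in% names(snps)) snps$allele_b <- "B"
  snps$chromosome <- as.character(snps$chromosome)
  snps$position_bp <- as.double(snps$position_bp)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(individuals) || ncol(geno) != nrow(snps)) {
    abort(sprintf(
      "genotype matrix is %d x %d but panel has %d individuals and %d SNPs",
      nrow(geno), ncol(geno), nrow(individuals), nrow(snps)
    ), class = "rohscan_dim_error")
  }
  bad <- !(geno %in% c(0L, 1L, 2L)) & !is.na(geno)
  if (any(bad)) {
    abort("genotype codes must be 0, 1, 2 or NA", class = "rohscan_code_error")
  }
  if (anyDuplicated(snps$snp_id)) {
    dup <- unique(snps$snp_id[duplicated(snps$snp_id)])
    abort(paste0("duplicate snp_id: ", paste(head(dup, 5), collapse = ", ")),
          class = "rohscan_validation_error")
  }
  if (anyDuplicated(individuals$individual_id)) {
    abort("duplicate individual_id", class = "rohscan_validation_error")
  }
  ord <- order(chrom_rank(snps$chromosome), snps$position_bp, snps$snp_id)
  snps <- snps[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  dimnames(geno) <- list(individuals$individual_id, snps$snp_id)
  structure(
    list(individuals = individuals, snps = snps, geno = geno),
    class = "genotype_panel"
  )
}

# Deterministic chromosome ordering: numeric labels numerically, then
# X, Y, MT, then anything else alphabetically.
chrom_rank <- function(labels) {
  u <- unique(labels)
  num <- suppressWarnings(as.numeric(u))
  special <- match(toupper(u), c("X", "Y", "XY", "MT", "M"))
  key <- ifelse(!is.na(num), sprintf("0%015.2f", num),
         ifelse(!is.na(special), sprintf("1%02d", special), paste0("2", u)))
  match(labels, u[order(key)])
}

#' Print a short description of a genotype panel
#'
#' @param x A [genotype_panel].
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d individuals x %d SNPs on %d chromosome(s)\n",
    n_individuals(x), n_snps(x), length(unique(x$snps$chromosome))
  ))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing call rate %.4f\n", miss))
  invisible(x)
}

#' Panel dimensions
#' @param panel A [genotype_panel].
#' @return Integer count.
#' @export
n_individuals <- function(panel) nrow(panel$individuals)

#' @rdname n_individuals
#' @export
n_snps <- function(panel) nrow(panel$snps)

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel].
#' @param keep_individuals,keep_snps Logical or integer index vectors; `NULL`
#'   keeps everything.
#' @return A [genotype_panel].
#' @export
subset_panel <- function(panel, keep_individuals = NULL, keep_snps = NULL) {
  ind <- panel$individuals
  snps <- panel$snps
  geno <- panel$geno
  if (!is.null(keep_individuals)) {
    ind <- ind[keep_individuals, , drop = FALSE]
    geno <- geno[keep_individuals, , drop = FALSE]
  }
  if (!is.null(keep_snps)) {
    snps <- snps[keep_snps, , drop = FALSE]
    geno <- geno[, keep_snps, drop = FALSE]
  }
  genotype_panel(geno, snps, ind)
}

stop_if_not_panel <- function(panel) {
  if (!inherits(panel, "genotype_panel")) {
    abort("expected a genotype_panel object", class = "rohscan_type_error")
  }
  invisible(panel)
}
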