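#' QC thresholds for a SNP-array panel
#'
#' Defaults mirror routine medium-density array QC: SNPs are removed at
#' call rate < 0.90, minor allele frequency < 0.05 or Hardy-Weinberg exact
#' p < 1e-6; individuals at missing rate > 0.10. Non-autosomal and unplaced
#' markers (chromosome "0"/unknown or position 0) are always removed first.
#'
#' @param min_snp_call_rate Minimum per-SNP call rate (strict `<` removes).
#' @param min_maf Minimum minor allele frequency (strict `<` removes).
#' @param hwe_p_floor Hardy-Weinberg exact-test p-value floor (strict `<`
#'   removes).
#' @param max_individual_missing Maximum per-individual missing-call
#'   fraction (strict `>` removes).
#' @param autosomes Chromosome labels treated as autosomal; default `1:29`
#'   (goat).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_snp_call_rate = 0.90, min_maf = 0.05,
                          hwe_p_floor = 1e-6, max_individual_missing = 0.10,
                          autosomes = as.character(1:29)) {
  stopifnot(
    min_snp_call_rate >= 0, min_snp_call_rate <= 1,
    min_maf >= 0, min_maf <= 1,
    hwe_p_floor >= 0, hwe_p_floor <= 1,
    max_individual_missing >= 0, max_individual_missing <= 1
  )
  structure(list(
    min_snp_call_rate = min_snp_call_rate, min_maf = min_maf,
    hwe_p_floor = hwe_p_floor, max_individual_missing = max_individual_missing,
    autosomes = as.character(autosomes)
  ), class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: conditioning on the observed allele counts, the
#' probability of every compatible heterozygote count is computed by the
#' stable ratio recurrence, and the two-sided p-value is the sum of
#' probabilities no larger than that of the observed configuration. The
#' chi-square approximation is avoided because array QC thresholds sit in
#' its far tail.
#'
#' @param n_hom_a,n_het,n_hom_b Genotype counts (each a scalar or a vector;
#'   vectors are recycled element-wise).
#' @param full If `TRUE` (scalar input only), also return the enumerated
#'   heterozygote-count distribution.
#' @return p-value(s) in (0, 1]; with `full = TRUE` a list with elements
#'   `p_value`, `het`, `prob`.
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b, full = FALSE) {
  if (length(n_hom_a) > 1 || length(n_het) > 1 || length(n_hom_b) > 1) {
    return(mapply(hwe_exact_test, n_hom_a, n_het, n_hom_b))
  }
  stopifnot(n_hom_a >= 0, n_het >= 0, n_hom_b >= 0)
  n <- n_hom_a + n_het + n_hom_b
  if (n < 1) {
    abort("all genotype counts are zero", class = "rohscan_input_error")
  }
  n_a <- 2 * n_hom_a + n_het
  n_b <- 2 * n_hom_b + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) {                           # monomorphic: one configuration
    out <- list(p_value = 1, het = 0L, prob = 1)
    return(if (full) out else out$p_value)
  }
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- numeric(length(hets))
  prob[1] <- 1
  # unnormalised recurrence in het count h (common allele count fixed):
  # P(h + 2) / P(h) = 4 * hom_rare(h) * hom_common(h) / ((h + 1) * (h + 2))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    prob[k] <- prob[k - 1] * 4 * ((rare - h) / 2) * ((2 * n - rare - h) / 2) /
      ((h + 1) * (h + 2))
  }
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  p <- min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
  if (full) list(p_value = p, het = hets, prob = prob) else p
}

snp_genotype_counts <- function(panel) {
  g <- panel$geno
  tibble(
    snp_id = panel$snps$snp_id,
    n_hom_a = colSums(g == 0L, na.rm = TRUE),
    n_het = colSums(g == 1L, na.rm = TRUE),
    n_hom_b = colSums(g == 2L, na.rm = TRUE),
    n_missing = colSums(is.na(g))
  )
}

#' Per-SNP minor allele frequency
#'
#' Computed from non-missing calls only; always in \[0, 0.5\].
#'
#' @param panel A [genotype_panel].
#' @return Numeric vector, one value per SNP (`NaN` where every call is
#'   missing).
#' @export
snp_maf <- function(panel) {
  cc <- snp_genotype_counts(panel)
  n_called <- cc$n_hom_a + cc$n_het + cc$n_hom_b
  p_b <- (2 * cc$n_hom_b + cc$n_het) / (2 * n_called)
  pmin(p_b, 1 - p_b)
}

#' Apply SNP- and individual-level quality control
#'
#' Filters are applied in a fixed, documented order: (1) non-autosomal and
#' unplaced SNPs, (2) individuals over the missing-rate cap (missingness
#' measured on the remaining SNPs), (3) SNP call rate, (4) minor allele
#' frequency, (5) Hardy-Weinberg exact test. Frequency-dependent filters
#' therefore see the retained individual set. Boundary behaviour is strict
#' per threshold definition: remove if call rate < min, MAF < min, p < floor,
#' individual missingness > max.
#'
#' @param panel A [genotype_panel].
#' @param thresholds A [qc_thresholds] object.
#' @return A list with elements `panel` (filtered [genotype_panel]) and
#'   `report` (tibble: one row per filter step with SNPs/individuals
#'   removed, plus a `retained` row).
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stop_if_not_panel(panel)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (n_snps(panel) == 0 || n_individuals(panel) == 0) {
    abort("empty panel", class = "rohscan_input_error")
  }
  steps <- list()
  note <- function(step, snps_removed, ind_removed) {
    steps[[length(steps) + 1]] <<- tibble(
      step = step, snps_removed = snps_removed, individuals_removed = ind_removed
    )
  }

  keep_snp <- panel$snps$chromosome %in% thresholds$autosomes &
    panel$snps$position_bp >= 1
  note("non_autosomal_or_unplaced", sum(!keep_snp), 0L)
  panel <- subset_panel(panel, keep_snps = keep_snp)

  ind_miss <- rowMeans(is.na(panel$geno))
  keep_ind <- ind_miss <= thresholds$max_individual_missing
  note("individual_missing_rate", 0L, sum(!keep_ind))
  panel <- subset_panel(panel, keep_individuals = keep_ind)

  call_rate <- 1 - colMeans(is.na(panel$geno))
  keep_snp <- call_rate >= thresholds$min_snp_call_rate
  note("snp_call_rate", sum(!keep_snp), 0L)
  panel <- subset_panel(panel, keep_snps = keep_snp)

  maf <- snp_maf(panel)
  keep_snp <- !is.nan(maf) & maf >= thresholds$min_maf
  note("minor_allele_frequency", sum(!keep_snp), 0L)
  panel <- subset_panel(panel, keep_snps = keep_snp)

  cc <- snp_genotype_counts(panel)
  hwe_p <- hwe_exact_test(cc$n_hom_a, cc$n_het, cc$n_hom_b)
  keep_snp <- hwe_p >= thresholds$hwe_p_floor
  note("hwe_exact_test", sum(!keep_snp), 0L)
  panel <- subset_panel(panel, keep_snps = keep_snp)

  report <- bind_rows(steps)
  report <- bind_rows(report, tibble(
    step = "retained",
    snps_removed = n_snps(panel), individuals_removed = n_individuals(panel)
  ))
  names(report)[2:3] <- c("snps", "individuals")
  report$snps <- as.integer(report$snps)
  report$individuals <- as.integer(report$individuals)
  if (n_snps(panel) == 0 || n_individuals(panel) == 0) {
    abort("no SNPs or individuals survive QC", class = "rohscan_empty_result",
          body = c(i = "see attached report"), report = report)
  }
  list(panel = panel, report = report)
}
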