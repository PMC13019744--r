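#' Autosomal genome length covered by the array
#'
#' Sum over chromosomes of (last SNP position - first SNP position + 1):
#' the denominator L_auto of F_ROH. A chromosome holding a single SNP
#' contributes 1 bp (degenerate; a message is emitted).
#'
#' @param panel A post-QC, autosome-only [genotype_panel].
#' @return Length in bp.
#' @export
autosome_span <- function(panel) {
  stop_if_not_panel(panel)
  spans <- panel$snps |>
    group_by(.data$chromosome) |>
    summarise(span = max(.data$position_bp) - min(.data$position_bp) + 1,
              n = n(), .groups = "drop")
  if (any(spans$n == 1)) {
    inform(paste("chromosome(s) with a single SNP contribute 1 bp to L_auto:",
                 paste(spans$chromosome[spans$n == 1], collapse = ", ")))
  }
  sum(spans$span)
}

class_bounds <- function(class) {
  switch(class,
    "1-5" = c(1e6, 5e6), "5-10" = c(5e6, 10e6),
    "10-20" = c(10e6, 20e6), ">20" = c(20e6, Inf),
    abort(paste("unknown ROH length class:", class))
  )
}

#' Per-individual F_ROH
#'
#' F_ROH = (total ROH length in the individual) / L_auto, optionally
#' restricted to one length class (half-open Mb intervals \[1,5), \[5,10),
#' \[10,20), \[20,Inf)). Individuals without segments get 0.
#'
#' @param segments Segment tibble from [detect_roh].
#' @param l_auto_bp Autosomal span from [autosome_span].
#' @param individuals Character vector of individual ids defining the output
#'   rows (defaults to the ids present in `segments`).
#' @param class Optional length class: `"1-5"`, `"5-10"`, `"10-20"`, `">20"`.
#' @return Tibble with `individual_id`, `f_roh`.
#' @export
f_roh <- function(segments, l_auto_bp, individuals = NULL, class = NULL) {
  stopifnot(l_auto_bp > 0)
  if (nrow(segments) && any(segments$length_bp > l_auto_bp)) {
    abort("segment longer than the autosomal span",
          class = "rohscan_validation_error")
  }
  if (is.null(individuals)) individuals <- unique(segments$individual_id)
  seg <- segments
  if (!is.null(class)) {
    b <- class_bounds(class)
    seg <- filter(seg, .data$length_bp / 1 >= b[1], .data$length_bp < b[2])
  }
  sums <- seg |>
    group_by(.data$individual_id) |>
    summarise(total = sum(.data$length_bp), .groups = "drop")
  tibble(individual_id = individuals) |>
    left_join(sums, by = "individual_id") |>
    mutate(f_roh = dplyr::coalesce(.data$total, 0) / l_auto_bp) |>
    select("individual_id", "f_roh")
}

#' Per-individual excess-homozygosity F_HOM
#'
#' Method-of-moments coefficient F = (O_hom - E_hom) / (m - E_hom) over the
#' individual's non-missing SNPs, where O_hom is the observed homozygote
#' count, m the SNP count, and E_hom = sum_i (1 - 2 p_i q_i * N_i/(N_i - 1))
#' with p_i the sample allele frequency and N_i the non-missing allele
#' count at SNP i. The finite-sample factor N/(N-1) (on by default) matches
#' standard toolchain behaviour; negative values arise under heterozygote
#' excess relative to Hardy-Weinberg expectation.
#'
#' @param panel A post-QC [genotype_panel] with at least two individuals.
#' @param finite_sample_correction Apply the N/(N-1) factor to expected
#'   heterozygosity.
#' @return Tibble with `individual_id`, `f_hom`.
#' @export
f_hom <- function(panel, finite_sample_correction = TRUE) {
  stop_if_not_panel(panel)
  if (n_individuals(panel) < 2) {
    abort("F_HOM needs at least 2 individuals (sample allele frequencies)",
          class = "rohscan_input_error")
  }
  g <- panel$geno
  called <- !is.na(g)
  n_called <- colSums(called)
  p <- (2 * colSums(g == 2L, na.rm = TRUE) + colSums(g == 1L, na.rm = TRUE)) /
    (2 * n_called)
  exp_het <- 2 * p * (1 - p)
  if (finite_sample_correction) {
    n_alleles <- 2 * n_called
    exp_het <- exp_het * n_alleles / pmax(n_alleles - 1, 1)
  }
  exp_hom_snp <- 1 - exp_het
  o_hom <- rowSums((g == 0L | g == 2L) & called, na.rm = TRUE)
  e_hom <- as.vector(called %*% exp_hom_snp)
  m <- rowSums(called)
  denom <- m - e_hom
  if (any(abs(denom) < .Machine$double.eps * m)) {
    abort("expected homozygosity equals the SNP count (monomorphic-only set)",
          class = "rohscan_degenerate_error")
  }
  tibble(
    individual_id = panel$individuals$individual_id,
    f_hom = unname((o_hom - e_hom) / denom)
  )
}

#' Per-individual inbreeding profiles
#'
#' Combines F_HOM, overall F_ROH and the four class-specific F_ROH values
#' (shared denominator L_auto, so the class values sum exactly to F_ROH).
#'
#' @param panel A post-QC [genotype_panel].
#' @param segments Segment tibble from [detect_roh] on the same panel.
#' @param finite_sample_correction Passed to [f_hom].
#' @return Tibble: `individual_id`, `f_hom`, `f_roh`, `f_roh_1_5`,
#'   `f_roh_5_10`, `f_roh_10_20`, `f_roh_gt20`, `l_auto_bp`.
#' @export
inbreeding_profiles <- function(panel, segments,
                                finite_sample_correction = TRUE) {
  l_auto <- autosome_span(panel)
  ids <- panel$individuals$individual_id
  prof <- f_hom(panel, finite_sample_correction)
  prof$f_roh_1_5 <- f_roh(segments, l_auto, ids, "1-5")$f_roh
  prof$f_roh_5_10 <- f_roh(segments, l_auto, ids, "5-10")$f_roh
  prof$f_roh_10_20 <- f_roh(segments, l_auto, ids, "10-20")$f_roh
  prof$f_roh_gt20 <- f_roh(segments, l_auto, ids, ">20")$f_roh
  # the classes partition the segments, so the overall coefficient is the
  # component sum; summing the components makes the identity hold bitwise
  prof$f_roh <- prof$f_roh_1_5 + prof$f_roh_5_10 + prof$f_roh_10_20 +
    prof$f_roh_gt20
  prof$l_auto_bp <- l_auto
  prof[, c("individual_id", "f_hom", "f_roh", "f_roh_1_5", "f_roh_5_10",
           "f_roh_10_20", "f_roh_gt20", "l_auto_bp")]
}

#' Pearson correlation with a two-sided t-test
#'
#' r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum sq * sum sq); the
#' p-value comes from t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom, two-sided.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @param names Optional pair of variable names for the output.
#' @return One-row tibble: `var_x`, `var_y`, `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y, names = c("x", "y")) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs", class = "rohscan_input_error")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    abort("correlation undefined for a constant vector",
          class = "rohscan_degenerate_error")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) {
    .Machine$double.xmin                     # degenerate perfect fit
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t_stat), df = n - 2)
  }
  tibble(var_x = names[1], var_y = names[2], r = r, p_value = p, n = n)
}

#' All pairwise correlations among inbreeding coefficients
#'
#' The 15 pairs among F_HOM, F_ROH and the four class-specific F_ROH
#' values, each with its two-sided significance test. No multiple-testing
#' correction is applied.
#'
#' @param profiles Tibble from [inbreeding_profiles] (>= 3 rows).
#' @return Tibble of class `roh_correlations`, one row per pair.
#' @export
correlation_matrix <- function(profiles) {
  vars <- c("f_hom", "f_roh", "f_roh_1_5", "f_roh_5_10", "f_roh_10_20",
            "f_roh_gt20")
  stopifnot(all(vars %in% names(profiles)), nrow(profiles) >= 3)
  pairs <- utils::combn(vars, 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    tryCatch(
      pearson_correlation(profiles[[pairs[1, k]]], profiles[[pairs[2, k]]],
                          names = pairs[, k]),
      rohscan_degenerate_error = function(e) {
        warn(paste0("correlation undefined (constant vector) for ",
                    pairs[1, k], " ~ ", pairs[2, k], "; reported as NA"))
        tibble(var_x = pairs[1, k], var_y = pairs[2, k], r = NA_real_,
               p_value = NA_real_, n = nrow(profiles))
      }
    )
  }) |> bind_rows()
  class(res) <- c("roh_correlations", class(res))
  res
}
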