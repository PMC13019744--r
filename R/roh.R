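#' Sliding-window ROH detection parameters
#'
#' Defaults reproduce the standard medium-density array configuration:
#' a 50-SNP sliding window allowing at most one heterozygous and one
#' missing call, a 1 Mb cap on the gap between consecutive SNPs, a density
#' bound of one SNP per 100 kb, a 1 Mb minimum segment length and a
#' window-hit proportion of 0.05 above which a SNP is deemed in-run. The
#' minimum number of SNPs per segment is derived from the panel through the
#' false-positive formula of Lencz et al. (see [lencz_min_snps]) at
#' `fp_alpha = 0.05`, unless pinned with `min_snps_override`.
#'
#' @param window_snps Window size in SNPs.
#' @param fp_alpha Genome-wide false-positive rate for the minimum-SNP
#'   formula.
#' @param max_het_per_window Maximum heterozygous calls for a window to
#'   count as homozygous.
#' @param max_missing_per_window Maximum missing calls per window.
#' @param max_gap_bp Maximum bp gap between consecutive SNPs inside a run.
#' @param min_density_bp_per_snp Maximum average bp per SNP inside a run
#'   (1e5 = at least one SNP per 100 kb).
#' @param min_length_bp Minimum segment length in bp.
#' @param window_hit_threshold A SNP is in-run when the fraction of
#'   homozygous windows covering it exceeds this value.
#' @param min_snps_override Optional integer pinning the minimum SNP count
#'   per segment, bypassing the Lencz formula.
#' @param segment_het_cap Optional strict per-segment cap on heterozygous
#'   calls (off by default; the window allowance is the standard semantics).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50L, fp_alpha = 0.05,
                       max_het_per_window = 1L, max_missing_per_window = 1L,
                       max_gap_bp = 1e6, min_density_bp_per_snp = 1e5,
                       min_length_bp = 1e6, window_hit_threshold = 0.05,
                       min_snps_override = NULL, segment_het_cap = NULL) {
  stopifnot(
    window_snps >= 2, fp_alpha > 0, fp_alpha < 1,
    max_het_per_window >= 0, max_missing_per_window >= 0,
    max_gap_bp > 0, min_density_bp_per_snp > 0, min_length_bp > 0,
    window_hit_threshold >= 0, window_hit_threshold < 1
  )
  structure(list(
    window_snps = as.integer(window_snps), fp_alpha = fp_alpha,
    max_het_per_window = as.integer(max_het_per_window),
    max_missing_per_window = as.integer(max_missing_per_window),
    max_gap_bp = max_gap_bp, min_density_bp_per_snp = min_density_bp_per_snp,
    min_length_bp = min_length_bp, window_hit_threshold = window_hit_threshold,
    min_snps_override = min_snps_override, segment_het_cap = segment_het_cap
  ), class = "roh_params")
}

#' Minimum SNPs per ROH controlling genome-wide false positives
#'
#' Implements l = ceiling( ln(alpha / (ns * ni)) / ln(1 - het) ): the run
#' length at which a chance all-homozygous stretch is expected at rate at
#' most `fp_alpha` across `n_snps` markers in `n_individuals` individuals,
#' given mean per-SNP heterozygosity `mean_het`.
#'
#' @param fp_alpha False-positive rate (0 < alpha < 1).
#' @param n_snps Number of SNPs per individual.
#' @param n_individuals Number of individuals.
#' @param mean_het Mean heterozygosity across all SNPs (0 < het < 1).
#' @return Integer minimum SNP count (>= 1).
#' @export
lencz_min_snps <- function(fp_alpha, n_snps, n_individuals, mean_het) {
  stopifnot(fp_alpha > 0, fp_alpha < 1, n_snps >= 1, n_individuals >= 1)
  if (mean_het <= 0 || mean_het >= 1) {
    abort("mean_het must lie strictly between 0 and 1",
          class = "rohscan_domain_error")
  }
  l <- log(fp_alpha / (n_snps * n_individuals)) / log(1 - mean_het)
  max(1L, as.integer(ceiling(l)))
}

#' Mean heterozygosity of a panel
#'
#' Number of heterozygous calls over the number of non-missing calls,
#' pooled across the whole genotype matrix.
#'
#' @param panel A [genotype_panel].
#' @return Fraction in \[0, 1\].
#' @export
mean_heterozygosity <- function(panel) {
  stop_if_not_panel(panel)
  called <- sum(!is.na(panel$geno))
  if (called == 0) {
    abort("all calls are missing", class = "rohscan_input_error")
  }
  sum(panel$geno == 1L, na.rm = TRUE) / called
}

# Windowed in-run mask for one individual on one chromosome.
# g: integer codes; returns logical vector, TRUE where the fraction of
# homozygous windows covering the SNP exceeds the hit threshold.
window_in_run_mask <- function(g, params) {
  m <- length(g)
  w <- params$window_snps
  if (m < w) return(rep(FALSE, m))
  het <- cumsum(c(0L, !is.na(g) & g == 1L))
  mis <- cumsum(c(0L, is.na(g)))
  nw <- m - w + 1L
  i <- seq_len(nw)
  hom_win <- (het[i + w] - het[i]) <= params$max_het_per_window &
             (mis[i + w] - mis[i]) <= params$max_missing_per_window
  chw <- cumsum(c(0L, hom_win))
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  n_cov <- hi - lo + 1L
  n_hom <- chw[hi + 1L] - chw[lo]
  (n_hom / n_cov) > params$window_hit_threshold
}

#' Detect runs of homozygosity
#'
#' Per individual and chromosome: a window of `window_snps` SNPs slides one
#' SNP at a time; a window is homozygous when it holds at most
#' `max_het_per_window` heterozygous and `max_missing_per_window` missing
#' calls; a SNP is in-run when the fraction of homozygous windows covering
#' it exceeds `window_hit_threshold`. Maximal in-run stretches are split at
#' inter-SNP gaps above `max_gap_bp`, trimmed so both ends sit on
#' homozygous non-missing calls, and kept only if they meet the minimum
#' length, the minimum SNP count (Lencz formula or override) and the
#' density bound. Chromosomes holding fewer SNPs than the window size yield
#' no windows and hence no runs.
#'
#' @param panel A [genotype_panel] (post-QC; SNPs are sorted by
#'   construction).
#' @param params A [roh_params] object.
#' @return Tibble of segments sorted by (individual, chromosome, start):
#'   `individual_id`, `chromosome`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_bp`. Attributes `min_snps` and `mean_het` record the realized
#'   minimum SNP count and the heterozygosity it was derived from.
#' @export
detect_roh <- function(panel, params = roh_params()) {
  stop_if_not_panel(panel)
  stopifnot(inherits(params, "roh_params"))
  het <- mean_heterozygosity(panel)
  min_snps <- if (!is.null(params$min_snps_override)) {
    as.integer(params$min_snps_override)
  } else {
    lencz_min_snps(params$fp_alpha, n_snps(panel), n_individuals(panel), het)
  }
  chroms <- unique(panel$snps$chromosome)
  ids <- panel$individuals$individual_id
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    idx <- which(panel$snps$chromosome == chroms[ci])
    pos <- panel$snps$position_bp[idx]
    gap_break <- which(diff(pos) > params$max_gap_bp)
    segs_chrom <- vector("list", length(ids))
    for (ii in seq_along(ids)) {
      g <- unname(panel$geno[ii, idx])
      mask <- window_in_run_mask(g, params)
      segs_chrom[[ii]] <- assemble_segments(
        mask, g, pos, gap_break, params, min_snps, ids[ii], chroms[ci]
      )
    }
    out[[ci]] <- bind_rows(segs_chrom)
  }
  segments <- bind_rows(out)
  if (nrow(segments) == 0) {
    segments <- tibble(
      individual_id = character(), chromosome = character(),
      start_bp = double(), end_bp = double(), n_snps = integer(),
      length_bp = double()
    )
  }
  segments <- arrange(segments, .data$individual_id,
                      chrom_rank(.data$chromosome), .data$start_bp)
  attr(segments, "min_snps") <- min_snps
  attr(segments, "mean_het") <- het
  segments
}

# Turn an in-run mask into final segments: split stretches at oversized
# gaps, trim ends to homozygous non-missing calls, apply final filters.
assemble_segments <- function(mask, g, pos, gap_break, params, min_snps,
                              id, chrom) {
  if (!any(mask)) return(NULL)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- list()
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    cuts <- gap_break[gap_break >= a & gap_break < b]
    sub_start <- c(a, cuts + 1L)
    sub_end <- c(cuts, b)
    for (s in seq_along(sub_start)) {
      i <- sub_start[s]; j <- sub_end[s]
      hom <- !is.na(g[i:j]) & g[i:j] != 1L
      if (!any(hom)) next
      i2 <- i + which(hom)[1] - 1L
      j2 <- i + which(hom)[sum(hom)] - 1L
      n_mem <- j2 - i2 + 1L
      len <- pos[j2] - pos[i2] + 1
      if (len < params$min_length_bp) next
      if (n_mem < min_snps) next
      if (len / n_mem > params$min_density_bp_per_snp) next
      if (!is.null(params$segment_het_cap) &&
          sum(!is.na(g[i2:j2]) & g[i2:j2] == 1L) > params$segment_het_cap) next
      res[[length(res) + 1]] <- tibble(
        individual_id = id, chromosome = chrom,
        start_bp = pos[i2], end_bp = pos[j2],
        n_snps = n_mem, length_bp = len
      )
    }
  }
  if (length(res)) bind_rows(res) else NULL
}

#' Validate ROH segment invariants
#'
#' Checks every segment against the panel and parameters it was called
#' from: coordinate ordering, the length identity, the minimum length,
#' minimum SNP count, density bound and the internal gap cap.
#'
#' @param segments Segment tibble from [detect_roh].
#' @param panel The source [genotype_panel].
#' @param params The [roh_params] used.
#' @param min_snps Minimum SNP count the segments were filtered at
#'   (defaults to the `min_snps` attribute of `segments`).
#' @return `TRUE` invisibly; aborts on the first violated invariant.
#' @export
validate_segments <- function(segments, panel, params,
                              min_snps = attr(segments, "min_snps")) {
  for (r in seq_len(nrow(segments))) {
    seg <- segments[r, ]
    if (seg$end_bp < seg$start_bp) abort("end < start")
    if (seg$length_bp != seg$end_bp - seg$start_bp + 1) abort("length identity broken")
    if (seg$length_bp < params$min_length_bp) abort("below minimum length")
    if (!is.null(min_snps) && seg$n_snps < min_snps) abort("below minimum SNP count")
    if (seg$length_bp / seg$n_snps > params$min_density_bp_per_snp) abort("density bound broken")
    sel <- panel$snps$chromosome == seg$chromosome &
      panel$snps$position_bp >= seg$start_bp &
      panel$snps$position_bp <= seg$end_bp
    pos <- panel$snps$position_bp[sel]
    if (length(pos) != seg$n_snps) abort("member SNP count mismatch")
    if (length(pos) > 1 && any(diff(pos) > params$max_gap_bp)) abort("gap cap broken")
  }
  invisible(TRUE)
}
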