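#' Per-SNP ROH incidence across individuals
#'
#' For every SNP, counts the individuals in which the SNP lies inside at
#' least one called segment on its chromosome (closed bp intervals; one
#' count per individual regardless of segment overlap).
#'
#' @param segments Segment tibble from [detect_roh].
#' @param panel The source [genotype_panel].
#' @return Tibble sorted in map order: `snp_id`, `chromosome`,
#'   `position_bp`, `n_in_roh`, `fraction_in_roh`.
#' @export
snp_roh_incidence <- function(segments, panel) {
  stop_if_not_panel(panel)
  unknown <- setdiff(unique(segments$chromosome), unique(panel$snps$chromosome))
  if (length(unknown)) {
    abort(paste("segment chromosome(s) not in panel:",
                paste(unknown, collapse = ", ")),
          class = "rohscan_validation_error")
  }
  n_ind <- n_individuals(panel)
  snps <- panel$snps
  counts <- numeric(nrow(snps))
  for (chrom in unique(snps$chromosome)) {
    idx <- which(snps$chromosome == chrom)
    pos <- snps$position_bp[idx]
    seg <- segments[segments$chromosome == chrom, , drop = FALSE]
    if (nrow(seg) == 0) next
    # one count per (individual, SNP): collapse an individual's segments
    # into covered index ranges, then difference-array accumulation
    diffs <- numeric(length(idx) + 1)
    for (id in unique(seg$individual_id)) {
      s <- seg[seg$individual_id == id, , drop = FALSE]
      lo <- findInterval(s$start_bp - 0.5, pos) + 1L
      hi <- findInterval(s$end_bp + 0.5, pos)
      covered <- unique(unlist(
        purrr::map2(lo, hi, function(a, b) if (a <= b) a:b else integer())
      ))
      diffs[covered] <- diffs[covered] + 1
    }
    counts[idx] <- diffs[seq_along(idx)]
  }
  tibble(
    snp_id = snps$snp_id, chromosome = snps$chromosome,
    position_bp = snps$position_bp,
    n_in_roh = as.integer(counts),
    fraction_in_roh = counts / n_ind
  )
}

#' Top-percentile incidence threshold for ROH islands
#'
#' Returns the k-th largest `fraction_in_roh`, where
#' k = ceiling(top_fraction * number of SNPs). SNPs with fraction >= the
#' returned value are island candidates, so the candidate set holds at
#' least k SNPs and ties at the cutoff are never split.
#'
#' @param incidences Tibble from [snp_roh_incidence].
#' @param top_fraction Fraction of SNPs to take (default 0.01, the top 1%).
#' @return The threshold fraction. A degenerate distribution (all values
#'   identical) returns that value with a warning: every SNP ties at the
#'   cutoff.
#' @export
island_threshold <- function(incidences, top_fraction = 0.01) {
  stopifnot(nrow(incidences) > 0, top_fraction > 0, top_fraction < 1)
  f <- incidences$fraction_in_roh
  if (length(unique(f)) == 1) {
    warn("all incidence fractions identical; island threshold is degenerate")
  }
  k <- ceiling(top_fraction * length(f))
  sort(f, decreasing = TRUE)[k]
}

#' Assemble ROH islands from high-incidence SNPs
#'
#' Maximal runs of map-consecutive SNPs with incidence >= `threshold` on
#' one chromosome; runs shorter than `min_snps` SNPs are discarded. Island
#' bounds are the first and last member SNP positions. No intra-island gap
#' constraint is applied, but the largest physical gap is reported so
#' sparse islands can be audited.
#'
#' @param incidences Tibble from [snp_roh_incidence] (map-sorted).
#' @param threshold Incidence threshold from [island_threshold].
#' @param min_snps Minimum SNPs per island (default 2; singletons dropped).
#' @return Tibble: `chromosome`, `start_bp`, `end_bp`, `length_bp`,
#'   `n_snps`, `max_gap_bp`, `genes` (empty list column), `n_genes`.
#' @export
detect_islands <- function(incidences, threshold, min_snps = 2L) {
  cand <- incidences$fraction_in_roh >= threshold
  res <- list()
  for (chrom in unique(incidences$chromosome)) {
    sel <- incidences$chromosome == chrom
    mask <- cand[sel]
    pos <- incidences$position_bp[sel]
    if (!any(mask)) next
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_snps)) {
      i <- starts[k]; j <- ends[k]
      res[[length(res) + 1]] <- tibble(
        chromosome = chrom, start_bp = pos[i], end_bp = pos[j],
        length_bp = pos[j] - pos[i] + 1, n_snps = j - i + 1L,
        max_gap_bp = if (j > i) max(diff(pos[i:j])) else 0
      )
    }
  }
  out <- if (length(res)) bind_rows(res) else tibble(
    chromosome = character(), start_bp = double(), end_bp = double(),
    length_bp = double(), n_snps = integer(), max_gap_bp = double()
  )
  out <- arrange(out, chrom_rank(.data$chromosome), .data$start_bp)
  out$genes <- rep(list(character()), nrow(out))
  out$n_genes <- 0L
  out
}

#' Annotate ROH islands with overlapping genes
#'
#' A gene is assigned to an island when its interval overlaps the island
#' interval by at least 1 bp (closed coordinates on both sides); overlap is
#' computed with GenomicRanges.
#'
#' @param islands Tibble from [detect_islands].
#' @param gene_models Tibble from [read_gene_models] (columns `chromosome`,
#'   `start_bp`, `end_bp`, `gene_id`).
#' @return `islands` with the `genes` list column and `n_genes` filled in.
#' @export
annotate_islands <- function(islands, gene_models) {
  if (nrow(islands) == 0) return(islands)
  stopifnot(all(c("chromosome", "start_bp", "end_bp", "gene_id") %in%
                  names(gene_models)))
  shared <- intersect(unique(islands$chromosome),
                      unique(gene_models$chromosome))
  if (length(shared) == 0 && nrow(gene_models) > 0) {
    abort(paste0(
      "no chromosome label shared between islands and gene file; island ",
      "labels: ", paste(unique(islands$chromosome), collapse = ", "),
      " | gene labels: ",
      paste(head(unique(gene_models$chromosome), 10), collapse = ", ")
    ), class = "rohscan_validation_error")
  }
  isl_gr <- GenomicRanges::GRanges(
    islands$chromosome,
    IRanges::IRanges(islands$start_bp, islands$end_bp)
  )
  gene_gr <- GenomicRanges::GRanges(
    gene_models$chromosome,
    IRanges::IRanges(gene_models$start_bp, gene_models$end_bp)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(isl_gr, gene_gr))
  genes <- rep(list(character()), nrow(islands))
  for (k in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[k]
    genes[[i]] <- c(genes[[i]], gene_models$gene_id[S4Vectors::subjectHits(hits)[k]])
  }
  islands$genes <- purrr::map(genes, unique)
  islands$n_genes <- lengths(islands$genes)
  islands
}
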