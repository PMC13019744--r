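roh_class_breaks <- c(1, 5, 10, 20, Inf)
roh_class_labels <- c("1-5", "5-10", "10-20", ">20")

#' Length class of each ROH segment
#'
#' Classes are half-open in Mb: \[1,5), \[5,10), \[10,20), \[20, Inf); a
#' 5.0 Mb segment belongs to the 5-10 Mb class.
#'
#' @param length_bp Numeric vector of segment lengths in bp.
#' @return Factor with levels `1-5`, `5-10`, `10-20`, `>20`.
#' @export
roh_length_class <- function(length_bp) {
  cut(length_bp / 1e6, breaks = roh_class_breaks, labels = roh_class_labels,
      right = FALSE, include.lowest = TRUE)
}

#' Summarise ROH segments by length class
#'
#' Per class (1-5, 5-10, 10-20, >20 Mb): count, share of segment number,
#' mean and SD of length, total length and share of cumulative length, plus
#' an `all` row. Both percentage columns sum to 100 over the four classes.
#'
#' @param segments Segment tibble (needs `length_bp`).
#' @return Tibble with columns `class`, `n_segments`, `pct_of_number`,
#'   `mean_length_mb`, `sd_length_mb`, `total_length_mb`, `pct_of_length`.
#' @export
classify_roh <- function(segments) {
  mb <- segments$length_bp / 1e6
  cls <- roh_length_class(segments$length_bp)
  per <- tibble(class = cls, mb = mb) |>
    group_by(.data$class, .drop = FALSE) |>
    summarise(
      n_segments = n(),
      mean_length_mb = if (n() > 0) mean(.data$mb) else NA_real_,
      sd_length_mb = if (n() > 1) sd(.data$mb) else NA_real_,
      total_length_mb = sum(.data$mb),
      .groups = "drop"
    )
  total_n <- sum(per$n_segments)
  total_mb <- sum(per$total_length_mb)
  per <- per |>
    mutate(
      pct_of_number = if (total_n > 0) 100 * .data$n_segments / total_n else 0,
      pct_of_length = if (total_mb > 0) 100 * .data$total_length_mb / total_mb else 0
    )
  all_row <- tibble(
    class = "all", n_segments = total_n,
    pct_of_number = if (total_n > 0) 100 else 0,
    mean_length_mb = if (total_n > 0) mean(mb) else NA_real_,
    sd_length_mb = if (total_n > 1) sd(mb) else NA_real_,
    total_length_mb = total_mb,
    pct_of_length = if (total_mb > 0) 100 else 0
  )
  per$class <- as.character(per$class)
  bind_rows(per, all_row) |>
    select("class", "n_segments", "pct_of_number", "mean_length_mb",
           "sd_length_mb", "total_length_mb", "pct_of_length")
}

#' Population-level ROH descriptive statistics
#'
#' MN_ROH (mean number of segments per individual), ML_ROH (mean cumulative
#' ROH length per individual, Mb), mean segment length and the per-individual
#' segment-count range.
#'
#' @param segments Segment tibble.
#' @param n_individuals Number of individuals in the panel (individuals
#'   without segments count toward the means).
#' @return One-row tibble: `n_segments`, `mn_roh`, `ml_roh_mb`,
#'   `mean_segment_length_mb`, `min_per_individual`, `max_per_individual`.
#' @export
roh_population_summary <- function(segments, n_individuals) {
  stopifnot(n_individuals >= 1)
  per_ind <- segments |> count(.data$individual_id)
  tibble(
    n_segments = nrow(segments),
    mn_roh = nrow(segments) / n_individuals,
    ml_roh_mb = sum(segments$length_bp) / 1e6 / n_individuals,
    mean_segment_length_mb =
      if (nrow(segments)) mean(segments$length_bp) / 1e6 else NA_real_,
    min_per_individual = if (nrow(per_ind)) min(per_ind$n) else 0L,
    max_per_individual = if (nrow(per_ind)) max(per_ind$n) else 0L
  )
}

#' Per-chromosome ROH summary
#'
#' Coverage is the population-average fraction of the chromosome inside
#' ROH: 100 * (sum of segment lengths) / (n_individuals * chromosome
#' length). Set `per_individual = FALSE` for the cohort-total variant
#' (denominator = chromosome length alone).
#'
#' @param segments Segment tibble.
#' @param chrom_lengths Tibble with `chromosome`, `length_bp` (e.g. from
#'   [read_chrom_lengths]).
#' @param n_individuals Number of individuals in the panel.
#' @param per_individual Average coverage across individuals (default) or
#'   cohort-total coverage.
#' @return Tibble with one row per chromosome in `chrom_lengths`:
#'   `chromosome`, `n_segments`, `total_length_mb`, `coverage_pct`,
#'   `longest_mb`, `shortest_mb`.
#' @export
chromosome_summary <- function(segments, chrom_lengths, n_individuals,
                               per_individual = TRUE) {
  stopifnot(n_individuals >= 1)
  unknown <- setdiff(unique(segments$chromosome), chrom_lengths$chromosome)
  if (length(unknown)) {
    abort(paste("segment chromosome(s) not in length table:",
                paste(unknown, collapse = ", ")),
          class = "rohscan_lookup_error")
  }
  per <- segments |>
    group_by(.data$chromosome) |>
    summarise(
      n_segments = n(),
      total_bp = sum(.data$length_bp),
      longest_mb = max(.data$length_bp) / 1e6,
      shortest_mb = min(.data$length_bp) / 1e6,
      .groups = "drop"
    )
  denom_ind <- if (per_individual) n_individuals else 1
  chrom_lengths |>
    left_join(per, by = "chromosome") |>
    mutate(
      n_segments = dplyr::coalesce(.data$n_segments, 0L),
      total_bp = dplyr::coalesce(.data$total_bp, 0),
      total_length_mb = .data$total_bp / 1e6,
      coverage_pct = 100 * .data$total_bp / (denom_ind * .data$length_bp)
    ) |>
    arrange(chrom_rank(.data$chromosome)) |>
    select("chromosome", "n_segments", "total_length_mb", "coverage_pct",
           "longest_mb", "shortest_mb")
}
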