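#' Stylised autosome set for simulations
#'
#' A synthetic autosome length table: `n_chrom` chromosomes with lengths
#' decreasing linearly from `longest_bp` to `shortest_bp`. The default 29
#' autosomes from 140 Mb down to 30 Mb total about 2.46 Gb, the scale of a
#' goat-like genome, so that the default SNP spacing of 40 kb yields a
#' panel of roughly 60k markers.
#'
#' @param n_chrom Number of autosomes.
#' @param longest_bp,shortest_bp Lengths of the first and last chromosome.
#' @return Tibble with `chromosome`, `length_bp`.
#' @export
sim_chromosomes <- function(n_chrom = 29, longest_bp = 140e6,
                            shortest_bp = 30e6) {
  tibble(
    chromosome = as.character(seq_len(n_chrom)),
    length_bp = round(seq(longest_bp, shortest_bp, length.out = n_chrom))
  )
}

#' Simulation configuration
#'
#' Defines a synthetic SNP-array panel: marker positions drawn with
#' exponential inter-SNP spacing, per-SNP minor allele frequencies uniform
#' on `maf_range`, background genotypes at Hardy-Weinberg proportions, and
#' per-individual planted autozygous tracts whose genotypes are homozygous
#' for a founder allele drawn by population frequency. Genotyping errors
#' flip the call to one of the other two states uniformly; missingness
#' masks calls at random. Tract lengths are drawn from the four ROH length
#' classes (1-5, 5-10, 10-20, 20-35 Mb) with `class_weights`, or uniformly
#' from `tract_length_range_bp` when that is supplied.
#'
#' @param n_individuals Number of individuals.
#' @param chromosomes Tibble `chromosome`/`length_bp`; default
#'   [sim_chromosomes()].
#' @param snp_spacing_bp Mean inter-SNP distance (default 40 kb, emulating
#'   a ~50-60k autosomal array on a ~2.5 Gb genome).
#' @param maf_range Minor-allele-frequency range, uniform draw per SNP.
#' @param f_target Planted autozygous fraction of the SNP-covered genome
#'   per individual (0 = no tracts).
#' @param tract_length_range_bp Optional c(min, max): tract lengths uniform
#'   on this range instead of the class mixture.
#' @param class_weights Mixture weights for tract lengths over the classes
#'   1-5 / 5-10 / 10-20 / 20-35 Mb.
#' @param genotype_error_rate Per-call state-flip probability.
#' @param missing_rate Per-call missing probability.
#' @param seed RNG seed; the panel is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 380,
                       chromosomes = sim_chromosomes(),
                       snp_spacing_bp = 40000,
                       maf_range = c(0.05, 0.5),
                       f_target = 0,
                       tract_length_range_bp = NULL,
                       class_weights = c(0.50, 0.29, 0.15, 0.06),
                       genotype_error_rate = 0,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(
    n_individuals >= 1, snp_spacing_bp > 0,
    genotype_error_rate >= 0, genotype_error_rate <= 1,
    missing_rate >= 0, missing_rate <= 1,
    f_target >= 0, f_target < 1,
    maf_range[1] > 0, maf_range[2] <= 0.5
  )
  structure(list(
    n_individuals = as.integer(n_individuals),
    chromosomes = as_tibble(chromosomes),
    snp_spacing_bp = snp_spacing_bp, maf_range = maf_range,
    f_target = f_target, tract_length_range_bp = tract_length_range_bp,
    class_weights = class_weights / sum(class_weights),
    genotype_error_rate = genotype_error_rate, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

draw_tract_length <- function(config) {
  if (!is.null(config$tract_length_range_bp)) {
    return(runif(1, config$tract_length_range_bp[1],
                 config$tract_length_range_bp[2]))
  }
  cls <- sample.int(4, 1, prob = config$class_weights)
  lo <- c(1e6, 5e6, 10e6, 20e6)[cls]
  hi <- c(5e6, 10e6, 20e6, 35e6)[cls]
  runif(1, lo, hi)
}

# Non-overlapping tract placement on one individual: chromosomes chosen
# proportional to length, uniform start, rejection on overlap.
plant_tracts <- function(config, target_bp) {
  chroms <- config$chromosomes
  tracts <- tibble(chromosome = character(), start_bp = double(),
                   end_bp = double())
  planted <- 0
  tries <- 0
  while (planted < target_bp && tries < 1000) {
    tries <- tries + 1
    # truncate the final tract toward the target, but never below 2 Mb so
    # every planted tract stays comfortably callable
    len <- min(draw_tract_length(config), max(target_bp - planted, 2e6))
    ci <- sample.int(nrow(chroms), 1, prob = chroms$length_bp)
    if (len >= chroms$length_bp[ci]) next
    start <- floor(runif(1, 1, chroms$length_bp[ci] - len))
    end <- start + len - 1
    same <- tracts[tracts$chromosome == chroms$chromosome[ci], , drop = FALSE]
    if (nrow(same) && any(start <= same$end_bp & end >= same$start_bp)) next
    tracts <- bind_rows(tracts, tibble(
      chromosome = chroms$chromosome[ci], start_bp = start, end_bp = end
    ))
    planted <- planted + len
  }
  if (planted < 0.8 * target_bp) {
    abort("tract plan exceeds chromosome capacity",
          class = "rohscan_config_error")
  }
  tracts
}

#' Simulate a genotype panel with planted autozygous tracts
#'
#' @param config A [sim_config].
#' @return A list with elements `panel` (a [genotype_panel]) and `truth`
#'   (list: `tracts` tibble with `individual_id`, `chromosome`, `start_bp`,
#'   `end_bp`; `f_true` tibble with `individual_id`, `f_true`, the planted
#'   fraction of the SNP-covered span; `snp_freq`, the allele-B frequency
#'   used per SNP; `l_auto_bp`).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- config$chromosomes
  pos_list <- purrr::map(seq_len(nrow(chroms)), function(ci) {
    len <- chroms$length_bp[ci]
    n_exp <- ceiling(len / config$snp_spacing_bp * 1.5) + 10
    gaps <- rexp(n_exp, rate = 1 / config$snp_spacing_bp)
    p <- cumsum(c(max(1, round(gaps[1])), pmax(1, round(gaps[-1]))))
    p[p <= len]
  })
  snps <- tibble(
    chromosome = rep(chroms$chromosome, lengths(pos_list)),
    position_bp = unlist(pos_list)
  )
  m <- nrow(snps)
  snps$snp_id <- sprintf("snp_%s_%07d", snps$chromosome,
                         unlist(lapply(lengths(pos_list), seq_len)))
  snps$allele_a <- "A"
  snps$allele_b <- "B"
  freq <- runif(m, config$maf_range[1], config$maf_range[2])
  n <- config$n_individuals
  ids <- sprintf("ind_%04d", seq_len(n))

  # background genotypes at HWE proportions, individuals x SNPs
  u <- matrix(runif(n * m), n, m)
  p0 <- matrix(rep((1 - freq)^2, each = n), n, m)
  p01 <- matrix(rep((1 - freq)^2 + 2 * freq * (1 - freq), each = n), n, m)
  geno <- matrix(2L, n, m)
  geno[u < p01] <- 1L
  geno[u < p0] <- 0L

  # planted tracts: founder allele drawn by frequency, set homozygous
  span_by_chrom <- vapply(pos_list, function(p) {
    if (length(p) >= 1) max(p) - min(p) + 1 else 0
  }, numeric(1))
  l_auto <- sum(span_by_chrom)
  all_tracts <- list()
  f_true <- numeric(n)
  if (config$f_target > 0) {
    target_bp <- config$f_target * l_auto
    for (ii in seq_len(n)) {
      tr <- plant_tracts(config, target_bp)
      covered <- 0
      for (k in seq_len(nrow(tr))) {
        ci <- match(tr$chromosome[k], chroms$chromosome)
        pos <- pos_list[[ci]]
        idx0 <- which(snps$chromosome == tr$chromosome[k])
        inside <- idx0[pos >= tr$start_bp[k] & pos <= tr$end_bp[k]]
        if (length(inside)) {
          founder <- rbinom(length(inside), 1, freq[inside])
          geno[ii, inside] <- 2L * founder
        }
        # overlap of the tract with the SNP-covered span of its chromosome
        if (length(pos)) {
          covered <- covered +
            max(0, min(tr$end_bp[k], max(pos)) - max(tr$start_bp[k], min(pos)) + 1)
        }
      }
      f_true[ii] <- covered / l_auto
      if (nrow(tr)) {
        tr$individual_id <- ids[ii]
        all_tracts[[length(all_tracts) + 1]] <- tr
      }
    }
  }

  if (config$genotype_error_rate > 0) {
    err <- which(matrix(runif(n * m) < config$genotype_error_rate, n, m))
    if (length(err)) {
      shift <- sample.int(2, length(err), replace = TRUE)  # +1 or +2 mod 3
      geno[err] <- (geno[err] + shift) %% 3L
    }
  }
  if (config$missing_rate > 0) {
    geno[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_integer_
  }

  tracts <- if (length(all_tracts)) {
    bind_rows(all_tracts) |>
      select("individual_id", "chromosome", "start_bp", "end_bp")
  } else {
    tibble(individual_id = character(), chromosome = character(),
           start_bp = double(), end_bp = double())
  }
  panel <- genotype_panel(geno, snps, tibble(individual_id = ids, sex = 0L))
  list(
    panel = panel,
    truth = list(
      tracts = tracts,
      f_true = tibble(individual_id = ids, f_true = f_true),
      snp_freq = tibble(snp_id = snps$snp_id, freq_b = freq),
      l_auto_bp = l_auto
    )
  )
}

interval_overlap_bp <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
}

#' Recovery of planted tracts by called segments
#'
#' Per individual: bp-level sensitivity (fraction of planted tract length
#' covered by called segments), false-discovery bp (called bp outside any
#' planted tract) and the F_ROH - f_true bias; plus aggregate mean/SD.
#'
#' @param truth The `truth` element from [simulate_panel].
#' @param segments Segment tibble from [detect_roh] on the simulated panel.
#' @param profiles Optional tibble with `individual_id`, `f_roh` (e.g. from
#'   [inbreeding_profiles] or [f_roh]); enables the bias column.
#' @return A list with `per_individual` (tibble) and `summary` (one-row
#'   tibble of means/SDs).
#' @export
evaluate_recovery <- function(truth, segments, profiles = NULL) {
  ids <- truth$f_true$individual_id
  extra <- setdiff(unique(segments$individual_id), ids)
  if (length(extra)) {
    abort(paste("segments reference unknown individuals:",
                paste(head(extra, 5), collapse = ", ")),
          class = "rohscan_validation_error")
  }
  per <- purrr::map(ids, function(id) {
    tr <- truth$tracts[truth$tracts$individual_id == id, , drop = FALSE]
    sg <- segments[segments$individual_id == id, , drop = FALSE]
    planted_bp <- sum(tr$end_bp - tr$start_bp + 1)
    called_bp <- sum(sg$length_bp)
    hit_bp <- 0
    if (nrow(tr) && nrow(sg)) {
      for (k in seq_len(nrow(tr))) {
        same <- sg[sg$chromosome == tr$chromosome[k], , drop = FALSE]
        if (nrow(same)) {
          hit_bp <- hit_bp + sum(interval_overlap_bp(
            tr$start_bp[k], tr$end_bp[k], same$start_bp, same$end_bp
          ))
        }
      }
    }
    tibble(
      individual_id = id,
      planted_bp = planted_bp, called_bp = called_bp,
      sensitivity_bp = if (planted_bp > 0) hit_bp / planted_bp else NA_real_,
      false_discovery_bp = called_bp - hit_bp
    )
  }) |> bind_rows()
  if (!is.null(profiles)) {
    per <- per |>
      left_join(truth$f_true, by = "individual_id") |>
      left_join(select(profiles, "individual_id", "f_roh"),
                by = "individual_id") |>
      mutate(f_roh_bias = .data$f_roh - .data$f_true)
  }
  summary <- tibble(
    mean_sensitivity = mean(per$sensitivity_bp, na.rm = TRUE),
    sd_sensitivity = sd(per$sensitivity_bp, na.rm = TRUE),
    mean_false_discovery_bp = mean(per$false_discovery_bp),
    mean_f_roh_bias = if ("f_roh_bias" %in% names(per)) {
      mean(per$f_roh_bias)
    } else NA_real_
  )
  list(per_individual = per, summary = summary)
}
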