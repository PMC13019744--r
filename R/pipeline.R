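#' Run the full ROH analysis pipeline
#'
#' Chains QC, ROH detection, length-class and chromosome summaries,
#' inbreeding coefficients with correlations, ROH islands and gene
#' annotation, writing every stage's table before the next stage starts and
#' ending with a JSON run manifest (parameter echo, input checksums, stage
#' row counts, package version, realized Lencz minimum-SNP count and mean
#' heterozygosity).
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `input` (list: `format` = "ped"/"bed"/"vcf", `prefix` or `path`),
#'   `out_dir`, and optionally `qc` (arguments to [qc_thresholds]), `roh`
#'   (arguments to [roh_params]), `island_top_fraction` (default 0.01),
#'   `min_island_snps` (default 2), `chrom_lengths` (path; required for the
#'   chromosome summary), `gene_models` (path; enables island annotation).
#' @return An object of class `roh_analysis`: list with `panel`,
#'   `qc_report`, `segments`, `class_summary`, `population_summary`,
#'   `chrom_summary`, `profiles`, `correlations`, `incidence`, `islands`,
#'   `params`, `files`.
#' @export
run_roh_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$input), !is.null(config$out_dir))

  input_files <- character()
  fmt <- config$input$format %||% "ped"
  if (fmt %in% c("ped", "bed")) {
    prefix <- config$input$prefix
    ext <- if (fmt == "ped") c(".ped", ".map") else c(".bed", ".bim", ".fam")
    input_files <- paste0(prefix, ext)
  } else if (fmt == "vcf") {
    input_files <- config$input$path
  } else {
    abort(paste("unknown input format:", fmt), class = "rohscan_config_error")
  }
  paths_needed <- c(input_files, config$chrom_lengths, config$gene_models)
  missing <- paths_needed[!file.exists(paths_needed)]
  if (length(missing)) {
    abort(paste("missing input file(s):", paste(missing, collapse = ", ")),
          class = "rohscan_config_error")
  }

  panel0 <- switch(fmt,
    ped = read_ped_map(input_files[1], input_files[2]),
    bed = read_bed_bim_fam(config$input$prefix),
    vcf = read_vcf(input_files[1])
  )

  thresholds <- do.call(qc_thresholds, config$qc %||% list())
  qc <- apply_qc(panel0, thresholds)
  panel <- qc$panel
  write_reports(list(qc_report = qc$report), config$out_dir)

  params <- do.call(roh_params, config$roh %||% list())
  segments <- detect_roh(panel, params)
  write_reports(list(segments = segments), config$out_dir)

  class_summary <- classify_roh(segments)
  pop_summary <- roh_population_summary(segments, n_individuals(panel))
  chrom_summary <- NULL
  if (!is.null(config$chrom_lengths)) {
    chrom_summary <- chromosome_summary(
      segments, read_chrom_lengths(config$chrom_lengths), n_individuals(panel)
    )
  }
  write_reports(list(class_summary = class_summary,
                     chrom_summary = chrom_summary), config$out_dir)

  profiles <- inbreeding_profiles(panel, segments)
  correlations <- correlation_matrix(profiles)
  write_reports(list(profiles = profiles, correlations = correlations),
                config$out_dir)

  incidence <- snp_roh_incidence(segments, panel)
  threshold <- island_threshold(incidence,
                                config$island_top_fraction %||% 0.01)
  islands <- detect_islands(incidence, threshold,
                            config$min_island_snps %||% 2L)
  if (!is.null(config$gene_models)) {
    islands <- annotate_islands(islands, read_gene_models(config$gene_models))
  }
  write_reports(list(incidence = incidence, islands = islands),
                config$out_dir)

  manifest <- list(
    package_version = as.character(packageVersion("rohscan")),
    config = config[setdiff(names(config), "out_dir")],
    input_md5 = as.list(tools::md5sum(input_files)),
    qc = list(
      retained_individuals = n_individuals(panel),
      retained_snps = n_snps(panel)
    ),
    roh = list(
      mean_heterozygosity = attr(segments, "mean_het"),
      lencz_min_snps = attr(segments, "min_snps"),
      n_segments = nrow(segments)
    ),
    islands = list(threshold = threshold, n_islands = nrow(islands)),
    rows = list(
      segments = nrow(segments), profiles = nrow(profiles),
      correlations = nrow(correlations), incidence = nrow(incidence),
      islands = nrow(islands)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(
    panel = panel, qc_report = qc$report, segments = segments,
    class_summary = class_summary, population_summary = pop_summary,
    chrom_summary = chrom_summary, profiles = profiles,
    correlations = correlations, incidence = incidence,
    islands = islands, island_threshold = threshold,
    params = list(qc = thresholds, roh = params,
                  min_snps = attr(segments, "min_snps"),
                  mean_het = attr(segments, "mean_het")),
    files = list.files(config$out_dir, full.names = TRUE)
  ), class = "roh_analysis")
}

#' Print a short description of an ROH analysis
#'
#' @param x An `roh_analysis` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.roh_analysis <- function(x, ...) {
  cat("<roh_analysis>\n")
  cat(sprintf("  panel: %d individuals x %d SNPs (post-QC)\n",
              n_individuals(x$panel), n_snps(x$panel)))
  cat(sprintf("  ROH: %d segments (min SNPs %d, mean het %.4f)\n",
              nrow(x$segments), x$params$min_snps, x$params$mean_het))
  cat(sprintf("  mean F_ROH %.4f | mean F_HOM %.4f | islands: %d\n",
              mean(x$profiles$f_roh), mean(x$profiles$f_hom),
              nrow(x$islands)))
  invisible(x)
}

#' Tidy an ROH analysis into its segment table
#'
#' @param x An `roh_analysis` object.
#' @param ... Unused.
#' @return The segment tibble.
#' @exportS3Method generics::tidy
tidy.roh_analysis <- function(x, ...) as_tibble(x$segments)

#' One-row summary of an ROH analysis
#'
#' @param x An `roh_analysis` object.
#' @param ... Unused.
#' @return One-row tibble with panel dimensions, segment count, MN_ROH,
#'   ML_ROH, mean F_ROH, mean F_HOM and island count.
#' @exportS3Method generics::glance
glance.roh_analysis <- function(x, ...) {
  bind_cols(
    tibble(
      n_individuals = n_individuals(x$panel),
      n_snps = n_snps(x$panel),
      min_snps_per_roh = x$params$min_snps,
      mean_heterozygosity = x$params$mean_het
    ),
    x$population_summary,
    tibble(
      mean_f_roh = mean(x$profiles$f_roh),
      mean_f_hom = mean(x$profiles$f_hom),
      n_islands = nrow(x$islands)
    )
  )
}

#' Replicate the published cashmere-goat study run
#'
#' Convenience wrapper binding the study's exact configuration (default QC
#' thresholds, 50-SNP window, alpha 0.05, 1 het + 1 missing per window,
#' 1 Mb gap, 1 SNP/100 kb, 1 Mb minimum length, top-1% islands) to a local
#' copy of a deposited genotype dataset.
#'
#' @param prefix Path prefix of the PLINK fileset (`format` "ped" or "bed").
#' @param out_dir Output directory.
#' @param format Input format.
#' @param gene_models Optional gene-model path for island annotation.
#' @return An `roh_analysis` object.
#' @export
replicate_study_run <- function(prefix, out_dir, format = "bed",
                                gene_models = NULL) {
  run_roh_pipeline(list(
    input = list(format = format, prefix = prefix),
    out_dir = out_dir,
    qc = list(),                              # study defaults
    roh = list(),                             # study defaults
    island_top_fraction = 0.01,
    gene_models = gene_models
  ))
}
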