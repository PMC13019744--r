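#' Read a chromosome-length table
#'
#' A two-column TSV (label, length in bp), with or without a header line.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `chromosome`, `length_bp`.
#' @export
read_chrom_lengths <- function(path) {
  stopifnot(file.exists(path))
  first <- read.table(path, nrows = 1, colClasses = "character")
  has_header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  tab <- read.table(path, header = has_header, colClasses = "character")
  tibble(chromosome = tab[[1]], length_bp = as.double(tab[[2]]))
}

#' Read gene models from a GFF3 or BED file
#'
#' GFF3 files are parsed with rtracklayer and filtered to `feature_type`
#' records; the gene identifier is taken from the `Name`, `gene_id` or `ID`
#' attribute, in that order. BED input (4+ columns) is converted from
#' 0-based half-open to 1-based closed coordinates.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @param feature_type GFF3 record type to keep (default `"gene"`).
#' @return A tibble with columns `chromosome`, `start_bp`, `end_bp`, `gene_id`.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  stopifnot(file.exists(path))
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    bed <- read.table(path, header = FALSE, colClasses = "character")
    if (ncol(bed) < 4) {
      abort("BED gene file needs at least 4 columns", class = "rohscan_format_error")
    }
    return(tibble(
      chromosome = bed[[1]],
      start_bp = as.double(bed[[2]]) + 1,
      end_bp = as.double(bed[[3]]),
      gene_id = bed[[4]]
    ))
  }
  gr <- rtracklayer::import(path)
  meta <- as.data.frame(gr)
  if ("type" %in% names(meta)) {
    keep <- as.character(meta$type) == feature_type
    meta <- meta[keep, , drop = FALSE]
  }
  id <- rep(NA_character_, nrow(meta))
  for (col in c("Name", "gene_id", "ID")) {
    if (col %in% names(meta)) {
      val <- as.character(meta[[col]])
      id[is.na(id) & !is.na(val)] <- val[is.na(id) & !is.na(val)]
    }
  }
  tibble(
    chromosome = as.character(meta$seqnames),
    start_bp = as.double(meta$start),
    end_bp = as.double(meta$end),
    gene_id = id
  )
}

fmt_fixed <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

#' Write the pipeline's tabular reports
#'
#' Emits tab-separated files with fixed headers into `out_dir`. Recognised
#' elements of `results`: `segments` (-> roh_segments.tsv), `class_summary`
#' (-> roh_class_summary.tsv), `chrom_summary` (-> chromosome_summary.tsv),
#' `profiles` (-> inbreeding.tsv), `correlations` (-> correlations.tsv),
#' `islands` (-> islands.tsv + islands.bed, 0-based half-open),
#' `qc_report` (-> qc_report.tsv), `incidence` (-> snp_incidence.tsv).
#' Fractions and coefficients are printed at 4 decimals, Mb summaries at 2.
#'
#' @param results Named list of stage outputs (any subset).
#' @param out_dir Output directory, created if absent.
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste("cannot create", out_dir), class = "rohscan_io_error")
  }
  if (file.access(out_dir, 2) != 0) {
    abort(paste(out_dir, "is not writable"), class = "rohscan_io_error")
  }
  written <- character()
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_tsv(df, path)
    written <<- c(written, path)
  }
  if (!is.null(results$segments)) {
    seg <- results$segments
    emit(tibble(
      individual_id = seg$individual_id, chromosome = seg$chromosome,
      start_bp = seg$start_bp, end_bp = seg$end_bp, n_snps = seg$n_snps,
      length_mb = fmt_fixed(seg$length_bp / 1e6, 2)
    ), "roh_segments.tsv")
  }
  if (!is.null(results$class_summary)) {
    cs <- results$class_summary
    emit(tibble(
      class = cs$class, n_segments = cs$n_segments,
      pct_of_number = fmt_fixed(cs$pct_of_number, 2),
      mean_length_mb = fmt_fixed(cs$mean_length_mb, 2),
      sd_length_mb = fmt_fixed(cs$sd_length_mb, 2),
      total_length_mb = fmt_fixed(cs$total_length_mb, 2),
      pct_of_length = fmt_fixed(cs$pct_of_length, 2)
    ), "roh_class_summary.tsv")
  }
  if (!is.null(results$chrom_summary)) {
    ch <- results$chrom_summary
    emit(tibble(
      chromosome = ch$chromosome, n_segments = ch$n_segments,
      total_length_mb = fmt_fixed(ch$total_length_mb, 2),
      coverage_pct = fmt_fixed(ch$coverage_pct, 2),
      longest_mb = fmt_fixed(ch$longest_mb, 2),
      shortest_mb = fmt_fixed(ch$shortest_mb, 2)
    ), "chromosome_summary.tsv")
  }
  if (!is.null(results$profiles)) {
    pr <- results$profiles
    emit(tibble(
      individual_id = pr$individual_id,
      F_HOM = fmt_fixed(pr$f_hom, 4), F_ROH = fmt_fixed(pr$f_roh, 4),
      F_ROH_1_5 = fmt_fixed(pr$f_roh_1_5, 4),
      F_ROH_5_10 = fmt_fixed(pr$f_roh_5_10, 4),
      F_ROH_10_20 = fmt_fixed(pr$f_roh_10_20, 4),
      F_ROH_gt20 = fmt_fixed(pr$f_roh_gt20, 4)
    ), "inbreeding.tsv")
  }
  if (!is.null(results$correlations)) {
    co <- results$correlations
    emit(tibble(
      pair = paste(co$var_x, co$var_y, sep = "~"),
      r = fmt_fixed(co$r, 4), p_value = format(co$p_value, digits = 4),
      n = co$n
    ), "correlations.tsv")
  }
  if (!is.null(results$incidence)) {
    inc <- results$incidence
    emit(tibble(
      snp_id = inc$snp_id, chromosome = inc$chromosome,
      position_bp = inc$position_bp, n_in_roh = inc$n_in_roh,
      fraction_in_roh = fmt_fixed(inc$fraction_in_roh, 4)
    ), "snp_incidence.tsv")
  }
  if (!is.null(results$islands)) {
    isl <- results$islands
    emit(tibble(
      chromosome = isl$chromosome, start_bp = isl$start_bp,
      end_bp = isl$end_bp, length_bp = isl$length_bp, n_snps = isl$n_snps,
      n_genes = isl$n_genes %||% 0L,
      genes = vapply(isl$genes %||% rep(list(character()), nrow(isl)),
                     paste, character(1), collapse = ",")
    ), "islands.tsv")
    bed <- data.frame(isl$chromosome,
                      format(isl$start_bp - 1, scientific = FALSE, trim = TRUE),
                      format(isl$end_bp, scientific = FALSE, trim = TRUE),
                      paste0("roh_island_", seq_len(nrow(isl))))
    path <- file.path(out_dir, "islands.bed")
    write.table(bed, path, quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    written <- c(written, path)
  }
  if (!is.null(results$qc_report)) {
    emit(results$qc_report, "qc_report.tsv")
  }
  invisible(written)
}
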