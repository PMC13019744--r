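# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as naive enumerations so they share no code path
# with the package implementations they check.

make_panel <- function(geno, chromosome, position_bp, ids = NULL) {
  geno <- rbind(geno)
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(nrow(geno)))
  m <- ncol(geno)
  genotype_panel(
    geno,
    tibble::tibble(
      snp_id = sprintf("s%04d", seq_len(m)),
      chromosome = as.character(rep_len(chromosome, m)),
      position_bp = position_bp
    ),
    ids
  )
}

# closed-form conditional distribution of the heterozygote count given the
# allele counts (lgamma route, independent of the package's recurrence)
oracle_hwe <- function(n_hom_a, n_het, n_hom_b) {
  n <- n_hom_a + n_het + n_hom_b
  n_a <- 2 * n_hom_a + n_het
  n_b <- 2 * n_hom_b + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(list(het = 0, prob = 1, p_value = 1))
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- (2 * n - rare - h) / 2
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(lp)
  obs <- prob[match(n_het, hets)]
  list(het = hets, prob = prob,
       p_value = min(1, sum(prob[prob <= obs * (1 + 1e-12)])))
}

# naive per-window / per-SNP tally of the in-run mask
oracle_mask <- function(g, params) {
  m <- length(g)
  w <- params$window_snps
  frac <- numeric(m)
  if (m >= w) {
    nw <- m - w + 1
    hom_win <- logical(nw)
    for (s in seq_len(nw)) {
      win <- g[s:(s + w - 1)]
      hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$max_het_per_window &&
        sum(is.na(win)) <= params$max_missing_per_window
    }
    for (j in seq_len(m)) {
      ws <- max(1, j - w + 1):min(j, nw)
      frac[j] <- mean(hom_win[ws])
    }
  }
  frac > params$window_hit_threshold
}

# exhaustive-interval ROH oracle for one individual on one chromosome:
# enumerate every interval whose SNPs are all in-run, whose internal gaps
# respect the cap and whose endpoints are homozygous non-missing calls;
# keep maximal intervals, then apply the final length/count/density filters
oracle_detect_one <- function(g, pos, params, min_snps) {
  n <- length(g)
  mask <- oracle_mask(g, params)
  valid <- list()
  for (i in seq_len(n)) {
    if (!mask[i] || is.na(g[i]) || g[i] == 1) next
    j <- i
    best <- NA_integer_
    while (j <= n) {
      if (!mask[j]) break
      if (j > i && pos[j] - pos[j - 1] > params$max_gap_bp) break
      if (!is.na(g[j]) && g[j] != 1) best <- j
      j <- j + 1
    }
    if (!is.na(best)) valid[[length(valid) + 1]] <- c(i, best)
  }
  if (!length(valid)) return(NULL)
  iv <- do.call(rbind, valid)
  maximal <- vapply(seq_len(nrow(iv)), function(k) {
    !any(iv[, 1] <= iv[k, 1] & iv[, 2] >= iv[k, 2] &
           (iv[, 1] != iv[k, 1] | iv[, 2] != iv[k, 2]))
  }, logical(1))
  iv <- iv[maximal, , drop = FALSE]
  keep <- vapply(seq_len(nrow(iv)), function(k) {
    len <- pos[iv[k, 2]] - pos[iv[k, 1]] + 1
    cnt <- iv[k, 2] - iv[k, 1] + 1
    len >= params$min_length_bp && cnt >= min_snps &&
      len / cnt <= params$min_density_bp_per_snp
  }, logical(1))
  iv <- iv[keep, , drop = FALSE]
  if (!nrow(iv)) return(NULL)
  tibble::tibble(
    start_bp = pos[iv[, 1]], end_bp = pos[iv[, 2]],
    n_snps = iv[, 2] - iv[, 1] + 1L,
    length_bp = pos[iv[, 2]] - pos[iv[, 1]] + 1
  )
}

oracle_detect_roh <- function(panel, params, min_snps) {
  out <- list()
  for (ii in seq_len(n_individuals(panel))) {
    id <- panel$individuals$individual_id[ii]
    for (chrom in unique(panel$snps$chromosome)) {
      idx <- which(panel$snps$chromosome == chrom)
      seg <- oracle_detect_one(panel$geno[ii, idx],
                               panel$snps$position_bp[idx], params, min_snps)
      if (!is.null(seg)) {
        seg$individual_id <- id
        seg$chromosome <- chrom
        out[[length(out) + 1]] <- seg
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(individual_id = character(), chromosome = character(),
                          start_bp = double(), end_bp = double(),
                          n_snps = integer(), length_bp = double()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res[, c("individual_id", "chromosome", "start_bp", "end_bp",
                         "n_snps", "length_bp")],
                 individual_id, chromosome, start_bp)
}

# random small panel for oracle-equivalence sweeps: dense positions, high
# homozygosity so runs actually form
random_small_panel <- function(seed, max_snps = 200, max_ind = 5) {
  set.seed(seed)
  m <- sample(20:max_snps, 1)
  n <- sample(1:max_ind, 1)
  pos <- cumsum(sample(c(1e4, 4e4, 8e4, 1.5e6), m, replace = TRUE,
                       prob = c(0.4, 0.4, 0.15, 0.05)))
  g <- matrix(sample(c(0L, 1L, 2L, NA), n * m, replace = TRUE,
                     prob = c(0.55, 0.08, 0.32, 0.05)), n, m)
  make_panel(g, "1", pos)
}

# segment table fixture encoding the published per-class counts and totals
# (counts 1818/1056/554/194, totals 6070.26/7452.72/7663.09/5978.23 Mb
# across 380 individuals); per-class lengths are uniform at total/count
table1_fixture_segments <- function(n_individuals = 380) {
  counts <- c(1818L, 1056L, 554L, 194L)
  totals_mb <- c(6070.26, 7452.72, 7663.09, 5978.23)
  len_bp <- unlist(mapply(function(k, tot) rep(tot * 1e6 / k, k),
                          counts, totals_mb, SIMPLIFY = FALSE))
  n_seg <- sum(counts)
  tibble::tibble(
    individual_id = sprintf("goat_%03d", rep_len(seq_len(n_individuals), n_seg)),
    chromosome = "1",
    start_bp = 1,
    end_bp = len_bp,
    n_snps = pmax(2L, as.integer(len_bp / 5e4)),
    length_bp = len_bp
  )
}
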