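#' Quality-control thresholds
#'
#' Defaults follow standard chip QC for pig ssGBLUP analyses: SNPs are
#' dropped when unmapped or on a sex chromosome, when call rate < 0.95,
#' minor allele frequency < 0.01 or the 1-df Hardy-Weinberg goodness-of-fit
#' chi-square exceeds 600; animals are dropped when more than 5% of their
#' genotypes are missing.
#'
#' @param min_call_rate,min_maf,max_hwe_chi2,max_animal_missing numeric
#'   thresholds.
#' @param drop_unmapped,drop_sex_chromosomes logical flags.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                          max_hwe_chi2 = 600, max_animal_missing = 0.05,
                          drop_unmapped = TRUE, drop_sex_chromosomes = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 0.5,
            max_hwe_chi2 >= 0, max_animal_missing >= 0, max_animal_missing <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_hwe_chi2 = max_hwe_chi2,
                 max_animal_missing = max_animal_missing,
                 drop_unmapped = isTRUE(drop_unmapped),
                 drop_sex_chromosomes = isTRUE(drop_sex_chromosomes)),
            class = "qc_thresholds")
}

#' Hardy-Weinberg goodness-of-fit chi-square
#'
#' 1-df chi-square of observed genotype counts against Hardy-Weinberg
#' expectations `(n p^2, 2 n p q, n q^2)` with the allele frequency estimated
#' from the sample. Monomorphic SNPs return 0 by convention (they are removed
#' by the MAF filter instead). All three arguments are vectorised.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return Chi-square statistic(s).
#' @examples
#' hwe_chi2(25, 50, 25)  # exact HWE proportions -> 0
#' hwe_chi2(30, 40, 30)  # 4
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0)) stop_wssgwas("total genotype count must be positive", "qc_invalid")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  exp_AA <- n * p^2
  exp_Aa <- 2 * n * p * q
  exp_aa <- n * q^2
  chi2 <- ifelse(p %in% c(0, 1), 0,
                 (n_AA - exp_AA)^2 / exp_AA +
                 (n_Aa - exp_Aa)^2 / exp_Aa +
                 (n_aa - exp_aa)^2 / exp_aa)
  unname(chi2)
}

#' Apply genotype quality control
#'
#' Filters are applied in a fixed, logged order: (1) unmapped / sex
#' chromosome SNPs, (2) SNP call rate, (3) minor allele frequency, (4) HWE
#' chi-square, (5) animal missingness. Surviving missing genotypes are
#' mean-imputed (filled with `2p` per SNP) and allele frequencies are
#' recomputed on the surviving panel, so the result has no missing entries.
#' Re-applying QC to its own output removes nothing.
#'
#' @param panel a [genotype_panel()] (may contain `NA` calls).
#' @param thresholds a [qc_thresholds()].
#' @return List with `panel` (clean panel, `freq` populated) and `report`
#'   (tibble: `rule`, `snps_removed`, `animals_removed`).
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$geno
  map <- panel$map
  report <- list()
  note <- function(rule, s = 0L, a = 0L) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      rule = rule, snps_removed = as.integer(s), animals_removed = as.integer(a))
  }

  sexchr <- c("X", "Y", "x", "y", "23", "chrX", "chrY")
  drop1 <- logical(ncol(g))
  if (thresholds$drop_unmapped) drop1 <- drop1 | is.na(map$chrom) | is.na(map$pos)
  if (thresholds$drop_sex_chromosomes) drop1 <- drop1 | map$chrom %in% sexchr
  note("unmapped_or_sex_chromosome", sum(drop1))
  g <- g[, !drop1, drop = FALSE]; map <- map[!drop1, , drop = FALSE]

  call_rate <- colMeans(!is.na(g))
  drop2 <- call_rate < thresholds$min_call_rate
  note("snp_call_rate", sum(drop2))
  g <- g[, !drop2, drop = FALSE]; map <- map[!drop2, , drop = FALSE]

  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop3 <- maf < thresholds$min_maf
  note("maf", sum(drop3))
  g <- g[, !drop3, drop = FALSE]; map <- map[!drop3, , drop = FALSE]

  if (ncol(g)) {
    counts2 <- colSums(g == 2L, na.rm = TRUE)
    counts1 <- colSums(g == 1L, na.rm = TRUE)
    counts0 <- colSums(g == 0L, na.rm = TRUE)
    chi2 <- hwe_chi2(counts2, counts1, counts0)
    drop4 <- chi2 > thresholds$max_hwe_chi2
  } else drop4 <- logical(0)
  note("hwe_chi2", sum(drop4))
  g <- g[, !drop4, drop = FALSE]; map <- map[!drop4, , drop = FALSE]

  miss_animal <- if (ncol(g)) rowMeans(is.na(g)) else rep(0, nrow(g))
  drop5 <- miss_animal > thresholds$max_animal_missing
  note("animal_missingness", 0L, sum(drop5))
  g <- g[!drop5, , drop = FALSE]

  report <- dplyr::bind_rows(report)
  if (ncol(g) == 0L) {
    stop_wssgwas(paste0("all SNPs removed by QC; removals per rule: ",
                        paste(report$rule, report$snps_removed, sep = "=", collapse = ", ")),
                 "qc_all_removed")
  }
  # recompute frequencies on survivors, then mean-impute remaining holes
  p <- colMeans(g, na.rm = TRUE) / 2
  if (anyNA(g)) {
    for (j in which(colSums(is.na(g)) > 0L)) {
      g[is.na(g[, j]), j] <- 2 * p[j]
    }
  }
  # imputed entries are fractional (2p), so bypass the 0/1/2 code check
  out <- structure(list(geno = g, map = map,
                        freq = stats::setNames(p, map$snp)),
                   class = "genotype_panel")
  bf <- attr(panel, "base_freq")
  if (!is.null(bf)) attr(out, "base_freq") <- bf[map$snp]
  list(panel = out, report = report)
}

#' Centered gene contents
#'
#' Column `j` of the result is the raw code minus `2 p_j`, where `p_j` is the
#' counted-allele frequency, so each column has (near) zero mean over the
#' genotyped animals. Requires a panel without missing entries (run
#' [apply_qc()] first).
#'
#' With observed (panel-derived) frequencies the columns sum to exactly zero,
#' which makes the unblended genomic relationship matrix singular (the ones
#' vector is in its null space); supply base-population frequencies via
#' `freq` when an invertible unblended G is required.
#'
#' @param panel a QC'd [genotype_panel()] with `freq` populated (frequencies
#'   are computed from the panel when absent).
#' @param freq optional frequency vector overriding the panel's (e.g.
#'   base-population frequencies).
#' @return Dense numeric matrix of centered gene contents.
#' @export
center_gene_content <- function(panel, freq = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (anyNA(panel$geno)) {
    stop_wssgwas("panel has missing entries; run apply_qc() (mean fill) first",
                 "geno_missing")
  }
  p <- freq %||% panel$freq %||% allele_freqs(panel)
  stopifnot(length(p) == ncol(panel$geno))
  sweep(panel$geno, 2, 2 * p)
}

#' Write a QC report TSV
#'
#' @param report the report tibble from [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
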