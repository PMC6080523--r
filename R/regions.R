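#' Select relevant SNP windows
#'
#' Keeps windows explaining at least `threshold_pct` of the genetic variance
#' (boundary inclusive: "1% or more"). The default 1% equals 50 times the
#' expected contribution of one window in a genome of ~4000-4500 windows
#' under equal contributions.
#'
#' @param windows window tibble with a `pct_variance` column (and ideally a
#'   `trait` column, as from `tidy(<wssgwas_fit>)`).
#' @param threshold_pct selection threshold in percent.
#' @return The selected rows (possibly empty).
#' @export
select_windows <- function(windows, threshold_pct = 1.0) {
  windows[windows$pct_variance >= threshold_pct, , drop = FALSE]
}

#' Expected per-window variance contribution
#'
#' Under equal contributions of all windows, each explains `100 / n_windows`
#' percent of the genetic variance; the customary selection threshold is a
#' multiple of this expectation.
#'
#' @param n_windows number of SNP windows in the genome.
#' @param multiple threshold multiple (default 50).
#' @return Tibble with `expected_pct` and `threshold_pct`.
#' @export
window_expectation <- function(n_windows, multiple = 50) {
  expected <- 100 / n_windows
  tibble::tibble(n_windows = n_windows, expected_pct = expected,
                 threshold_pct = multiple * expected)
}

# Internal: single-linkage clusters of midpoints on one chromosome,
# strictly-less-than gap rule.
cluster_midpoints <- function(midpoint, max_gap_bp) {
  ord <- order(midpoint)
  gaps <- diff(midpoint[ord])
  cl_sorted <- cumsum(c(1L, as.integer(!(gaps < max_gap_bp))))
  cl <- integer(length(midpoint))
  cl[ord] <- cl_sorted
  cl
}

#' Merge overlapping selected windows into QTL regions
#'
#' Windows (within one population, across its traits) are considered to
#' overlap when their midpoints are strictly less than `max_midpoint_gap_bp`
#' apart on the same chromosome; chains are merged transitively (single
#' linkage). Each cluster becomes one QTL region spanning the members' first
#' to last SNP positions, with per-trait variance percentages carried along.
#'
#' @param selected selected window tibble (columns `trait`, `chrom`,
#'   `start_pos`, `end_pos`, `midpoint`, `pct_variance`, optionally
#'   `n_snps`).
#' @param max_midpoint_gap_bp midpoint distance rule (default 400 kb,
#'   strict `<`).
#' @param population optional population label attached to the regions.
#' @return Tibble of regions: `region_id`, `chrom`, `start`, `end`,
#'   `n_windows`, `n_snps`, `traits` (comma-separated), `population`, plus
#'   list columns `members` (the member windows) and `pct_by_trait` (named
#'   per-trait maximum percentage).
#' @export
overlap_windows <- function(selected, max_midpoint_gap_bp = 400000,
                            population = NA_character_) {
  if (!nrow(selected)) {
    return(tibble::tibble(region_id = integer(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          n_windows = integer(0), n_snps = integer(0),
                          traits = character(0), population = character(0),
                          members = list(), pct_by_trait = list()))
  }
  if (!"trait" %in% names(selected)) selected$trait <- "trait"
  selected <- dplyr::arrange(selected, .data$chrom, .data$midpoint, .data$trait)
  selected$.cluster <- NA_integer_
  base <- 0L
  for (ch in unique(selected$chrom)) {
    rows <- which(selected$chrom == ch)
    cl <- cluster_midpoints(selected$midpoint[rows], max_midpoint_gap_bp)
    selected$.cluster[rows] <- base + cl
    base <- base + max(cl)
  }
  groups <- split(seq_len(nrow(selected)), selected$.cluster)
  regions <- lapply(seq_along(groups), function(k) {
    mem <- selected[groups[[k]], , drop = FALSE]
    mem$.cluster <- NULL
    pct <- vapply(split(mem$pct_variance, mem$trait), max, numeric(1))
    tibble::tibble(
      region_id = k, chrom = mem$chrom[1],
      start = min(mem$start_pos), end = max(mem$end_pos),
      n_windows = nrow(mem),
      n_snps = if ("n_snps" %in% names(mem)) sum(mem$n_snps) else NA_integer_,
      traits = paste(sort(unique(mem$trait)), collapse = ","),
      population = population,
      members = list(mem), pct_by_trait = list(pct))
  })
  dplyr::bind_rows(regions)
}

#' Top windows per trait with flanking regions
#'
#' The `k` windows with the highest variance percentage per trait; each
#' becomes a region `[midpoint - flank_bp, midpoint + flank_bp]`, clipped at
#' position 0. Ties at rank `k` break deterministically by (chromosome,
#' position). When a trait has fewer than `k` windows, all are returned and
#' the result is flagged.
#'
#' @param windows window tibble (with `trait`, `chrom`, `midpoint`,
#'   `pct_variance`).
#' @param k number of windows per trait (default 3).
#' @param flank_bp flank on either side of the window midpoint (default
#'   400 kb).
#' @return Tibble with one row per selected window: `trait`, `rank`,
#'   `chrom`, `midpoint`, `pct_variance`, `start`, `end`, `flagged_short`.
#' @export
top_windows_with_flanks <- function(windows, k = 3L, flank_bp = 400000) {
  if (!"trait" %in% names(windows)) windows$trait <- "trait"
  out <- lapply(split(windows, windows$trait), function(w) {
    w <- w[order(-w$pct_variance, w$chrom, w$midpoint), , drop = FALSE]
    short <- nrow(w) < k
    if (short) {
      rlang::warn(paste0("trait ", w$trait[1], ": only ", nrow(w),
                         " windows available (requested ", k, ")"))
    }
    w <- utils::head(w, k)
    tibble::tibble(
      trait = w$trait, rank = seq_len(nrow(w)), chrom = w$chrom,
      midpoint = w$midpoint, pct_variance = w$pct_variance,
      start = pmax(w$midpoint - flank_bp, 0), end = w$midpoint + flank_bp,
      flagged_short = short)
  })
  dplyr::bind_rows(out)
}

#' Cross-population window overlap
#'
#' For one trait analysed in two populations, reports every pair of selected
#' windows on the same chromosome whose midpoints are strictly less than
#' `max_midpoint_gap_bp` apart. An empty result is a valid, reportable
#' outcome.
#'
#' @param selected_pop1,selected_pop2 selected window tibbles of the two
#'   populations (same trait).
#' @param max_midpoint_gap_bp midpoint distance rule (strict `<`).
#' @return Tibble of pairs: `chrom`, `midpoint_pop1`, `midpoint_pop2`,
#'   `distance_bp`, `pct_pop1`, `pct_pop2`.
#' @export
cross_population_overlap <- function(selected_pop1, selected_pop2,
                                     max_midpoint_gap_bp = 400000) {
  empty <- tibble::tibble(chrom = character(0), midpoint_pop1 = numeric(0),
                          midpoint_pop2 = numeric(0), distance_bp = numeric(0),
                          pct_pop1 = numeric(0), pct_pop2 = numeric(0))
  if (!nrow(selected_pop1) || !nrow(selected_pop2)) return(empty)
  pairs <- merge(
    data.frame(chrom = selected_pop1$chrom, midpoint_pop1 = selected_pop1$midpoint,
               pct_pop1 = selected_pop1$pct_variance),
    data.frame(chrom = selected_pop2$chrom, midpoint_pop2 = selected_pop2$midpoint,
               pct_pop2 = selected_pop2$pct_variance),
    by = "chrom")
  pairs$distance_bp <- abs(pairs$midpoint_pop1 - pairs$midpoint_pop2)
  pairs <- pairs[pairs$distance_bp < max_midpoint_gap_bp, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  tibble::as_tibble(pairs[order(pairs$chrom, pairs$midpoint_pop1),
                          c("chrom", "midpoint_pop1", "midpoint_pop2",
                            "distance_bp", "pct_pop1", "pct_pop2")])
}

#' Write a QTL-region report TSV
#'
#' Columns: chromosome, region in Mb (1-based inclusive bp underneath), SNP
#' count, traits, per-trait variance percentages and candidate genes (when
#' annotated).
#'
#' @param regions region tibble from [overlap_windows()] (optionally after
#'   [genes_in_region()]).
#' @param path output path.
#' @export
write_region_report <- function(regions, path) {
  tab <- tibble::tibble(
    chrom = regions$chrom,
    region_mb = sprintf("%.2f-%.2f", regions$start / 1e6, regions$end / 1e6),
    start_bp = regions$start, end_bp = regions$end,
    n_snps = regions$n_snps, traits = regions$traits,
    pct_by_trait = vapply(regions$pct_by_trait, function(p) {
      paste(sprintf("%s=%.2f", names(p), p), collapse = ";")
    }, character(1)),
    genes = if ("genes" %in% names(regions)) {
      vapply(regions$genes, function(g) paste(g$gene_id, collapse = ","),
             character(1))
    } else NA_character_
  )
  readr::write_tsv(tab, path)
  invisible(path)
}
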