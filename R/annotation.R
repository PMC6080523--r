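#' Read a gene annotation (BED or GFF)
#'
#' BED (3+ columns, 0-based half-open) is parsed directly; GFF3/GTF go
#' through `rtracklayer::import()`, keeping `gene` features when present.
#' All coordinates are returned 1-based inclusive.
#'
#' @param path annotation file; format inferred from the extension
#'   (`.bed`, `.gff`, `.gff3`, `.gtf`).
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, `name`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) {
    stop_wssgwas(paste0("annotation file not found: ", path), "io_missing_file")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols(.default = "c"))
    if (ncol(raw) < 3) stop_wssgwas("BED needs at least 3 columns", "io_parse")
    tibble::tibble(
      chrom = raw[[1]],
      start = as.integer(raw[[2]]) + 1L,   # BED 0-based half-open -> 1-based
      end = as.integer(raw[[3]]),
      gene_id = if (ncol(raw) >= 4) raw[[4]] else paste0("feature", seq_len(nrow(raw))),
      name = if (ncol(raw) >= 4) raw[[4]] else paste0("feature", seq_len(nrow(raw)))
    )
  } else if (ext %in% c("gff", "gff3", "gtf")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop_wssgwas("rtracklayer is required to read GFF/GTF", "io_parse")
    }
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    meta <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else
      if ("gene_id" %in% names(meta)) as.character(meta$gene_id) else
        paste0("feature", seq_along(gr))
    nm <- if ("Name" %in% names(meta)) as.character(meta$Name) else ids
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      gene_id = ids, name = nm
    )
  } else {
    stop_wssgwas(paste0("unrecognised annotation extension: .", ext), "io_parse")
  }
}

#' Genes overlapping QTL regions
#'
#' Intersects each region `[start, end]` (1-based inclusive bp) with the
#' gene annotation, ignoring strand. Uses `GenomicRanges::findOverlaps()`.
#' Annotation chromosome names must cover the regions' chromosomes.
#'
#' @param regions region tibble with `chrom`, `start`, `end` (e.g. from
#'   [overlap_windows()] or [top_windows_with_flanks()]).
#' @param annotation gene tibble from [read_gene_annotation()] or
#'   [simulate_gene_annotation()].
#' @return `regions` with an added list column `genes` (tibble of hits per
#'   region) and an integer `n_genes` column.
#' @export
genes_in_region <- function(regions, annotation) {
  if (!nrow(regions)) {
    regions$genes <- list(); regions$n_genes <- integer(0)
    return(regions)
  }
  missing_chr <- setdiff(unique(regions$chrom), unique(annotation$chrom))
  if (length(missing_chr)) {
    stop_wssgwas(paste0("annotation lacks chromosome(s): ",
                        paste(missing_chr, collapse = ", ")), "chrom_mismatch")
  }
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = pmax(round(regions$start), 1), end = round(regions$end)))
  ann_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(start = annotation$start, end = annotation$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, ann_gr, ignore.strand = TRUE)
  by_region <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  regions$genes <- lapply(seq_len(nrow(regions)), function(i) {
    idx <- by_region[[as.character(i)]]
    if (is.null(idx)) annotation[0, , drop = FALSE] else
      annotation[sort(idx), , drop = FALSE]
  })
  regions$n_genes <- vapply(regions$genes, nrow, integer(1))
  regions
}
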