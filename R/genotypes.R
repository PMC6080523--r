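#' Genotype panel
#'
#' Container for SNP gene contents and their map. Gene contents are coded
#' 0/1/2 copies of the counted allele (`NA` = missing); the map gives one row
#' per SNP, sorted by (chromosome, position), positions 1-based inclusive bp.
#'
#' @param geno integer/numeric matrix, animals in rows (rownames = ids),
#'   SNPs in columns (colnames = SNP ids), values in `{0, 1, 2, NA}`.
#' @param map tibble with columns `snp`, `chrom`, `pos` matching `geno`
#'   columns.
#' @param freq optional per-SNP counted-allele frequencies (computed lazily
#'   by [allele_freqs()] otherwise).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, map, freq = NULL) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == nrow(map), all(c("snp", "chrom", "pos") %in% names(map)))
  map <- tibble::as_tibble(map)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (is.null(colnames(geno))) colnames(geno) <- map$snp
  if (!identical(colnames(geno), as.character(map$snp))) {
    geno <- geno[, as.character(map$snp), drop = FALSE]
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad)) stop_wssgwas("gene contents must be 0, 1, 2 or NA", "geno_invalid")
  structure(list(geno = geno, map = map, freq = freq), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$geno), " animals x ", ncol(x$geno), " SNPs on ",
      length(unique(x$map$chrom)), " chromosome(s); ",
      sum(is.na(x$geno)), " missing calls\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

#' Subset a panel to a set of animals
#'
#' @param panel a [genotype_panel()].
#' @param ids animal ids to keep (order preserved).
#' @return A `genotype_panel` over those animals; allele frequencies are
#'   dropped (recompute on the subset).
#' @export
subset_panel <- function(panel, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, rownames(panel$geno))
  if (length(missing)) {
    stop_wssgwas(paste0("animals not in panel: ", paste(head(missing, 10), collapse = ", ")),
                 "ids_missing")
  }
  out <- genotype_panel(panel$geno[ids, , drop = FALSE], panel$map)
  bf <- attr(panel, "base_freq")
  if (!is.null(bf)) attr(out, "base_freq") <- bf[out$map$snp]
  out
}

#' Counted-allele frequencies
#'
#' Frequency of the counted allele per SNP, computed over non-missing calls.
#'
#' @param panel a [genotype_panel()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_freqs <- function(panel) {
  f <- colMeans(panel$geno, na.rm = TRUE) / 2
  stats::setNames(f, panel$map$snp)
}

#' Read and write PLINK-style text genotypes
#'
#' Minimal reader/writer for the whitespace-delimited `.ped`/`.map` pair:
#' `.map` columns are chromosome, SNP id, genetic distance (ignored), bp
#' position; `.ped` rows are FID IID PAT MAT SEX PHENO followed by two allele
#' columns per SNP, alleles coded `A`/`B` (or `1`/`2`), `0` = missing. Gene
#' content is the count of the `B` (second) allele.
#'
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are used.
#' @return `read_plink()`: a [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) stop_wssgwas(paste0("file not found: ", p), "io_missing_file")
  }
  map_raw <- readr::read_table(map_path,
    col_names = c("chrom", "snp", "cm", "pos"),
    col_types = readr::cols(chrom = "c", snp = "c", cm = "d", pos = "i"))
  fields <- strsplit(trimws(readr::read_lines(ped_path)), "\\s+")
  m <- nrow(map_raw)
  geno <- matrix(NA_integer_, length(fields), m)
  ids <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 6 + 2 * m) {
      stop_wssgwas(paste0(".ped row ", i, " has ", length(f), " fields, expected ",
                          6 + 2 * m), "io_parse")
    }
    ids[i] <- f[2]
    a1 <- f[seq(7, by = 2, length.out = m)]
    a2 <- f[seq(8, by = 2, length.out = m)]
    miss <- a1 == "0" | a2 == "0"
    g <- (a1 %in% c("B", "2")) + (a2 %in% c("B", "2"))
    g[miss] <- NA_integer_
    geno[i, ] <- g
  }
  rownames(geno) <- ids
  colnames(geno) <- map_raw$snp
  genotype_panel(geno, tibble::tibble(snp = map_raw$snp, chrom = map_raw$chrom,
                                      pos = map_raw$pos))
}

#' @rdname read_plink
#' @param panel a [genotype_panel()].
#' @export
write_plink <- function(panel, prefix) {
  map <- panel$map
  readr::write_delim(
    tibble::tibble(chrom = map$chrom, snp = map$snp, cm = 0, pos = map$pos),
    paste0(prefix, ".map"), col_names = FALSE)
  g <- panel$geno
  alleles <- function(x) {
    out <- matrix("0", length(x), 2)
    out[which(x == 0), ] <- "A"
    out[which(x == 2), ] <- "B"
    out[which(x == 1), 1] <- "A"
    out[which(x == 1), 2] <- "B"
    out
  }
  lines <- vapply(seq_len(nrow(g)), function(i) {
    al <- alleles(g[i, ])
    paste(c(rownames(g)[i], rownames(g)[i], "0", "0", "0", "-9",
            as.vector(t(al))), collapse = " ")
  }, character(1))
  readr::write_lines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read an additive-coded genotype table
#'
#' Tab-separated text: first column `animal`, remaining columns one per SNP
#' holding 0/1/2 codes (`NA` or empty = missing), plus a companion map file
#' as in [read_plink()].
#'
#' @param geno_path path to the genotype TSV.
#' @param map_path path to the `.map` file.
#' @return A [genotype_panel()].
#' @export
read_geno_table <- function(geno_path, map_path) {
  for (p in c(geno_path, map_path)) {
    if (!file.exists(p)) stop_wssgwas(paste0("file not found: ", p), "io_missing_file")
  }
  tab <- readr::read_tsv(geno_path, col_types = readr::cols(animal = "c", .default = "i"))
  map_raw <- readr::read_table(map_path,
    col_names = c("chrom", "snp", "cm", "pos"),
    col_types = readr::cols(chrom = "c", snp = "c", cm = "d", pos = "i"))
  geno <- as.matrix(tab[, -1, drop = FALSE])
  rownames(geno) <- tab$animal
  genotype_panel(geno, tibble::tibble(snp = map_raw$snp, chrom = map_raw$chrom,
                                      pos = map_raw$pos))
}

#' Dump a relationship matrix as TSV
#'
#' Debug export: animal ids in the first column, one column per animal.
#'
#' @param mat relationship matrix with id dimnames (A, G, H inverse, ...).
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  tab <- tibble::as_tibble(as.data.frame(mat), rownames = "animal")
  readr::write_tsv(tab, path)
  invisible(path)
}
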