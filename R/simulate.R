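#' Simulation configuration
#'
#' Parameters of the synthetic breeding-population generator. Defaults
#' emulate a desk-scale boar AI population: a few hundred animals over three
#' generations, a chip-density SNP panel with ~0.4 Mb haplotype-block LD,
#' a low-to-moderate-heritability repeated-record trait with a permanent
#' environment component, contemporary-group fixed effects and two
#' record-level covariates (collection interval in days, boar age in months),
#' and deliberately partial genotyping/phenotyping.
#'
#' One seed governs all stages: pedigree, genotypes, phenotypes and sampling
#' of the genotyped set consume `seed + 1 .. seed + 4` respectively, so a
#' stage can be re-run in isolation yet the whole dataset is reproducible.
#'
#' @param seed integer master seed.
#' @param n_founders,n_generations,n_animals_target pedigree size controls.
#' @param n_chromosomes,chrom_length_bp,n_snps genome layout.
#' @param block_size_bp haplotype-block size in bp (default 400 kb, the
#'   average block size reported for commercial pig lines; also the SNP
#'   window span used downstream).
#' @param n_qtl,qtl_variance_fractions number of QTL and the fraction of the
#'   additive variance each explains (remainder is polygenic).
#' @param h2 narrow-sense heritability (0 < h2 <= rep < 1).
#' @param rep repeatability, (sigma2_a + sigma2_p) / sigma2_phenotypic.
#' @param records_per_animal integer range `c(lo, hi)` of ejaculate records
#'   per phenotyped boar.
#' @param n_fixed_groups number of contemporary-group levels.
#' @param covariate_effects slopes (phenotypic-SD units per SD of covariate)
#'   for collection interval and age.
#' @param prop_genotyped,prop_phenotyped sampling proportions.
#' @param polygene how the polygenic background is realized: `"snp"`
#'   (default) spreads it over all non-QTL SNPs with equal expected variance
#'   per SNP (infinitesimal architecture, transmitted through the pedigree by
#'   gene dropping); `"pedigree"` draws a SNP-free additive effect down the
#'   pedigree (parent average plus Mendelian sampling), leaving the marker
#'   panel uninformative about it.
#' @param qc_violations inject low-MAF, low-call-rate and HWE-violating SNPs
#'   plus a high-missingness animal, to exercise quality control.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 40L,
                       n_generations = 3L,
                       n_animals_target = 400L,
                       n_chromosomes = 3L,
                       chrom_length_bp = 40e6,
                       n_snps = 2000L,
                       block_size_bp = 400000L,
                       n_qtl = 3L,
                       qtl_variance_fractions = c(0.10, 0.05, 0.05),
                       h2 = 0.21,
                       rep = 0.45,
                       records_per_animal = c(10L, 50L),
                       n_fixed_groups = 10L,
                       covariate_effects = c(interval = 0.10, age = 0.05),
                       prop_genotyped = 0.5,
                       prop_phenotyped = 0.5,
                       polygene = c("snp", "pedigree"),
                       qc_violations = FALSE) {
  polygene <- match.arg(polygene)
  cfg <- list(
    seed = as.integer(seed), n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_animals_target = as.integer(n_animals_target),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_snps = as.integer(n_snps), block_size_bp = as.numeric(block_size_bp),
    n_qtl = as.integer(n_qtl),
    qtl_variance_fractions = as.numeric(qtl_variance_fractions),
    h2 = h2, rep = rep,
    records_per_animal = as.integer(records_per_animal),
    n_fixed_groups = as.integer(n_fixed_groups),
    covariate_effects = covariate_effects,
    prop_genotyped = prop_genotyped, prop_phenotyped = prop_phenotyped,
    polygene = polygene,
    qc_violations = isTRUE(qc_violations)
  )
  if (!(cfg$h2 > 0 && cfg$h2 <= cfg$rep && cfg$rep < 1)) {
    stop_wssgwas("need 0 < h2 <= rep < 1", "config_invalid")
  }
  if (length(cfg$qtl_variance_fractions) != cfg$n_qtl) {
    stop_wssgwas("qtl_variance_fractions must have length n_qtl", "config_invalid")
  }
  if (sum(cfg$qtl_variance_fractions) > 1) {
    stop_wssgwas("QTL variance fractions sum above 1", "config_invalid")
  }
  if (cfg$block_size_bp <= 0) stop_wssgwas("block_size_bp must be positive", "config_invalid")
  if (!(cfg$prop_genotyped > 0 && cfg$prop_genotyped <= 1 &&
        cfg$prop_phenotyped > 0 && cfg$prop_phenotyped <= 1)) {
    stop_wssgwas("prop_genotyped, prop_phenotyped must be in (0, 1]", "config_invalid")
  }
  if (length(cfg$records_per_animal) == 1L) {
    cfg$records_per_animal <- rep(cfg$records_per_animal, 2L)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a pedigree
#'
#' Discrete generations: founders (unknown parents, alternating sexes), then
#' each generation's offspring drawn from random sire x dam pairs of the
#' previous generation. Rows are parent-first ordered by construction.
#'
#' @param config a [sim_config()].
#' @return A pedigree tibble with extra columns `sex` ("M"/"F") and
#'   `generation`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_founders < 2L) {
    stop_wssgwas("need at least 2 founders (one of each sex)", "sim_infeasible")
  }
  if (config$n_generations < 1L) stop_wssgwas("need n_generations >= 1", "config_invalid")
  n_off_per_gen <- ceiling(max(config$n_animals_target - config$n_founders, 1) /
                             config$n_generations)
  if (config$n_generations > 1L && n_off_per_gen < 2L) {
    stop_wssgwas("fewer than 2 offspring per generation: later matings impossible",
                 "sim_infeasible")
  }
  withr::with_seed(config$seed + 1L, {
    counter <- 0L
    new_id <- function(k) {
      ids <- sprintf("A%05d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
    f_ids <- new_id(config$n_founders)
    sexes <- rep(c("M", "F"), length.out = config$n_founders)
    rows <- list(tibble::tibble(animal = f_ids, sire = NA_character_,
                                dam = NA_character_, sex = sexes, generation = 0L))
    prev <- rows[[1]]
    for (g in seq_len(config$n_generations)) {
      sires <- prev$animal[prev$sex == "M"]
      dams  <- prev$animal[prev$sex == "F"]
      if (!length(sires) || !length(dams)) {
        stop_wssgwas(paste0("generation ", g - 1L, " has a single sex; mating impossible"),
                     "sim_infeasible")
      }
      k <- n_off_per_gen
      off <- tibble::tibble(
        animal = new_id(k),
        sire = sample(sires, k, replace = TRUE),
        dam  = sample(dams,  k, replace = TRUE),
        sex = if (k >= 2) c("M", "F", sample(c("M", "F"), k - 2, replace = TRUE))
              else sample(c("M", "F"), k),
        generation = g
      )
      rows[[g + 1L]] <- off
      prev <- off
    }
    ped <- dplyr::bind_rows(rows)
    out <- pedigree(ped$animal, ped$sire, ped$dam)
    out$sex <- ped$sex
    out$generation <- ped$generation
    out
  })
}

# Internal: gamete from parent haplotypes h1, h2 (vectors over all SNPs),
# one crossover per chromosome placed uniformly over block boundaries.
gamete_from <- function(h1, h2, chrom, block) {
  out <- integer(length(h1))
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    b <- block[j]
    boundaries <- which(diff(b) != 0)   # crossover allowed after these offsets
    start_hap <- sample(c(1L, 2L), 1L)
    seg <- rep(start_hap, length(j))
    if (length(boundaries)) {
      cut <- sample(boundaries, 1L)
      seg[(cut + 1L):length(j)] <- 3L - start_hap
    }
    out[j] <- ifelse(seg == 1L, h1[j], h2[j])
  }
  out
}

#' Simulate LD-structured genotypes by gene dropping
#'
#' Founder haplotypes are drawn with block-correlated alleles: SNP
#' frequencies are uniform on (0.05, 0.5) and, within each ~`block_size_bp`
#' haplotype block, alleles of one haplotype share a common latent uniform
#' (a small fraction of SNPs is redrawn independently so LD is strong but
#' imperfect). Descendant haplotypes are produced by gene dropping with one
#' crossover per chromosome per meiosis, uniform over block boundaries.
#'
#' @param ped an ordered pedigree (from [simulate_pedigree()] or compatible).
#' @param config a [sim_config()].
#' @return A [genotype_panel()] covering every pedigree animal, with the
#'   founder haplotypes retained in attribute `"haplotypes"`.
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_pedigree(ped)
  if (config$n_snps < config$n_chromosomes) {
    stop_wssgwas("n_snps must be at least n_chromosomes", "config_invalid")
  }
  withr::with_seed(config$seed + 2L, {
    per_chr <- diff(round(seq(0, config$n_snps, length.out = config$n_chromosomes + 1)))
    map <- dplyr::bind_rows(lapply(seq_len(config$n_chromosomes), function(ch) {
      pos <- sort(sample.int(config$chrom_length_bp, per_chr[ch]))
      tibble::tibble(snp = sprintf("c%ds%05d", ch, seq_along(pos)),
                     chrom = as.character(ch), pos = as.integer(pos))
    }))
    m <- nrow(map)
    block <- paste0(map$chrom, "_", (map$pos - 1) %/% config$block_size_bp)
    block_id <- match(block, unique(block))
    p <- runif(m, 0.05, 0.5)

    n <- nrow(ped)
    idx <- stats::setNames(seq_len(n), ped$animal)
    H1 <- matrix(0L, n, m)
    H2 <- matrix(0L, n, m)
    n_blocks <- max(block_id)
    draw_founder_hap <- function() {
      u <- runif(n_blocks)[block_id]
      base <- as.integer(u < p)
      redo <- runif(m) < 0.15
      base[redo] <- as.integer(runif(sum(redo)) < p[redo])
      base
    }
    si <- unname(idx[ped$sire])
    di <- unname(idx[ped$dam])
    for (i in seq_len(n)) {
      H1[i, ] <- if (is.na(si[i])) draw_founder_hap() else
        gamete_from(H1[si[i], ], H2[si[i], ], map$chrom, block_id)
      H2[i, ] <- if (is.na(di[i])) draw_founder_hap() else
        gamete_from(H1[di[i], ], H2[di[i], ], map$chrom, block_id)
    }
    geno <- H1 + H2
    rownames(geno) <- ped$animal
    colnames(geno) <- map$snp

    if (config$qc_violations) {
      k <- max(2L, m %/% 100L)
      low_maf <- sample.int(m, k)
      geno[, low_maf] <- 0L
      geno[sample.int(n, min(n, 2L)), low_maf] <- 1L   # MAF ~ 1/n
      low_call <- sample(setdiff(seq_len(m), low_maf), k)
      for (s in low_call) geno[runif(n) < 0.10, s] <- NA_integer_
      hwe_bad <- sample(setdiff(seq_len(m), c(low_maf, low_call)), k)
      for (s in hwe_bad) {
        het <- which(geno[, s] == 1L)
        geno[het, s] <- 2L * rbinom(length(het), 1L, 0.5)  # het deficit
      }
      bad_animal <- sample.int(n, 1L)
      geno[bad_animal, runif(m) < 0.06] <- NA_integer_
    }
    panel <- genotype_panel(geno, map)
    attr(panel, "haplotypes") <- list(H1 = H1, H2 = H2)
    # founder (base-population) allele frequencies: the theoretically correct
    # centering for VanRaden G, under which the unblended G is invertible
    attr(panel, "base_freq") <- stats::setNames(p, map$snp)
    panel
  })
}

#' Simulate repeated-record phenotypes
#'
#' Each phenotyped boar receives a negative-binomial-like number of records
#' (clipped to `records_per_animal`). A record is the sum of a
#' contemporary-group effect, two covariate terms, the animal's true breeding
#' value (QTL part plus pedigree-transmitted polygenic part), its permanent
#' environment effect and a residual. The phenotypic variance is 1, so
#' `sigma2_a = h2`, `sigma2_p = rep - h2`, `sigma2_e = 1 - rep`.
#'
#' @param ped pedigree with optional `sex` column (phenotyped animals are
#'   sampled among males when present).
#' @param panel full-population [genotype_panel()] (QTL gene contents are
#'   read from it).
#' @param config a [sim_config()].
#' @return A list with `records` (tibble: `animal`, `record_id`, `trait`,
#'   `fixed_group`, `interval_days`, `age_months`, `value`) and `truth`
#'   (true breeding values, permanent-environment effects, QTL table and the
#'   true variance components).
#' @export
simulate_phenotypes <- function(ped, panel, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$h2 <= 0) stop_wssgwas("h2 = 0: model unidentifiable downstream", "config_invalid")
  s2a <- config$h2
  s2p <- config$rep - config$h2
  s2e <- 1 - config$rep
  withr::with_seed(config$seed + 3L, {
    n <- nrow(ped)
    ids <- ped$animal
    # QTL: sampled among reasonably common SNPs so each can carry its variance
    f <- allele_freqs(panel)
    maf <- pmin(f, 1 - f)
    eligible <- which(maf >= 0.05)
    if (config$n_qtl > 0L && length(eligible) < config$n_qtl) {
      stop_wssgwas("not enough common SNPs to place QTL", "sim_infeasible")
    }
    qtl_idx <- if (config$n_qtl > 0L) sort(sample(eligible, config$n_qtl)) else integer(0)
    frac <- config$qtl_variance_fractions
    qtl_value <- numeric(n)
    qtl_tbl <- tibble::tibble(snp = character(0), chrom = character(0),
                              pos = integer(0), effect = numeric(0),
                              variance_fraction = numeric(0))
    if (length(qtl_idx)) {
      pq <- f[qtl_idx] * (1 - f[qtl_idx])
      beta <- sqrt(frac * s2a / (2 * pq)) * sample(c(-1, 1), length(qtl_idx), replace = TRUE)
      Zq <- sweep(panel$geno[ids, qtl_idx, drop = FALSE], 2, 2 * f[qtl_idx])
      qtl_value <- drop(Zq %*% beta)
      qtl_tbl <- tibble::tibble(
        snp = panel$map$snp[qtl_idx], chrom = panel$map$chrom[qtl_idx],
        pos = panel$map$pos[qtl_idx], effect = beta, variance_fraction = frac)
    }
    # polygenic background
    s2_poly <- s2a * (1 - sum(frac))
    m <- ncol(panel$geno)
    poly_idx <- setdiff(seq_len(m), qtl_idx)
    if (config$polygene == "snp" && s2_poly > 0 && length(poly_idx)) {
      # infinitesimal architecture: every non-QTL SNP carries an equal
      # expected share of the polygenic variance
      p_base <- (attr(panel, "base_freq") %||% f)[poly_idx]
      pq <- pmax(p_base * (1 - p_base), 1e-4)
      gamma <- rnorm(length(poly_idx), 0,
                     sqrt(s2_poly / (length(poly_idx) * 2 * pq)))
      Zp <- sweep(panel$geno[ids, poly_idx, drop = FALSE], 2, 2 * p_base)
      poly <- drop(Zp %*% gamma)
    } else if (s2_poly > 0) {
      # SNP-free additive effect dropped down the pedigree
      idx <- stats::setNames(seq_len(n), ids)
      si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
      poly <- numeric(n)
      ms_sd <- sqrt(0.5 * s2_poly)
      for (i in seq_len(n)) {
        mid <- 0
        n_known <- 0L
        if (!is.na(si[i])) { mid <- mid + poly[si[i]]; n_known <- n_known + 1L }
        if (!is.na(di[i])) { mid <- mid + poly[di[i]]; n_known <- n_known + 1L }
        poly[i] <- if (n_known == 2L) mid / 2 + rnorm(1, 0, ms_sd)
                   else if (n_known == 1L) mid / 2 + rnorm(1, 0, sqrt(0.75 * s2_poly))
                   else rnorm(1, 0, sqrt(s2_poly))
      }
    } else poly <- numeric(n)
    tbv <- stats::setNames(qtl_value + poly, ids)

    candidates <- if ("sex" %in% names(ped)) ped$animal[ped$sex == "M"] else ped$animal
    n_ph <- max(1L, round(config$prop_phenotyped * length(candidates)))
    phenotyped <- sort(sample(candidates, n_ph))
    pe <- stats::setNames(rnorm(n_ph, 0, sqrt(max(s2p, 0))), phenotyped)

    lo <- config$records_per_animal[1]; hi <- config$records_per_animal[2]
    n_rec <- pmin(pmax(stats::rnbinom(n_ph, size = 4, mu = (lo + hi) / 2), lo), hi)
    group_eff <- rnorm(config$n_fixed_groups, 0, 0.5)
    b <- config$covariate_effects
    records <- tibble::tibble(
      animal = rep(phenotyped, n_rec),
      record_id = sequence(n_rec)
    )
    nr <- nrow(records)
    records$trait <- "sim_trait"
    records$fixed_group <- sprintf("g%02d", sample.int(config$n_fixed_groups, nr, replace = TRUE))
    records$interval_days <- rnorm(nr)
    records$age_months <- rnorm(nr)
    records$value <- group_eff[as.integer(substring(records$fixed_group, 2))] +
      b[[1]] * records$interval_days + b[[2]] * records$age_months +
      tbv[records$animal] + pe[records$animal] + rnorm(nr, 0, sqrt(s2e))
    records$record_id <- paste0(records$animal, "_r", records$record_id)

    list(
      records = records,
      truth = structure(list(
        tbv = tbv, pe = pe, qtl = qtl_tbl,
        variance_components = list(sigma2_a = s2a, sigma2_p = s2p, sigma2_e = s2e)
      ), class = "sim_truth")
    )
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_pedigree()], [simulate_genotypes()]
#' and [simulate_phenotypes()], then sampling the genotyped subset.
#'
#' @param config a [sim_config()].
#' @return List with `ped`, `panel` (genotyped animals only), `panel_all`,
#'   `records`, `truth`, `genotyped_ids`, `config`.
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  panel_all <- simulate_genotypes(ped, config)
  phen <- simulate_phenotypes(ped, panel_all, config)
  genotyped_ids <- withr::with_seed(config$seed + 4L, {
    n_g <- max(1L, round(config$prop_genotyped * nrow(ped)))
    sort(sample(ped$animal, n_g))
  })
  list(ped = ped, panel = subset_panel(panel_all, genotyped_ids),
       panel_all = panel_all, records = phen$records, truth = phen$truth,
       genotyped_ids = genotyped_ids, config = config)
}

#' Simulate a gene annotation
#'
#' Random non-overlapping "gene" intervals over the simulated genome, for
#' exercising interval lookup. Positions are 1-based inclusive bp.
#'
#' @param config a [sim_config()].
#' @param n_genes number of genes.
#' @param mean_length_bp mean gene length.
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, `name`.
#' @export
simulate_gene_annotation <- function(config, n_genes = 200L, mean_length_bp = 50000) {
  withr::with_seed(config$seed + 5L, {
    chrom <- as.character(sample.int(config$n_chromosomes, n_genes, replace = TRUE))
    start <- sample.int(config$chrom_length_bp - 2 * mean_length_bp, n_genes)
    len <- pmax(200, round(stats::rexp(n_genes, 1 / mean_length_bp)))
    tib <- tibble::tibble(
      chrom = chrom, start = as.integer(start),
      end = as.integer(pmin(start + len, config$chrom_length_bp)),
      gene_id = sprintf("SIMG%04d", seq_len(n_genes)),
      name = sprintf("GENE%04d", seq_len(n_genes))
    )
    dplyr::arrange(tib, .data$chrom, .data$start)
  })
}

#' Write records / annotation files
#'
#' `write_phenotypes_csv()` writes the record table as CSV;
#' `write_gene_bed()` writes a BED file (0-based half-open, as BED requires)
#' from a 1-based inclusive annotation tibble.
#'
#' @param records phenotype record tibble.
#' @param path output path.
#' @export
write_phenotypes_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @param annotation tibble with `chrom`, `start`, `end`, `gene_id`, `name`.
#' @export
write_gene_bed <- function(annotation, path) {
  bed <- tibble::tibble(
    chrom = annotation$chrom,
    start = annotation$start - 1L,   # BED is 0-based half-open
    end = annotation$end,
    name = annotation$gene_id
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a phenotype record CSV
#'
#' Schema as written by [write_phenotypes_csv()]: `animal`, `record_id`,
#' `trait`, `fixed_group`, `interval_days`, `age_months`, `value`.
#'
#' @param path file path.
#' @return Tibble of records.
#' @export
read_phenotypes_csv <- function(path) {
  if (!file.exists(path)) {
    stop_wssgwas(paste0("phenotype file not found: ", path), "io_missing_file")
  }
  readr::read_csv(path, col_types = readr::cols(
    animal = "c", record_id = "c", trait = "c", fixed_group = "c",
    .default = readr::col_double()))
}
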