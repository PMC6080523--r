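test_that("simulated pedigrees are ordered, complete and deterministic", {
  cfg <- sim_config(seed = 4, n_founders = 10, n_generations = 3,
                    n_animals_target = 70)
  ped <- simulate_pedigree(cfg)
  expect_silent(validate_pedigree(ped))
  founders <- is.na(ped$sire)
  expect_identical(sum(founders), 10L)
  expect_true(all(ped$generation[founders] == 0L))
  # every non-founder has both parents in earlier rows, opposite sexes
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  nf <- which(!founders)
  expect_true(all(idx[ped$sire[nf]] < nf & idx[ped$dam[nf]] < nf))
  sex <- stats::setNames(ped$sex, ped$animal)
  expect_true(all(sex[ped$sire[nf]] == "M" & sex[ped$dam[nf]] == "F"))
  expect_identical(simulate_pedigree(cfg), ped)

  expect_error(simulate_pedigree(sim_config(n_founders = 1)), class = "sim_infeasible")
})

test_that("minimal two-founder pedigree yields the trio", {
  cfg <- sim_config(seed = 1, n_founders = 2, n_generations = 1,
                    n_animals_target = 3)
  ped <- simulate_pedigree(cfg)
  expect_identical(nrow(ped), 3L)
  expect_setequal(c(ped$sire[3], ped$dam[3]), ped$animal[1:2])
})

test_that("config invariants are enforced", {
  expect_error(sim_config(h2 = 0), class = "config_invalid")
  expect_error(sim_config(h2 = 0.6, rep = 0.5), class = "config_invalid")
  expect_error(sim_config(rep = 1), class = "config_invalid")
  expect_error(sim_config(n_qtl = 2, qtl_variance_fractions = c(0.6, 0.6)),
               class = "config_invalid")
  expect_error(sim_config(prop_genotyped = 0), class = "config_invalid")
  cfg <- sim_config(n_snps = 2, n_chromosomes = 3)
  expect_error(simulate_genotypes(simulate_pedigree(cfg), cfg),
               class = "config_invalid")
})

test_that("gene dropping is Mendelian: every offspring allele is in a parent", {
  cfg <- sim_config(seed = 9, n_founders = 6, n_generations = 2,
                    n_animals_target = 30, n_chromosomes = 2,
                    chrom_length_bp = 5e6, n_snps = 60)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  haps <- attr(panel, "haplotypes")
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  for (i in which(!is.na(ped$sire))) {
    s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
    # paternal haplotype allele must be carried by the sire at every SNP
    expect_true(all(haps$H1[i, ] == haps$H1[s, ] | haps$H1[i, ] == haps$H2[s, ]))
    expect_true(all(haps$H2[i, ] == haps$H1[d, ] | haps$H2[i, ] == haps$H2[d, ]))
  }
  expect_true(all(panel$geno == haps$H1 + haps$H2))
})

test_that("LD is stronger within haplotype blocks than across boundaries", {
  cfg <- sim_config(seed = 12, n_founders = 60, n_generations = 1,
                    n_animals_target = 61, n_chromosomes = 1,
                    chrom_length_bp = 20e6, n_snps = 400)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  founders <- ped$animal[is.na(ped$sire)]
  g <- panel$geno[founders, ]
  block <- (panel$map$pos - 1) %/% cfg$block_size_bp
  r2 <- function(a, b) stats::cor(a, b)^2
  within <- across <- numeric(0)
  for (j in seq_len(ncol(g) - 1)) {
    r <- r2(g[, j], g[, j + 1])
    if (is.na(r)) next
    if (block[j] == block[j + 1]) within <- c(within, r) else across <- c(across, r)
  }
  expect_gt(mean(within), 5 * mean(across))
  expect_gt(mean(within), 0.2)   # blocks carry substantial LD
})

test_that("phenotype variance components are recovered empirically", {
  # ~2000 phenotyped boars with one record each keeps the Monte-Carlo error
  # of the component variance ratios inside the asserted band
  cfg <- sim_config(seed = 31, n_founders = 100, n_generations = 2,
                    n_animals_target = 4300, n_chromosomes = 2,
                    chrom_length_bp = 20e6, n_snps = 60,
                    h2 = 0.3, rep = 0.5, records_per_animal = c(1, 1),
                    prop_phenotyped = 1)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, panel, cfg)
  rec <- sim$records
  expect_gt(nrow(rec), 2000)
  tbv <- sim$truth$tbv[rec$animal]
  pe <- sim$truth$pe[rec$animal]
  resid <- rec$value - tbv - pe
  resid <- resid - stats::ave(resid, rec$fixed_group) -
    cfg$covariate_effects[[1]] * (rec$interval_days - mean(rec$interval_days)) -
    cfg$covariate_effects[[2]] * (rec$age_months - mean(rec$age_months))
  tot <- stats::var(tbv + pe) + stats::var(resid)
  expect_lt(abs(stats::var(tbv) / tot - 0.3), 0.03)
  expect_lt(abs(stats::var(tbv + pe) / tot - 0.5), 0.03)
})

test_that("a single full-variance QTL with tiny residual ranks phenotypes by genotype", {
  cfg <- sim_config(seed = 8, n_founders = 30, n_generations = 1,
                    n_animals_target = 150, n_chromosomes = 1,
                    chrom_length_bp = 5e6, n_snps = 50,
                    n_qtl = 1, qtl_variance_fractions = 1,
                    h2 = 0.98, rep = 0.98, records_per_animal = c(1, 1),
                    n_fixed_groups = 1, prop_phenotyped = 1)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, panel, cfg)
  rec <- sim$records
  qtl <- sim$truth$qtl
  g <- panel$geno[rec$animal, qtl$snp]
  dev <- rec$value - cfg$covariate_effects[[1]] * rec$interval_days -
    cfg$covariate_effects[[2]] * rec$age_months -
    stats::ave(rec$value, rec$fixed_group)
  rho <- abs(stats::cor(dev, g, method = "spearman"))
  expect_gt(rho, 0.9)
})

test_that("single-record animals still yield valid records", {
  cfg <- sim_config(seed = 13, n_founders = 10, n_generations = 1,
                    n_animals_target = 40, n_chromosomes = 1,
                    chrom_length_bp = 2e6, n_snps = 20,
                    records_per_animal = c(1, 1), prop_phenotyped = 1)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, simulate_genotypes(ped, cfg), cfg)
  expect_identical(anyDuplicated(sim$records$animal), 0L)
  expect_false(anyNA(sim$records$value))
})

test_that("the whole dataset is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 77, n_founders = 12, n_generations = 2,
                    n_animals_target = 50, n_chromosomes = 2,
                    chrom_length_bp = 4e6, n_snps = 80)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$ped, d2$ped)
  expect_identical(d1$panel$geno, d2$panel$geno)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth$tbv, d2$truth$tbv)
  expect_identical(d1$genotyped_ids, d2$genotyped_ids)
})

test_that("writers produce readable pedigree, phenotype, PLINK and BED files", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_phenotypes_csv(ds$records, file.path(dir, "phen.csv"))
  phen <- read_phenotypes_csv(file.path(dir, "phen.csv"))
  expect_identical(nrow(phen), nrow(ds$records))
  expect_named(phen, c("animal", "record_id", "trait", "fixed_group",
                       "interval_days", "age_months", "value"))

  write_plink(ds$panel, file.path(dir, "geno"))
  back <- read_plink(file.path(dir, "geno"))
  expect_identical(back$geno[rownames(ds$panel$geno), ],
                   matrix(as.integer(ds$panel$geno),
                          nrow(ds$panel$geno), ncol(ds$panel$geno),
                          dimnames = dimnames(ds$panel$geno)))
  expect_equal(back$map, ds$panel$map)

  ann <- simulate_gene_annotation(ds$config, n_genes = 50)
  write_gene_bed(ann, file.path(dir, "genes.bed"))
  back_ann <- read_gene_annotation(file.path(dir, "genes.bed"))
  expect_identical(back_ann$start, ann$start)  # 1-based round trip
  expect_identical(back_ann$end, ann$end)
  expect_identical(back_ann$gene_id, ann$gene_id)
})
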