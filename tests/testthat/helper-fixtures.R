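# Shared fixtures: tiny pedigrees and panels built in code.

# founders s, d; full sibs x, y; grandchild g from x mated to founder d2
ped_3gen <- function() {
  pedigree(
    animal = c("s", "d", "d2", "x", "y", "g"),
    sire   = c(NA, NA, NA, "s", "s", "x"),
    dam    = c(NA, NA, NA, "d", "d", "d2")
  )
}

# half-sib mating: s x d1 -> a ; s x d2 -> b ; a x b -> i (inbred)
ped_halfsib <- function() {
  pedigree(
    animal = c("s", "d1", "d2", "a", "b", "i"),
    sire   = c(NA, NA, NA, "s", "s", "a"),
    dam    = c(NA, NA, NA, "d1", "d2", "b")
  )
}

random_pedigree <- function(n, n_founders = max(4, n %/% 5), seed = 1) {
  withr::with_seed(seed, {
    animal <- sprintf("r%04d", seq_len(n))
    sire <- dam <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (i > n_founders) {
        sire[i] <- animal[sample.int(i - 1L, 1)]
        repeat {
          dam[i] <- animal[sample.int(i - 1L, 1)]
          if (dam[i] != sire[i]) break
        }
      }
    }
    pedigree(animal, sire, dam)
  })
}

# small genotype panel with known codes
toy_panel <- function(geno = rbind(a1 = c(0, 2), a2 = c(1, 1), a3 = c(2, 0)),
                      pos = c(100L, 200000L)) {
  genotype_panel(geno, tibble::tibble(
    snp = paste0("s", seq_along(pos)), chrom = "1", pos = pos))
}

# brute-force gene-drop estimate of additive relationships: drop two distinct
# founder alleles per founder through the pedigree n_rep times; a_ij is twice
# the probability that a random allele of i is IBD to a random allele of j
# (kinship), estimated over replicates. Vectorised over replicates.
gene_drop_A <- function(ped, n_rep = 1e5, seed = 42) {
  withr::with_seed(seed, {
    n <- nrow(ped)
    idx <- stats::setNames(seq_len(n), ped$animal)
    si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
    h1 <- vector("list", n); h2 <- vector("list", n)
    next_allele <- 0L
    for (i in seq_len(n)) {
      h1[[i]] <- if (is.na(si[i])) {
        next_allele <- next_allele + 1L
        rep.int(next_allele, n_rep)
      } else {
        pick <- stats::runif(n_rep) < 0.5
        ifelse(pick, h1[[si[i]]], h2[[si[i]]])
      }
      h2[[i]] <- if (is.na(di[i])) {
        next_allele <- next_allele + 1L
        rep.int(next_allele, n_rep)
      } else {
        pick <- stats::runif(n_rep) < 0.5
        ifelse(pick, h1[[di[i]]], h2[[di[i]]])
      }
    }
    A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        # kinship: average IBD probability over the 4 allele pairings
        kin <- (mean(h1[[i]] == h1[[j]]) + mean(h1[[i]] == h2[[j]]) +
                mean(h2[[i]] == h1[[j]]) + mean(h2[[i]] == h2[[j]])) / 4
        A[i, j] <- 2 * kin
      }
    }
    # diagonal: a_ii = 1 + F_i, F_i = P(two alleles of i IBD)
    for (i in seq_len(n)) A[i, i] <- 1 + mean(h1[[i]] == h2[[i]])
    A
  })
}

# small simulated dataset reused across tests (built once per test run)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_founders = 30, n_generations = 2,
                        n_animals_target = 160, n_chromosomes = 2,
                        chrom_length_bp = 20e6, n_snps = 400,
                        h2 = 0.3, rep = 0.5, records_per_animal = c(4, 8),
                        prop_genotyped = 1, prop_phenotyped = 1)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
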