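fake_windows <- function(trait, chrom, midpoint, pct, width = 2e5) {
  tibble::tibble(
    trait = trait, window = seq_along(chrom), chrom = as.character(chrom),
    start_pos = midpoint - width / 2, end_pos = midpoint + width / 2,
    midpoint = midpoint, n_snps = 5L, pct_variance = pct
  )
}

test_that("window selection is boundary-inclusive at the threshold", {
  w <- fake_windows("t1", c(1, 1, 1), c(1e6, 2e6, 3e6), c(0.5, 1.0, 3.2))
  sel <- select_windows(w)
  expect_identical(sel$midpoint, c(2e6, 3e6))
  expect_identical(nrow(select_windows(w, threshold_pct = 5)), 0L)
})

test_that("the 1% threshold equals 50x the expected window contribution", {
  ex <- window_expectation(4223)
  expect_equal(round(ex$expected_pct, 2), 0.02)
  expect_equal(50 * round(ex$expected_pct, 2), 1.0)
  expect_equal(ex$threshold_pct, 50 * 100 / 4223)
})

test_that("midpoint merging is strict at 0.4 Mb and transitive on chains", {
  near <- fake_windows(c("t1", "t2"), c(1, 1), c(10.0e6, 10.3e6), c(2, 3))
  r1 <- overlap_windows(near)
  expect_identical(nrow(r1), 1L)
  expect_identical(r1$traits, "t1,t2")
  expect_equal(r1$pct_by_trait[[1]], c(t1 = 2, t2 = 3))

  at_limit <- fake_windows(c("t1", "t2"), c(1, 1), c(10.0e6, 10.4e6), c(2, 3))
  expect_identical(nrow(overlap_windows(at_limit)), 2L)  # strictly less-than

  other_chr <- fake_windows(c("t1", "t2"), c(1, 2), c(10.0e6, 10.0e6), c(2, 3))
  expect_identical(nrow(overlap_windows(other_chr)), 2L)

  # chain: a-b close, b-c close, a-c far -> one region by single linkage
  chain <- fake_windows("t1", c(1, 1, 1), c(10.0e6, 10.3e6, 10.6e6), c(2, 2, 2))
  rc <- overlap_windows(chain)
  expect_identical(nrow(rc), 1L)
  expect_identical(rc$n_windows, 3L)
  expect_equal(rc$start, min(chain$start_pos))
  expect_equal(rc$end, max(chain$end_pos))
})

test_that("merging is independent of input row order", {
  withr::with_seed(14, {
    w <- fake_windows(sample(c("t1", "t2"), 12, TRUE),
                      sample(1:2, 12, TRUE),
                      sample(seq(1e6, 20e6, by = 0.25e6), 12),
                      stats::runif(12, 1, 5))
    ref <- overlap_windows(w)
    for (k in 1:5) {
      shuf <- w[sample.int(nrow(w)), ]
      got <- overlap_windows(shuf)
      expect_equal(got[order(got$chrom, got$start), c("chrom", "start", "end", "n_windows")],
                   ref[order(ref$chrom, ref$start), c("chrom", "start", "end", "n_windows")],
                   ignore_attr = TRUE)
    }
  })
})

test_that("selection + merging matches a brute-force reference on table-like data", {
  withr::with_seed(33, {
    w <- fake_windows(sample(paste0("t", 1:4), 60, TRUE),
                      sample(1:5, 60, TRUE),
                      round(stats::runif(60, 1e6, 60e6)),
                      stats::rexp(60, 1))
    sel <- select_windows(w, 1)
    regions <- overlap_windows(sel)
    # brute force: union-find over all pairs with the strict midpoint rule
    n <- nrow(sel)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && sel$chrom[i] == sel$chrom[j] &&
          abs(sel$midpoint[i] - sel$midpoint[j]) < 4e5) {
        parent[find(i)] <- find(j)
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    expect_identical(nrow(regions), length(unique(comp)))
    counts <- sort(as.integer(table(comp)))
    expect_identical(sort(regions$n_windows), counts)
  })
})

test_that("top windows gain clipped flanks and deterministic tie-breaks", {
  w <- fake_windows("t1", c(1, 1, 2, 2), c(5e6, 9e6, 0.1e6, 20e6),
                    c(5, 3, 2, 1))
  top <- top_windows_with_flanks(w, k = 3)
  expect_identical(top$pct_variance, c(5, 3, 2))
  expect_identical(top$rank, 1:3)
  expect_equal(top$start[3], 0)              # clip at zero
  expect_equal(top$end[3], 0.1e6 + 4e5)
  expect_true(all(top$midpoint >= top$start & top$midpoint <= top$end))

  tie <- fake_windows("t1", c(2, 1), c(1e6, 1e6), c(3, 3))
  t2 <- top_windows_with_flanks(tie, k = 1)
  expect_identical(t2$chrom, "1")            # (chromosome, position) tie-break

  short <- fake_windows("t1", 1, 1e6, 2)
  expect_warning(res <- top_windows_with_flanks(short, k = 3), "only 1")
  expect_true(all(res$flagged_short))
  expect_identical(nrow(res), 1L)
})

test_that("cross-population overlap applies the strict midpoint rule per trait", {
  p1 <- fake_windows("t1", c(1, 3), c(10e6, 5e6), c(2, 1.5))
  p2_far <- fake_windows("t1", 2, 10e6, 2)
  expect_identical(nrow(cross_population_overlap(p1, p2_far)), 0L)
  expect_identical(nrow(cross_population_overlap(p1, p1)), 2L)  # self pairs
  p2 <- fake_windows("t1", 1, 10.39e6, 4)
  hit <- cross_population_overlap(p1, p2)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$distance_bp, 0.39e6)
  expect_identical(nrow(cross_population_overlap(p1, fake_windows("t1", 1, 10.4e6, 4))), 0L)
  expect_identical(nrow(cross_population_overlap(p1[0, ], p2)), 0L)
})

test_that("a QTL shared by two analysed populations is reported as overlapping", {
  # two "lines" = disjoint halves of one simulated population, so both truly
  # segregate the same large QTL at the same map position
  hits <- 0L
  for (s in 1:3) {
    cfg <- sim_config(seed = 40 + s, n_founders = 50, n_generations = 2,
                      n_animals_target = 550, n_chromosomes = 2,
                      chrom_length_bp = 20e6, n_snps = 600,
                      n_qtl = 1, qtl_variance_fractions = 0.5,
                      h2 = 0.4, rep = 0.5, records_per_animal = c(6, 6),
                      prop_genotyped = 1, prop_phenotyped = 1)
    ped <- simulate_pedigree(cfg)
    panel <- simulate_genotypes(ped, cfg)
    sim <- simulate_phenotypes(ped, panel, cfg)
    boars <- sort(unique(sim$records$animal))
    halves <- split(boars, rep(1:2, length.out = length(boars)))
    sel <- lapply(halves, function(h) {
      rec <- sim$records[sim$records$animal %in% h, ]
      model <- build_model(rec, ped)
      vc <- estimate_reml(model)
      fit <- run_wssgwas(model, apply_qc(subset_panel(panel, h))$panel, vc)
      select_windows(tidy(fit), 1)
    })
    ov <- cross_population_overlap(sel[[1]], sel[[2]])
    qtl <- sim$truth$qtl
    if (nrow(ov) && any(ov$chrom == qtl$chrom &
                          abs(ov$midpoint_pop1 - qtl$pos) < 4e5)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 2L)
})
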