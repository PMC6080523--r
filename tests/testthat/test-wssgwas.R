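test_that("backsolving SNP effects reproduces hand linear algebra", {
  # 1-SNP toy: Z = (-1, 1), lambda = 2, G = 2 Z Z' has a_g = (-1, 1) as an
  # eigenvector with eigenvalue 4, so the formula gives u = 2 Z' (a_g / 4) = 1
  # and Z u = a_g; verify against an explicit generalized solution
  Z1 <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G1 <- build_G(Z1, freq = 0.5)
  expect_equal(unname(G1), matrix(c(2, -2, -2, 2), 2, 2), ignore_attr = TRUE)
  u_hand <- as.numeric(2 * crossprod(Z1, c(-1, 1) / 4))
  expect_equal(u_hand, 1)
  expect_equal(as.numeric(Z1 %*% u_hand), c(-1, 1))
  # singular G is an explicit error, not a silent pseudo-inverse
  expect_error(backsolve_snp_effects(Z1, G1, c(-1, 1), lambda = 2),
               class = "matrix_singular")

  # invertible 2-SNP toy exercises the exported path end to end
  Z <- matrix(c(-1, 1, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  G <- build_G(Z, freq = c(0.5, 0.25))
  a_g <- c(-0.8, 1.3)
  u <- backsolve_snp_effects(Z, G, a_g)
  expect_equal(as.numeric(Z %*% u), a_g, tolerance = 1e-10)
  expect_equal(backsolve_snp_effects(Z, G, c(0, 0)), c(0, 0))
  expect_equal(backsolve_snp_effects(Z, G, 2 * a_g), 2 * u)
  # weighted version keeps the identity
  w <- c(2, 0.5)
  Gw <- build_G(Z, freq = c(0.5, 0.25), weights = w)
  uw <- backsolve_snp_effects(Z, Gw, a_g, weights = w)
  expect_equal(as.numeric(Z %*% uw), a_g, tolerance = 1e-10)
})

test_that("weight update implements u^2 2pq and ignores sign", {
  expect_equal(update_weights(0, 0.3), 0)
  expect_equal(update_weights(0.1, 0.25), 0.01 * 2 * 0.25 * 0.75)
  expect_equal(update_weights(0.1, 0.25), 0.00375)
  u <- c(-0.4, 0.4, 0.2)
  p <- c(0.1, 0.1, 0.3)
  expect_equal(update_weights(u, p), update_weights(-u, p))
})

test_that("weight normalization conserves the trace exactly", {
  expect_equal(normalize_weights(rep(1, 7)), rep(1, 7))
  expect_equal(normalize_weights(c(2, 0, 0, 0), M = 4), c(4, 0, 0, 0))
  withr::with_seed(3, {
    for (k in 1:10) {
      d <- stats::rexp(50)
      expect_equal(sum(normalize_weights(d)), 50, tolerance = 1e-12)
    }
  })
  expect_error(normalize_weights(rep(0, 5)), class = "weights_zero")
})

test_that("greedy window partition matches the hand-applied rule", {
  map <- tibble::tibble(snp = paste0("s", 1:5), chrom = "1",
                        pos = as.integer(c(0, 0.1e6, 0.3e6, 0.45e6, 0.9e6) + 1))
  w <- define_windows(map, span_bp = 400000)
  expect_identical(nrow(w), 3L)
  expect_identical(w$n_snps, c(3L, 1L, 1L))
  expect_equal(w$midpoint, c((1 + 0.3e6 + 1) / 2, 0.45e6 + 1, 0.9e6 + 1))
  # one SNP per chromosome -> one window per chromosome
  map2 <- tibble::tibble(snp = paste0("s", 1:3), chrom = c("1", "2", "3"),
                         pos = c(5L, 5L, 5L))
  expect_identical(nrow(define_windows(map2)), 3L)
  # all SNPs within the span -> a single window
  map3 <- tibble::tibble(snp = paste0("s", 1:4), chrom = "1",
                         pos = as.integer(seq(1, 3e5, length.out = 4)))
  expect_identical(nrow(define_windows(map3)), 1L)
  expect_error(define_windows(map[c(2, 1, 3, 4, 5), ]), class = "map_unsorted")
})

test_that("window variance percentages behave under edge cases", {
  ds <- small_dataset()
  qc <- apply_qc(ds$panel)
  Z <- center_gene_content(qc$panel)
  w <- define_windows(qc$panel$map)
  u <- withr::with_seed(6, stats::rnorm(ncol(Z), 0, 0.01))
  res <- window_variance_percentages(w, u, Z, sigma2_a = 0.3)
  expect_true(all(res$pct_variance >= 0))
  # zero-effect windows score zero
  u0 <- u; u0[res$snp_index[[1]]] <- 0
  res0 <- window_variance_percentages(w, u0, Z, 0.3)
  expect_equal(res0$pct_variance[1], 0)
  # adding a zero-effect SNP to a window leaves its percentage unchanged
  w_aug <- w
  w_aug$snp_index[[2]] <- c(w_aug$snp_index[[2]], res$snp_index[[1]][1])
  res_aug <- window_variance_percentages(w_aug, u0, Z, 0.3)
  expect_equal(res_aug$pct_variance[2], res0$pct_variance[2])
  # single-window genome: percentage equals the all-SNP total
  one <- tibble::tibble(window = 1L, chrom = "1", start_pos = 1, end_pos = 2,
                        midpoint = 1.5, n_snps = ncol(Z),
                        snp_index = list(seq_len(ncol(Z))))
  tot <- window_variance_percentages(one, u, Z, 0.3)$pct_variance
  g <- as.numeric(Z %*% u)
  expect_equal(tot, 100 * mean((g - mean(g))^2) / 0.3)
  expect_error(window_variance_percentages(w, u, Z, 0), class = "vc_invalid")
})

test_that("percentages are invariant to SNP relabeling and chromosome order", {
  ds <- small_dataset()
  qc <- apply_qc(ds$panel)
  u <- withr::with_seed(9, stats::rnorm(ncol(qc$panel$geno), 0, 0.01))
  Z <- center_gene_content(qc$panel)
  w <- define_windows(qc$panel$map)
  base <- window_variance_percentages(w, u, Z, 0.3)
  # relabel SNPs and swap chromosome labels; window contents are unchanged
  relabel <- qc$panel
  relabel$map$snp <- paste0("renamed_", relabel$map$snp)
  colnames(relabel$geno) <- relabel$map$snp
  names(relabel$freq) <- relabel$map$snp
  res2 <- window_variance_percentages(define_windows(relabel$map), u,
                                      center_gene_content(relabel), 0.3)
  expect_equal(res2$pct_variance, base$pct_variance)
})

test_that("the full weighting loop conserves traces and the identity", {
  ds <- small_dataset()
  qc <- apply_qc(ds$panel)
  model <- build_model(ds$records, ds$ped)
  vc <- variance_components(0.3, 0.2, 0.5)
  M <- ncol(qc$panel$geno)
  fit <- run_wssgwas(model, qc$panel, vc, n_iterations = 3,
                     blend_alpha = 0, freq = attr(qc$panel, "base_freq"))
  for (st in fit$states) {
    expect_equal(sum(st$weights), M, tolerance = 1e-12 * M)
    expect_lt(st$identity_resid, 1e-8)
  }
  expect_identical(length(fit$states), 3L)
  # iteration 1 is the unweighted analysis
  expect_equal(fit$states[[1]]$weights, rep(1, M))
  # glance reports the bookkeeping
  g <- glance(fit)
  expect_identical(g$n_windows, nrow(fit$windows))
  expect_equal(g$trace_D, M)
  # percentages from the final iteration, tidy output is per window
  td <- tidy(fit)
  expect_identical(nrow(td), nrow(fit$windows))
  expect_true(all(c("trait", "chrom", "midpoint", "pct_variance") %in% names(td)))
})

test_that("manhattan table covers all iterations and autoplot returns a ggplot", {
  ds <- small_dataset()
  qc <- apply_qc(ds$panel)
  model <- build_model(ds$records, ds$ped)
  vc <- variance_components(0.3, 0.2, 0.5)
  fit <- run_wssgwas(model, qc$panel, vc, n_iterations = 2)
  mt <- manhattan_table(fit, center_gene_content(qc$panel))
  expect_setequal(unique(mt$iteration), 1:2)
  expect_identical(nrow(mt), 2L * nrow(fit$windows))
  expect_s3_class(autoplot(fit), "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manhattan_tsv(mt, path)
  expect_identical(nrow(readr::read_tsv(path, show_col_types = FALSE)), nrow(mt))
})

test_that("a dominant simulated QTL gains weight across iterations", {
  cfg <- sim_config(seed = 41, n_founders = 40, n_generations = 2,
                    n_animals_target = 300, n_chromosomes = 2,
                    chrom_length_bp = 20e6, n_snps = 600,
                    n_qtl = 1, qtl_variance_fractions = 0.4,
                    h2 = 0.4, rep = 0.5, records_per_animal = c(6, 6),
                    prop_genotyped = 1, prop_phenotyped = 1)
  ds <- simulate_dataset(cfg)
  qc <- apply_qc(ds$panel)
  model <- build_model(ds$records, ds$ped)
  vc <- estimate_reml(model)
  fit <- run_wssgwas(model, qc$panel, vc)
  j <- match(ds$truth$qtl$snp, qc$panel$map$snp)
  wts <- vapply(fit$states, function(st) st$weights[j], numeric(1))
  expect_true(all(diff(wts) > 0))     # non-decreasing, here strictly growing
  # and the QTL window tops the final ranking
  w <- fit$windows
  top <- w[which.max(w$pct_variance), ]
  expect_true(top$chrom == ds$truth$qtl$chrom &&
                ds$truth$qtl$pos >= top$start_pos &&
                ds$truth$qtl$pos <= top$end_pos)
})
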