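#' Back-solve SNP effects from genomic breeding values
#'
#' Converts the GEBV of the genotyped animals into SNP effects,
#' `u_hat = lambda D Z' G^-1 a_hat_g`. When `G` is the unblended weighted
#' genomic relationship matrix built from the same `Z`, `D` and `lambda`,
#' the decomposition identity `Z u_hat = a_hat_g` holds exactly.
#'
#' @param Z_centered centered gene contents of the genotyped animals.
#' @param G the (weighted, possibly blended) genomic relationship matrix used
#'   in the evaluation; its `"lambda"` attribute is used unless `lambda` is
#'   given.
#' @param a_hat_g GEBV of the genotyped animals, in `Z_centered` row order.
#' @param weights SNP weight vector (diagonal of D), defaults to 1.
#' @param lambda scaling constant `1 / sum 2 p_i (1 - p_i)`.
#' @return Numeric vector of SNP effects (one per column of `Z_centered`).
#' @export
backsolve_snp_effects <- function(Z_centered, G, a_hat_g, weights = NULL,
                                  lambda = attr(G, "lambda")) {
  m <- ncol(Z_centered)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(a_hat_g) == nrow(Z_centered), length(weights) == m,
            !is.null(lambda))
  Ginv_a <- tryCatch(solve(G, a_hat_g), error = function(e) NULL)
  if (is.null(Ginv_a)) {
    stop_wssgwas("G is singular; blend with A22 (blend_alpha > 0) or prune SNPs",
                 "matrix_singular")
  }
  as.numeric(lambda * weights * crossprod(Z_centered, Ginv_a))
}

#' SNP weights from estimated effects
#'
#' `d_i = u_i^2 2 p_i (1 - p_i)` — each SNP's weight for the next iteration
#' is the variance its estimated effect explains.
#'
#' @param u_hat SNP effect vector.
#' @param freq counted-allele frequencies.
#' @return Non-negative weight vector.
#' @export
update_weights <- function(u_hat, freq) {
  stopifnot(length(u_hat) == length(freq))
  u_hat^2 * 2 * freq * (1 - freq)
}

#' Normalize SNP weights to a constant trace
#'
#' Rescales the weight vector so its sum (the trace of D) equals `M`, the
#' trace of the initial identity weight matrix, keeping the total genetic
#' variance constant across iterations.
#'
#' @param d_raw raw weight vector.
#' @param M target trace (the number of SNPs).
#' @return Weight vector with `sum(d) = M`.
#' @export
normalize_weights <- function(d_raw, M = length(d_raw)) {
  s <- sum(d_raw)
  if (s <= 0) {
    stop_wssgwas("all SNP weights are zero: no signal to reweight", "weights_zero")
  }
  d_raw * (M / s)
}

#' Partition a SNP map into 0.4 Mb windows
#'
#' Greedy non-overlapping partition per chromosome: a window starts at the
#' first unassigned SNP and absorbs consecutive SNPs with position strictly
#' less than `start_position + span_bp`. The window midpoint is the mean of
#' its first and last member positions.
#'
#' @param map SNP map tibble (`snp`, `chrom`, `pos`), sorted by
#'   (chromosome, position).
#' @param span_bp window span in bp (default 400 kb).
#' @return Tibble with one row per window: `window`, `chrom`, `start_pos`,
#'   `end_pos`, `midpoint`, `n_snps`, and `snp_index` (list column of member
#'   column indices into the map/genotype matrix).
#' @export
define_windows <- function(map, span_bp = 400000) {
  if (is.unsorted(order(map$chrom, map$pos)) ||
      any(stats::ave(map$pos, map$chrom, FUN = function(x) c(0, diff(x))) < 0)) {
    stop_wssgwas("SNP map must be sorted by (chromosome, position)", "map_unsorted")
  }
  rows <- list()
  wid <- 0L
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    pos <- map$pos[j]
    i <- 1L
    while (i <= length(j)) {
      in_win <- pos >= pos[i] & pos < pos[i] + span_bp & seq_along(pos) >= i
      members <- j[in_win]
      wid <- wid + 1L
      first <- map$pos[members[1]]
      last <- map$pos[members[length(members)]]
      rows[[wid]] <- tibble::tibble(
        window = wid, chrom = ch, start_pos = first, end_pos = last,
        midpoint = (first + last) / 2, n_snps = length(members),
        snp_index = list(members))
      i <- i + length(members)
    }
  }
  dplyr::bind_rows(rows)
}

#' Percentage of genetic variance per SNP window
#'
#' For each window, the empirical variance across genotyped animals of the
#' window genetic value `sum_j Z_j u_j` (members `j` of the window), divided
#' by the additive genetic variance, times 100.
#'
#' @param windows window table from [define_windows()].
#' @param u_hat SNP effect vector (typically from the final iteration).
#' @param Z_centered centered gene contents of the genotyped animals.
#' @param sigma2_a additive genetic variance (from REML at unit weights).
#' @param denominator `"n"` (population variance, default) or `"n-1"`.
#' @return The window table with a `pct_variance` column (and the per-animal
#'   window values dropped).
#' @export
window_variance_percentages <- function(windows, u_hat, Z_centered, sigma2_a,
                                        denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  if (sigma2_a <= 0) stop_wssgwas("sigma2_a must be positive", "vc_invalid")
  stopifnot(length(u_hat) == ncol(Z_centered))
  n <- nrow(Z_centered)
  pct <- vapply(windows$snp_index, function(idx) {
    g <- as.numeric(Z_centered[, idx, drop = FALSE] %*% u_hat[idx])
    v <- sum((g - mean(g))^2) / if (denominator == "n") n else (n - 1)
    100 * v / sigma2_a
  }, numeric(1))
  out <- windows
  out$pct_variance <- pct
  out
}

#' Run the weighted single-step GWAS iteration
#'
#' The full weighting loop: iteration 1 uses unit SNP weights (`D = I`);
#' each iteration (1) builds the weighted genomic relationship matrix
#' `G = Z D Z' lambda` (optionally blended with `A22`), (2) forms
#' `H^-1` and re-solves the mixed model for GEBV, (3) back-solves SNP effects
#' `u = lambda D Z' G^-1 a_g`, (4) squares them into variance weights
#' `d_i = u_i^2 2 p_i (1 - p_i)` and (5) renormalizes the weights to trace
#' `M` for the next round. Variance components are estimated once beforehand
#' (at `D = I`) and held fixed. Window variance percentages are reported from
#' the final iteration's effects and the REML additive variance.
#'
#' @param model a [build_model()] object whose pedigree covers the panel's
#'   animals.
#' @param panel a QC'd [genotype_panel()] of the genotyped animals (no
#'   missing entries; `freq` populated).
#' @param vc converged [variance_components()] / `vc_fit`.
#' @param n_iterations number of weighting iterations (default 3).
#' @param blend_alpha blending proportion towards `A22` for invertibility
#'   (default 0.05; use 0 when the exact decomposition identity
#'   `Z u = a_g` is required).
#' @param span_bp window span in bp.
#' @param denominator variance denominator for window percentages.
#' @param freq allele frequencies used for centering, `lambda` and the
#'   weight updates; defaults to the panel's observed frequencies. With
#'   observed frequencies the unblended G is structurally singular (centered
#'   columns sum to zero), so `blend_alpha = 0` requires base-population
#'   frequencies here (the generator stores them in the panel's
#'   `"base_freq"` attribute).
#' @return Object of class `wssgwas_fit`: per-iteration states (weights used,
#'   SNP effects, GEBV of genotyped animals, the identity residual
#'   `max|Z u - a_g| / max|a_g|`), the final window table, and the inputs'
#'   metadata. `tidy()` returns the window table, `glance()` a one-row
#'   summary, `autoplot()` a Manhattan-style window plot.
#' @export
run_wssgwas <- function(model, panel, vc, n_iterations = 3L,
                        blend_alpha = 0.05, span_bp = 400000,
                        denominator = c("n", "n-1"), freq = NULL) {
  stopifnot(inherits(model, "trait_model"), inherits(panel, "genotype_panel"))
  denominator <- match.arg(denominator)
  gids <- rownames(panel$geno)
  if (!all(gids %in% model$ids_a)) {
    stop_wssgwas("genotyped animals missing from the model pedigree", "ids_missing")
  }
  freq <- freq %||% panel$freq %||% allele_freqs(panel)
  Z <- center_gene_content(panel, freq)
  M <- ncol(Z)
  A <- build_A(model$ped)
  A_inv <- build_A_inverse(model$ped, inbreeding = diag(A) - 1)
  A22 <- extract_A22(A, gids)
  A22_inv <- invert_spd(A22, "A22")
  lambda <- grm_lambda(freq)

  d <- rep(1, M)
  states <- vector("list", n_iterations)
  for (t in seq_len(n_iterations)) {
    G_raw <- build_G(Z, freq, d)
    G <- blend_G(G_raw, A22, blend_alpha)
    G_inv <- invert_spd(G, "G")
    H_inv <- build_H_inverse(A_inv, A22_inv, G_inv, gids)
    fit <- solve_mme(set_relationship_inverse(model, H_inv), vc)
    a_g <- fit$gebv[gids]
    u_hat <- as.numeric(lambda * d * crossprod(Z, G_inv %*% a_g))
    identity_resid <- max(abs(as.numeric(Z %*% u_hat) - a_g)) /
      max(max(abs(a_g)), .Machine$double.eps)
    states[[t]] <- list(iteration = t, weights = d, u_hat = u_hat, a_hat_g = a_g,
                        gebv = fit$gebv, identity_resid = identity_resid,
                        fit = fit)
    d_next <- normalize_weights(update_weights(u_hat, freq), M)
    if (max(d_next) > 0.999 * M) {
      rlang::warn("SNP weight collapse: one SNP holds > 99.9% of the trace")
    }
    d <- d_next
  }
  windows <- define_windows(panel$map, span_bp)
  windows <- window_variance_percentages(
    windows, states[[n_iterations]]$u_hat, Z, vc$sigma2_a, denominator)
  structure(list(states = states, windows = windows, map = panel$map,
                 gids = gids, vc = vc, lambda = lambda,
                 n_iterations = n_iterations, blend_alpha = blend_alpha,
                 span_bp = span_bp, trait = model$trait),
            class = "wssgwas_fit")
}

#' @export
print.wssgwas_fit <- function(x, ...) {
  top <- dplyr::arrange(x$windows, dplyr::desc(.data$pct_variance))
  cat("<wssgwas_fit> trait ", x$trait, ": ", x$n_iterations, " iterations, ",
      nrow(x$windows), " windows of ", x$span_bp / 1e6, " Mb; top window ",
      "chr", top$chrom[1], ":", round(top$midpoint[1] / 1e6, 2), " Mb (",
      round(top$pct_variance[1], 2), "% of genetic variance)\n", sep = "")
  invisible(x)
}

#' @rdname run_wssgwas
#' @param x a `wssgwas_fit`.
#' @param ... unused.
#' @method tidy wssgwas_fit
#' @export
tidy.wssgwas_fit <- function(x, ...) {
  out <- x$windows
  out$trait <- x$trait
  dplyr::select(out, "trait", "window", "chrom", "start_pos", "end_pos",
                "midpoint", "n_snps", "pct_variance")
}

#' @rdname run_wssgwas
#' @method glance wssgwas_fit
#' @export
glance.wssgwas_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, n_iterations = x$n_iterations,
    n_windows = nrow(x$windows), n_snps = nrow(x$map),
    n_genotyped = length(x$gids),
    max_pct_variance = max(x$windows$pct_variance),
    identity_resid = x$states[[x$n_iterations]]$identity_resid,
    trace_D = sum(x$states[[x$n_iterations]]$weights)
  )
}

#' Per-iteration Manhattan table
#'
#' Window variance percentages recomputed from each iteration's SNP effects,
#' suitable for plotting or export (`chromosome, midpoint bp, percentage,
#' trait, iteration`).
#'
#' @param fit a `wssgwas_fit`.
#' @param Z_centered optional centered gene contents (recomputed percentages
#'   use the stored windows when omitted, final iteration only).
#' @return Tibble with one row per window and iteration.
#' @export
manhattan_table <- function(fit, Z_centered = NULL) {
  base <- define_windows(fit$map, fit$span_bp)
  if (is.null(Z_centered)) {
    out <- tidy(fit)
    out$iteration <- fit$n_iterations
    return(dplyr::select(out, "chrom", "midpoint", "pct_variance", "trait",
                         "iteration"))
  }
  dplyr::bind_rows(lapply(fit$states, function(st) {
    w <- window_variance_percentages(base, st$u_hat, Z_centered, fit$vc$sigma2_a)
    tibble::tibble(chrom = w$chrom, midpoint = w$midpoint,
                   pct_variance = w$pct_variance, trait = fit$trait,
                   iteration = st$iteration)
  }))
}

#' @rdname run_wssgwas
#' @param object a `wssgwas_fit`.
#' @param threshold_pct horizontal reference line (default the 1% selection
#'   threshold); `NULL` suppresses it.
#' @method autoplot wssgwas_fit
#' @export
autoplot.wssgwas_fit <- function(object, threshold_pct = 1, ...) {
  tab <- tidy(object)
  tab$chrom <- factor(tab$chrom, levels = unique(object$map$chrom))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$midpoint / 1e6,
                                         y = .data$pct_variance,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (Mb)",
                  y = "Genetic variance explained by window (%)",
                  title = paste0("SNP windows of ", object$span_bp / 1e6,
                                 " Mb - ", object$trait)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold_pct)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_pct, linetype = 2)
  }
  p
}

#' Write a Manhattan table TSV
#'
#' @param tab a tibble from [manhattan_table()].
#' @param path output path.
#' @export
write_manhattan_tsv <- function(tab, path) {
  readr::write_tsv(tab, path)
  invisible(path)
}
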