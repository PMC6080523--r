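#' Assemble a repeatability animal model
#'
#' Builds the design matrices of the single-trait repeatability model
#' `y = X b + Z a + W p + e`, where `a` is the additive genetic effect over
#' all pedigree animals (`a ~ N(0, K sigma2_a)` with `K` the pedigree or
#' combined relationship matrix), `p` the permanent environment effect of
#' each animal with records, and `e` the residual. Fixed effects are an
#' intercept, one dummy-coded factor per entry of `fixed` (one level dropped
#' per factor) and mean-centered covariate columns.
#'
#' @param records tibble of phenotype records with columns `animal`, the
#'   response column, the fixed-effect factor columns and covariate columns.
#'   When a `trait` column is present, rows are filtered to `trait_name`.
#' @param ped ordered pedigree tibble covering every record's animal; its
#'   A-inverse is the default relationship inverse.
#' @param trait_name trait to analyse (matched against a `trait` column if
#'   present). Response values are assumed already on the analysis scale
#'   (e.g. log-transformed counts).
#' @param value name of the response column.
#' @param fixed character vector of fixed-effect factor column names.
#' @param covariates character vector of covariate column names (centered).
#' @param k_inv optional relationship inverse to use instead of the pedigree
#'   A-inverse (e.g. an H-inverse); must carry the pedigree's animal ids.
#' @param constraint which factor level to drop: `"first"` (default) or
#'   `"last"`. REML estimates are invariant to this choice.
#' @return An object of class `trait_model`.
#' @export
build_model <- function(records, ped, trait_name = NULL, value = "value",
                        fixed = "fixed_group",
                        covariates = c("interval_days", "age_months"),
                        k_inv = NULL, constraint = c("first", "last")) {
  constraint <- match.arg(constraint)
  validate_pedigree(ped)
  if (!is.null(trait_name) && "trait" %in% names(records)) {
    records <- records[records$trait == trait_name, , drop = FALSE]
    if (!nrow(records)) stop_wssgwas(paste0("no records for trait ", trait_name), "model_empty")
  }
  stopifnot(value %in% names(records), all(fixed %in% names(records)),
            all(covariates %in% names(records)))
  unknown <- setdiff(unique(records$animal), ped$animal)
  if (length(unknown)) {
    stop_wssgwas(paste0("records for animals absent from the pedigree: ",
                        paste(head(unknown, 10), collapse = ", ")),
                 "model_unknown_animal")
  }
  n <- nrow(records)
  y <- as.numeric(records[[value]])
  if (anyNA(y)) stop_wssgwas("missing response values", "model_invalid")

  X_parts <- list(`(Intercept)` = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  for (f in fixed) {
    fac <- factor(records[[f]])
    fac <- droplevels(fac)
    if (nlevels(fac) < 1L) {
      stop_wssgwas(paste0("fixed effect ", f, " has no non-empty level"), "model_invalid")
    }
    if (nlevels(fac) > 1L) {
      keep <- if (constraint == "first") levels(fac)[-1] else
        levels(fac)[-nlevels(fac)]
      Xf <- sapply(keep, function(lv) as.numeric(fac == lv))
      colnames(Xf) <- paste0(f, keep)
      X_parts[[f]] <- Xf
    }
  }
  for (cv in covariates) {
    col <- as.numeric(records[[cv]])
    X_parts[[cv]] <- matrix(col - mean(col), n, 1, dimnames = list(NULL, cv))
  }
  X <- do.call(cbind, X_parts)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_wssgwas(paste0("fixed-effect design is rank deficient (confounded: ",
                        paste(bad, collapse = ", "), ")"), "model_singular")
  }

  ids_a <- ped$animal
  ids_p <- sort(unique(records$animal))
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = match(records$animal, ids_a),
                             x = 1, dims = c(n, length(ids_a)))
  W <- Matrix::sparseMatrix(i = seq_len(n), j = match(records$animal, ids_p),
                            x = 1, dims = c(n, length(ids_p)))
  if (is.null(k_inv)) k_inv <- build_A_inverse(ped)
  if (!identical(rownames(k_inv), ids_a)) {
    if (!all(ids_a %in% rownames(k_inv))) {
      stop_wssgwas("relationship inverse does not cover all pedigree animals", "ids_missing")
    }
    k_inv <- k_inv[ids_a, ids_a]
  }
  structure(list(y = y, X = X, Za = Za, W = W, k_inv = k_inv, ped = ped,
                 ids_a = ids_a, ids_p = ids_p, records = records,
                 trait = trait_name %||% value, rank_X = qrX$rank,
                 constraint = constraint),
            class = "trait_model")
}

#' Replace the relationship inverse of a model
#'
#' Swap in a different relationship inverse (typically an H-inverse from
#' [build_H_inverse()]) while keeping all design matrices.
#'
#' @param model a [build_model()] object.
#' @param k_inv relationship inverse over the model's pedigree animals.
#' @return The updated `trait_model`.
#' @export
set_relationship_inverse <- function(model, k_inv) {
  stopifnot(inherits(model, "trait_model"))
  if (!all(model$ids_a %in% rownames(k_inv))) {
    stop_wssgwas("relationship inverse does not cover all pedigree animals", "ids_missing")
  }
  model$k_inv <- k_inv[model$ids_a, model$ids_a]
  model
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model> ", length(x$y), " records, ", length(x$ids_p),
      " animals with records, ", length(x$ids_a), " pedigree animals, ",
      ncol(x$X), " fixed-effect columns\n", sep = "")
  invisible(x)
}

#' Variance components of the repeatability model
#'
#' @param sigma2_a,sigma2_p,sigma2_e additive genetic, permanent environment
#'   and residual variances (trait units squared). `sigma2_p = 0` is allowed
#'   for models without a permanent-environment term.
#' @return A list of class `variance_components` with derived `h2` and
#'   `repeatability`.
#' @export
variance_components <- function(sigma2_a, sigma2_p, sigma2_e) {
  if (sigma2_a <= 0 || sigma2_e <= 0 || sigma2_p < 0) {
    stop_wssgwas("variances must be positive (sigma2_p may be zero)", "vc_invalid")
  }
  tot <- sigma2_a + sigma2_p + sigma2_e
  structure(list(sigma2_a = sigma2_a, sigma2_p = sigma2_p, sigma2_e = sigma2_e,
                 h2 = sigma2_a / tot, repeatability = (sigma2_a + sigma2_p) / tot),
            class = "variance_components")
}

# Internal: dense MME coefficient matrix and right-hand side.
# scale = "ratio": classic form with variance ratios (for solving);
# scale = "rinv" : R^-1-scaled form whose inverse gives prediction error
#                  (co)variances (for REML).
assemble_mme <- function(model, vc, scale = c("ratio", "rinv"), use_pe = TRUE) {
  scale <- match.arg(scale)
  X <- model$X; Za <- model$Za; W <- model$W; y <- model$y
  p <- ncol(X); qa <- ncol(Za); qp <- ncol(W)
  XX <- crossprod(X)
  XZ <- as.matrix(Matrix::crossprod(Matrix::Matrix(X, sparse = FALSE), Za))
  ZZ <- as.matrix(Matrix::crossprod(Za))
  ka <- vc$sigma2_e / vc$sigma2_a
  blocks_p <- use_pe && vc$sigma2_p > 0
  if (blocks_p) {
    XW <- as.matrix(Matrix::crossprod(Matrix::Matrix(X, sparse = FALSE), W))
    ZW <- as.matrix(Matrix::crossprod(Za, W))
    WW <- as.matrix(Matrix::crossprod(W))
    kp <- vc$sigma2_e / vc$sigma2_p
    C <- rbind(
      cbind(XX, XZ, XW),
      cbind(t(XZ), ZZ + ka * model$k_inv, ZW),
      cbind(t(XW), t(ZW), WW + diag(kp, qp))
    )
    rhs <- c(crossprod(X, y), as.numeric(Matrix::crossprod(Za, y)),
             as.numeric(Matrix::crossprod(W, y)))
  } else {
    C <- rbind(cbind(XX, XZ), cbind(t(XZ), ZZ + ka * model$k_inv))
    rhs <- c(crossprod(X, y), as.numeric(Matrix::crossprod(Za, y)))
  }
  if (scale == "rinv") {
    C <- C / vc$sigma2_e
    # replace the ratio-scaled G^-1 blocks by 1/sigma2 blocks: identical by
    # construction (k/sigma2_e = 1/sigma2), nothing to adjust
    rhs <- rhs / vc$sigma2_e
  }
  list(C = C, rhs = rhs, p = p, qa = qa, qp = if (blocks_p) qp else 0L,
       use_pe = blocks_p)
}

#' Solve the mixed-model equations
#'
#' Henderson's MME for the repeatability animal model at fixed variance
#' components, by dense Cholesky factorisation. Singular systems raise an
#' error naming the confounded block rather than silently pseudo-inverting.
#'
#' @param model a [build_model()] object.
#' @param vc a [variance_components()] (or `vc_fit`) object.
#' @return An object of class `mme_fit` with fixed-effect estimates, GEBV
#'   for every pedigree animal, permanent-environment estimates and solver
#'   diagnostics (relative normal-equation residual).
#' @export
solve_mme <- function(model, vc) {
  stopifnot(inherits(model, "trait_model"))
  mme <- assemble_mme(model, vc, "ratio")
  ch <- tryCatch(chol(mme$C), error = function(e) NULL)
  if (is.null(ch)) {
    stop_wssgwas("MME coefficient matrix is singular (confounded fixed/random blocks)",
                 "mme_singular")
  }
  sol <- backsolve(ch, forwardsolve(t(ch), mme$rhs))
  resid_ne <- max(abs(mme$C %*% sol - mme$rhs)) / max(abs(mme$rhs))
  p <- mme$p; qa <- mme$qa; qp <- mme$qp
  beta <- sol[seq_len(p)]
  a_hat <- stats::setNames(sol[p + seq_len(qa)], model$ids_a)
  p_hat <- if (qp) stats::setNames(sol[p + qa + seq_len(qp)], model$ids_p) else
    stats::setNames(numeric(0), character(0))
  fitted <- as.numeric(model$X %*% beta + model$Za %*% a_hat +
                         (if (qp) model$W %*% p_hat else 0))
  structure(list(
    fixed = tibble::tibble(term = colnames(model$X), estimate = beta),
    gebv = a_hat, pe = p_hat, vc = vc,
    fitted = fitted, residuals = model$y - fitted,
    diagnostics = list(normal_eq_rel_resid = resid_ne),
    trait = model$trait
  ), class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat("<mme_fit> trait ", x$trait, ": ", nrow(x$fixed), " fixed effects, ",
      length(x$gebv), " GEBV, ", length(x$pe), " PE effects; ",
      "normal-eq rel. residual ", format(x$diagnostics$normal_eq_rel_resid,
                                         digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname solve_mme
#' @param x an `mme_fit`.
#' @param effects which block to return in `tidy()`: fixed effects, GEBV or
#'   permanent-environment estimates.
#' @param ... unused.
#' @method tidy mme_fit
#' @export
tidy.mme_fit <- function(x, effects = c("fixed", "gebv", "pe"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    fixed = x$fixed,
    gebv = tibble::tibble(animal = names(x$gebv), gebv = unname(x$gebv)),
    pe = tibble::tibble(animal = names(x$pe), pe = unname(x$pe))
  )
}
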