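#' Estimate variance components by REML
#'
#' Maximises the restricted likelihood of the repeatability animal model in
#' the variance components `(sigma2_a, sigma2_p, sigma2_e)`. The first few
#' iterations are EM-REML steps (monotone, slow); once the trajectory is
#' stable the update switches to average-information (AI) steps, falling back
#' to an EM step whenever an AI step leaves the parameter space or decreases
#' the restricted likelihood. Convergence is declared when the maximum
#' relative parameter change falls below `tol`.
#'
#' Standard errors come from the inverse AI matrix at the optimum (the AI
#' matrix is the average of observed and expected information); heritability
#' and repeatability standard errors use the delta method.
#'
#' @param model a [build_model()] object (must have more records than fixed
#'   effect parameters).
#' @param start optional [variance_components()] starting values; defaults
#'   to an even split of the phenotypic variance.
#' @param tol relative-change convergence tolerance (default `1e-8`).
#' @param max_iter maximum iterations before aborting with the trajectory
#'   attached to the error condition.
#' @param n_em_start number of initial plain EM steps before AI steps are
#'   attempted.
#' @param verbose print per-iteration progress.
#' @return An object of class `vc_fit` (also `variance_components`): the
#'   estimates, their standard errors, `h2` and `repeatability` with
#'   delta-method standard errors, the restricted log-likelihood (up to a
#'   constant), the iteration trajectory, and a `boundary` flag set when a
#'   variance was pinned at the lower bound `1e-10` times the phenotypic
#'   variance.
#' @export
estimate_reml <- function(model, start = NULL, tol = 1e-8, max_iter = 200L,
                          n_em_start = 3L, verbose = FALSE) {
  stopifnot(inherits(model, "trait_model"))
  n <- length(model$y)
  if (n <= model$rank_X) {
    stop_wssgwas("need more records than fixed-effect parameters", "reml_invalid")
  }
  vy <- stats::var(model$y)
  lower <- 1e-10 * vy
  theta <- if (is.null(start)) c(a = 0.25, p = 0.25, e = 0.5) * vy else
    c(a = start$sigma2_a, p = max(start$sigma2_p, lower * 10), e = start$sigma2_e)

  # constant pieces
  X <- model$X; Za <- model$Za; W <- model$W; y <- model$y
  p <- ncol(X); qa <- ncol(Za); qp <- ncol(W)
  Kinv <- model$k_inv
  XX <- crossprod(X)
  Xs <- Matrix::Matrix(X, sparse = FALSE)
  XZ <- as.matrix(Matrix::crossprod(Xs, Za))
  XW <- as.matrix(Matrix::crossprod(Xs, W))
  ZZ <- as.matrix(Matrix::crossprod(Za))
  ZW <- as.matrix(Matrix::crossprod(Za, W))
  WW <- as.matrix(Matrix::crossprod(W))
  Xy <- as.numeric(crossprod(X, y))
  Zy <- as.numeric(Matrix::crossprod(Za, y))
  Wy <- as.numeric(Matrix::crossprod(W, y))
  yy <- sum(y^2)
  n_mme <- p + qa + qp
  ia <- p + seq_len(qa)
  ip <- p + qa + seq_len(qp)

  # one REML evaluation at theta: solutions, traces, score, loglik
  evaluate <- function(theta) {
    s2a <- theta[1]; s2p <- theta[2]; s2e <- theta[3]
    M <- rbind(cbind(XX, XZ, XW),
               cbind(t(XZ), ZZ + Kinv * (s2e / s2a), ZW),
               cbind(t(XW), t(ZW), WW + diag(s2e / s2p, qp))) / s2e
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Cm <- chol2inv(ch)
    logdetM <- 2 * sum(log(diag(ch)))
    rhs <- c(Xy, Zy, Wy) / s2e
    sol <- as.numeric(Cm %*% rhs)
    yPy <- yy / s2e - sum(sol * rhs)
    ll <- -0.5 * (n * log(s2e) + qa * log(s2a) + qp * log(s2p) + logdetM + yPy)
    ahat <- sol[ia]; phat <- sol[ip]
    tr_a <- sum(Kinv * Cm[ia, ia])          # tr(K^-1 C_aa)
    tr_p <- sum(diag(Cm[ip, ip]))           # tr(C_pp)
    aKa <- as.numeric(crossprod(ahat, Kinv %*% ahat))
    pp <- sum(phat^2)
    ehat <- y - as.numeric(X %*% sol[seq_len(p)]) -
      as.numeric(Za %*% ahat) - as.numeric(W %*% phat)
    trP <- (n - n_mme + tr_a / s2a + tr_p / s2p) / s2e
    score <- c(
      a = -0.5 * ((qa - tr_a / s2a) / s2a - aKa / s2a^2),
      p = -0.5 * ((qp - tr_p / s2p) / s2p - pp / s2p^2),
      e = -0.5 * (trP - sum(ehat^2) / s2e^2)
    )
    list(ll = ll, sol = sol, Cm = Cm, ahat = ahat, phat = phat, ehat = ehat,
         tr_a = tr_a, tr_p = tr_p, aKa = aKa, pp = pp, score = score,
         rhs = rhs, s2 = theta)
  }

  em_step <- function(ev) {
    c(a = (ev$aKa + ev$tr_a) / qa,
      p = (ev$pp + ev$tr_p) / qp,
      e = (yy - sum(ev$sol * c(Xy, Zy, Wy))) / (n - model$rank_X))
  }

  ai_matrix <- function(ev) {
    s2a <- ev$s2[1]; s2p <- ev$s2[2]; s2e <- ev$s2[3]
    f <- cbind(a = as.numeric(Za %*% ev$ahat) / s2a,
               p = as.numeric(W %*% ev$phat) / s2p,
               e = ev$ehat / s2e)
    Pf <- apply(f, 2, function(v) {
      wtv <- c(as.numeric(crossprod(X, v)), as.numeric(Matrix::crossprod(Za, v)),
               as.numeric(Matrix::crossprod(W, v))) / s2e
      t1 <- as.numeric(ev$Cm %*% wtv)
      (v - as.numeric(X %*% t1[seq_len(p)]) - as.numeric(Za %*% t1[ia]) -
         as.numeric(W %*% t1[ip])) / s2e
    })
    AI <- 0.5 * crossprod(f, Pf)
    (AI + t(AI)) / 2
  }

  trajectory <- list()
  ev <- evaluate(theta)
  if (is.null(ev)) stop_wssgwas("MME singular at starting values", "reml_singular")
  converged <- FALSE
  fixed <- c(a = FALSE, p = FALSE, e = FALSE)   # components pinned at the bound
  used <- "start"
  for (iter in seq_len(max_iter)) {
    trajectory[[iter]] <- tibble::tibble(
      iteration = iter - 1L, sigma2_a = theta[1], sigma2_p = theta[2],
      sigma2_e = theta[3], loglik = ev$ll, step = used)
    # release a pinned component whose score has turned positive
    release <- fixed & ev$score > 0
    if (any(release)) {
      fixed[release] <- FALSE
      theta[release] <- 1e-4 * vy
      ev <- evaluate(theta)
    }
    theta_new <- NULL
    used <- "em"
    free <- !fixed
    if (iter > n_em_start && sum(free) > 0L) {
      AI <- ai_matrix(ev)
      dir <- tryCatch(solve(AI[free, free, drop = FALSE], ev$score[free]),
                      error = function(e) NULL)
      if (!is.null(dir) && all(is.finite(dir))) {
        stepsize <- 1
        for (h in seq_len(8L)) {   # halve the AI step until feasible & uphill
          cand <- theta
          cand[free] <- theta[free] + stepsize * dir
          if (all(cand > lower)) {
            ev_cand <- evaluate(cand)
            if (!is.null(ev_cand) && ev_cand$ll >= ev$ll - 1e-10) {
              theta_new <- cand; ev_new <- ev_cand; used <- "ai"
              break
            }
          }
          stepsize <- stepsize / 2
        }
        # AI wants a small component negative: pin it at the bound when that
        # does not lower the restricted likelihood (boundary optimum)
        if (is.null(theta_new)) {
          for (j in which(free & ev$score < 0 & theta < 1e-3 * vy)) {
            cand <- theta; cand[j] <- lower
            ev_cand <- evaluate(cand)
            if (!is.null(ev_cand) && ev_cand$ll >= ev$ll - 1e-10) {
              theta_new <- cand; ev_new <- ev_cand
              fixed[j] <- TRUE; used <- "pin"
              break
            }
          }
        }
      }
    }
    if (is.null(theta_new)) {
      theta_new <- pmax(em_step(ev), lower)
      theta_new[fixed] <- lower
      ev_new <- evaluate(theta_new)
      if (is.null(ev_new)) stop_wssgwas("MME became singular during EM", "reml_singular")
    }
    delta <- if (any(!fixed)) {
      max(abs(theta_new - theta)[!fixed] / pmax(abs(theta[!fixed]), 1e-6 * vy))
    } else 0
    if (verbose) {
      message(sprintf("iter %3d [%s] ll=%.6f s2a=%.5g s2p=%.5g s2e=%.5g d=%.2e",
                      iter, used, ev_new$ll, theta_new[1], theta_new[2],
                      theta_new[3], delta))
    }
    theta <- theta_new; ev <- ev_new
    if (delta < tol && used != "pin") { converged <- TRUE; break }
  }
  trajectory <- dplyr::bind_rows(trajectory)
  if (!converged) {
    stop_wssgwas(paste0("REML did not converge in ", max_iter, " iterations"),
                 "reml_no_convergence", trajectory = trajectory)
  }
  boundary <- any(theta <= lower * 1.01)
  if (boundary) {
    rlang::warn("a variance component is pinned at its lower bound")
  }
  AI <- ai_matrix(ev)
  Vtheta <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(Vtheta), 0))
  tot <- sum(theta)
  g_h2 <- c(tot - theta[1], -theta[1], -theta[1]) / tot^2
  g_rep <- c(theta[3], theta[3], -(theta[1] + theta[2])) / tot^2
  h2_se <- sqrt(max(as.numeric(t(g_h2) %*% Vtheta %*% g_h2), 0))
  rep_se <- sqrt(max(as.numeric(t(g_rep) %*% Vtheta %*% g_rep), 0))

  out <- variance_components(theta[1], theta[2], theta[3])
  out$se <- c(sigma2_a = se[1], sigma2_p = se[2], sigma2_e = se[3])
  out$h2_se <- h2_se
  out$repeatability_se <- rep_se
  out$loglik <- ev$ll
  out$iterations <- nrow(trajectory)
  out$converged <- TRUE
  out$boundary <- boundary
  out$trajectory <- trajectory
  out$constraint <- model$constraint
  class(out) <- c("vc_fit", "variance_components")
  out
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> REML variance components (", x$iterations, " iterations)\n",
      sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname estimate_reml
#' @param x a `vc_fit`.
#' @param ... unused.
#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma2_a", "sigma2_p", "sigma2_e", "h2", "repeatability"),
    estimate = c(x$sigma2_a, x$sigma2_p, x$sigma2_e, x$h2, x$repeatability),
    std.error = c(x$se, x$h2_se, x$repeatability_se)
  )
}

#' @rdname estimate_reml
#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, repeatability = x$repeatability,
                 logLik = x$loglik, iterations = x$iterations,
                 converged = x$converged, boundary = x$boundary)
}

#' Write a variance-component report TSV
#'
#' One row per component plus the derived ratios, mirroring the usual
#' additive genetic / permanent environment / residual layout.
#'
#' @param vc a `vc_fit` or [variance_components()] object.
#' @param path output path.
#' @export
write_vc_report <- function(vc, path) {
  tab <- if (inherits(vc, "vc_fit")) tidy(vc) else tibble::tibble(
    term = c("sigma2_a", "sigma2_p", "sigma2_e", "h2", "repeatability"),
    estimate = c(vc$sigma2_a, vc$sigma2_p, vc$sigma2_e, vc$h2, vc$repeatability),
    std.error = NA_real_)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML log-likelihood (up to an additive constant not
#' depending on the variance components) of a repeatability model, using the
#' mixed-model-equations identity
#' `-2 l = n log s2e + q_a log s2a + q_p log s2p + log|M| + y'Py`.
#'
#' @param model a [build_model()] object.
#' @param vc a [variance_components()] object (all variances positive).
#' @return Scalar log-likelihood.
#' @export
reml_loglik <- function(model, vc) {
  stopifnot(inherits(model, "trait_model"))
  X <- model$X; Za <- model$Za; W <- model$W; y <- model$y
  n <- length(y); p <- ncol(X); qa <- ncol(Za); qp <- ncol(W)
  s2a <- vc$sigma2_a; s2p <- vc$sigma2_p; s2e <- vc$sigma2_e
  if (min(s2a, s2p, s2e) <= 0) stop_wssgwas("variances must be positive", "vc_invalid")
  Xs <- Matrix::Matrix(X, sparse = FALSE)
  M <- rbind(
    cbind(crossprod(X), as.matrix(Matrix::crossprod(Xs, Za)),
          as.matrix(Matrix::crossprod(Xs, W))),
    cbind(t(as.matrix(Matrix::crossprod(Xs, Za))),
          as.matrix(Matrix::crossprod(Za)) + model$k_inv * (s2e / s2a),
          as.matrix(Matrix::crossprod(Za, W))),
    cbind(t(as.matrix(Matrix::crossprod(Xs, W))),
          t(as.matrix(Matrix::crossprod(Za, W))),
          as.matrix(Matrix::crossprod(W)) + diag(s2e / s2p, qp))
  ) / s2e
  ch <- chol(M)
  rhs <- c(as.numeric(crossprod(X, y)), as.numeric(Matrix::crossprod(Za, y)),
           as.numeric(Matrix::crossprod(W, y))) / s2e
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  yPy <- sum(y^2) / s2e - sum(sol * rhs)
  -0.5 * (n * log(s2e) + qa * log(s2a) + qp * log(s2p) +
            2 * sum(log(diag(ch))) + yPy)
}
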