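#' Model frame for (multi-)kernel mixed models
#'
#' Bundles the response, the fixed-effects design (intercept plus a
#' treatment-coded breeding-set/year factor, first level as reference) and one
#' or more genomic relationship kernels. Kernels may cover more lines than are
#' phenotyped; unphenotyped lines receive GEBVs through their kernel rows.
#'
#' @param y named numeric vector of phenotypes (names = line ids).
#' @param kernels a `g_matrix` or list of them, all with identical row names
#'   that include every phenotyped line.
#' @param sets optional factor/character of set labels for the phenotyped
#'   lines (in the order of `y`); adds a fixed set effect.
#' @param X optional explicit fixed-effects design matrix (overrides `sets`).
#' @return object of class `model_frame`.
#' @export
model_frame <- function(y, kernels, sets = NULL, X = NULL) {
  if (inherits(kernels, "g_matrix") || (is.matrix(kernels) && is.null(names(kernels))))
    kernels <- list(G = kernels)
  stopifnot(length(kernels) >= 1L)
  kn <- names(kernels)
  if (is.null(kn)) names(kernels) <- kn <- paste0("K", seq_along(kernels))
  all_lines <- rownames(kernels[[1]])
  for (k in kernels) stopifnot(identical(rownames(as.matrix(k)), all_lines))
  if (is.null(names(y))) stop("y must be named by line id")
  if (!all(names(y) %in% all_lines)) stop("phenotyped line absent from kernel")
  keep <- !is.na(y)
  y <- y[keep]
  if (!is.null(sets)) sets <- sets[keep]
  if (length(unique(names(y))) < 2L) stop("need >= 2 distinct phenotyped lines")

  if (is.null(X)) {
    if (is.null(sets)) {
      X <- matrix(1, length(y), 1L, dimnames = list(names(y), "(Intercept)"))
    } else {
      X <- stats::model.matrix(~ factor(sets))
      rownames(X) <- names(y)
      colnames(X)[1] <- "(Intercept)"
    }
  } else {
    X <- as.matrix(X)[keep, , drop = FALSE]
  }
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design is rank deficient (set factor aliased)")

  structure(list(y = y, X = X, kernels = kernels,
                 lines = all_lines, obs = names(y)),
            class = "model_frame")
}

# kernels restricted to the phenotyped lines, ridge applied
obs_kernels <- function(frame, ridge = 1e-6) {
  lapply(frame$kernels, function(G)
    add_ridge(as.matrix(G)[frame$obs, frame$obs, drop = FALSE], ridge))
}

reml_ll <- function(cV, B, y, Py) {
  ld_V <- 2 * sum(log(diag(cV)))
  ld_B <- determinant(B, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (ld_V + ld_B + crossprod(y, Py)))
}

#' REML variance components by average information with EM fallback
#'
#' Fits y = Xb + sum_k u_k + e with u_k ~ N(0, G_k sigma_k^2) and
#' e ~ N(0, I sigma_e^2) by average-information REML. Steps that would leave
#' the parameter space trigger step halving and then an EM update; variances
#' are kept >= `floor` by reflection with a warning. Convergence requires a
#' relative log-likelihood change below `tol_ll` and a scaled gradient norm
#' below `tol_grad`. Approximate standard errors come from the inverse
#' average-information matrix; a near-singular AI matrix (flat likelihood
#' direction, e.g. G = I with one record per line) raises an
#' identifiability warning.
#'
#' @param frame a [model_frame()].
#' @param start optional named start values (kernel variances then residual).
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   iteration trace.
#' @param tol_ll,tol_grad convergence tolerances (1e-8, 1e-6).
#' @param floor lower bound for variances.
#' @param ridge diagonal ridge added to each kernel.
#' @return object of class `variance_components`: named `variances` and `se`
#'   (kernels then `residual`), `loglik`, `d` (average kernel diagonals),
#'   `n_iter`, `converged`, `trace`.
#' @export
fit_reml <- function(frame, start = NULL, max_iter = 200L,
                     tol_ll = 1e-8, tol_grad = 1e-6, floor = 1e-10,
                     ridge = 1e-6) {
  stopifnot(inherits(frame, "model_frame"))
  y <- frame$y
  X <- frame$X
  n <- length(y)
  Gs <- obs_kernels(frame, ridge)
  K <- length(Gs)
  comp_names <- c(names(Gs), "residual")

  v0 <- stats::var(stats::lm.fit(X, y)$residuals) * n / max(n - ncol(X), 1)
  theta <- if (is.null(start)) c(rep(v0 / (K + 1), K), v0 / (K + 1) * 1) else
    as.numeric(start)
  theta <- pmax(theta, floor)

  eval_parts <- function(theta) {
    V <- diag(theta[K + 1], n)
    for (k in seq_len(K)) V <- V + theta[k] * Gs[[k]]
    cV <- chol(V)
    Vi <- chol2inv(cV)
    XtVi <- crossprod(X, Vi)
    B <- XtVi %*% X
    Bi <- solve(B)
    P <- Vi - crossprod(XtVi, Bi %*% XtVi)
    Py <- as.numeric(P %*% y)
    GPy <- c(lapply(Gs, function(G) as.numeric(G %*% Py)), list(Py))
    trPG <- c(vapply(Gs, function(G) sum(P * G), 0), sum(diag(P)))
    yPGPy <- vapply(GPy, function(v) sum(Py * v), 0)
    grad <- -0.5 * (trPG - yPGPy)
    PGPy <- lapply(GPy, function(v) as.numeric(P %*% v))
    AI <- matrix(0, K + 1, K + 1)
    for (i in seq_len(K + 1)) for (j in i:(K + 1)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(GPy[[i]] * PGPy[[j]])
    }
    list(ll = reml_ll(cV, B, y, Py), grad = grad, AI = AI, yPGPy = yPGPy,
         trPG = trPG)
  }

  cur <- eval_parts(theta)
  trace <- data.frame(iter = 0L, ll = cur$ll,
                      t(stats::setNames(theta, comp_names)))
  converged <- FALSE
  reflected <- FALSE
  for (it in seq_len(max_iter)) {
    # active-set AI step: components pinned at the floor whose gradient
    # points outward are frozen, and the Newton step is solved over the free
    # components with a minimal-norm (pseudo-inverse) solve so flat
    # likelihood directions get no update instead of stalling
    free <- !(theta <= floor * 1.01 & cur$grad < 0)
    step <- tryCatch({
      st <- numeric(K + 1)
      if (any(free)) {
        sv <- svd(cur$AI[free, free, drop = FALSE])
        pos <- sv$d > max(sv$d) * 1e-10
        st[free] <- as.numeric(sv$v[, pos, drop = FALSE] %*%
                                 (crossprod(sv$u[, pos, drop = FALSE],
                                            cur$grad[free]) / sv$d[pos]))
      }
      st
    }, error = function(e) NULL)
    cand <- NULL
    if (!is.null(step)) {
      h <- 1
      for (half in 1:8) {
        # projected AI step: negative proposals land on the boundary floor
        prop <- pmax(theta + h * step, floor)
        ev <- tryCatch(eval_parts(prop), error = function(e) NULL)
        if (!is.null(ev) && is.finite(ev$ll) &&
            ev$ll >= cur$ll - 1e-9 * (1 + abs(cur$ll))) {
          cand <- list(theta = prop, ev = ev); break
        }
        h <- h / 2
      }
    }
    if (is.null(cand)) {  # EM fallback step
      prop <- theta + theta^2 * (cur$yPGPy - cur$trPG) / n
      if (any(prop < 0)) { prop <- pmax(abs(prop), floor); reflected <- TRUE }
      prop <- pmax(prop, floor)
      ev <- eval_parts(prop)
      cand <- list(theta = prop, ev = ev)
    }
    ll_old <- cur$ll
    theta <- pmax(cand$theta, floor)
    # a variance that is negligible relative to the total is parked at the
    # boundary instead of crawling toward it geometrically
    tiny <- theta < 1e-4 * sum(theta)
    if (any(tiny)) {
      theta[tiny] <- floor
      cand$ev <- eval_parts(theta)
    }
    cur <- cand$ev
    trace <- rbind(trace, data.frame(iter = it, ll = cur$ll,
                                     t(stats::setNames(theta, comp_names))))
    at_bound <- any(theta <= floor * 1.01)
    rel <- abs(cur$ll - ll_old) / (abs(ll_old) + 1)
    gnorm <- sqrt(sum(cur$grad^2)) / (1 + abs(cur$ll))
    if (rel < tol_ll && (gnorm < tol_grad || at_bound)) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- simpleError("REML did not converge within max_iter")
    cond$trace <- trace
    stop(cond)
  }
  if (reflected) warning("negative variance proposal reflected to the boundary")

  se <- rep(NA_real_, K + 1)
  kap <- tryCatch(kappa(cur$AI, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e10) {
    warning("variance components are weakly identified (flat likelihood direction)")
    AIi <- tryCatch(solve(cur$AI + diag(1e-8 * max(diag(cur$AI)), K + 1)),
                    error = function(e) NULL)
  } else AIi <- solve(cur$AI)
  if (!is.null(AIi)) se <- sqrt(pmax(diag(AIi), 0))

  structure(list(
    variances = stats::setNames(theta, comp_names),
    se = stats::setNames(se, comp_names),
    loglik = cur$ll,
    d = vapply(frame$kernels, g_diag_mean, 0),
    n_iter = it, converged = converged, trace = trace
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("REML variance components (logLik ", round(x$loglik, 3), ", ",
      x$n_iter, " iters)\n", sep = "")
  print(data.frame(variance = x$variances, se = x$se))
  invisible(x)
}

#' Solve the mixed-model equations at given variance components
#'
#' Computes GLS fixed effects and BLUPs of the per-kernel genetic effects at
#' the supplied variance ratios; lines present in the kernels but not
#' phenotyped receive GEBVs through their kernel covariances (equivalent to a
#' joint system with masked records).
#'
#' @param frame a [model_frame()].
#' @param vc a [fit_reml()] result (or compatible list with `variances`).
#' @param ridge kernel ridge, as in [fit_reml()].
#' @return object of class `blup_solution`: fixed effects `b`, per-kernel
#'   BLUP matrix `u` (all kernel lines x kernels), total `gebv`, and `vc`.
#' @export
solve_mme <- function(frame, vc, ridge = 1e-6) {
  stopifnot(inherits(frame, "model_frame"))
  th <- vc$variances
  K <- length(frame$kernels)
  stopifnot(length(th) == K + 1L, all(is.finite(th)))
  y <- frame$y
  X <- frame$X
  n <- length(y)
  Gs <- obs_kernels(frame, ridge)
  V <- diag(th[K + 1], n)
  for (k in seq_len(K)) V <- V + th[k] * Gs[[k]]
  cV <- tryCatch(chol(V), error = function(e)
    stop("singular phenotypic covariance matrix even after ridge"))
  Vi <- chol2inv(cV)
  XtVi <- crossprod(X, Vi)
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- as.numeric(Vi %*% (y - X %*% b))
  u <- matrix(0, length(frame$lines), K,
              dimnames = list(frame$lines, names(frame$kernels)))
  oi <- match(frame$obs, frame$lines)
  for (k in seq_len(K)) {
    Gk <- as.matrix(frame$kernels[[k]])[frame$lines, frame$obs, drop = FALSE]
    Gk[cbind(oi, seq_along(oi))] <- Gk[cbind(oi, seq_along(oi))] + ridge
    u[, k] <- th[k] * as.numeric(Gk %*% r)
  }
  structure(list(b = stats::setNames(as.numeric(b), colnames(X)),
                 u = u, gebv = rowSums(u), vc = vc, lines = frame$lines),
            class = "blup_solution")
}

#' Narrow-sense genomic heritability
#'
#' h2 = d * sigma_g2 / (d * sigma_g2 + sigma_e2), where `d` is the average
#' diagonal element of the G-matrix used in the fit. For near-inbred cohorts
#' the VanRaden diagonal averages about 2; supplying the realized `d` keeps
#' the estimate on the single-plot scale.
#'
#' @param vc single-kernel [fit_reml()] result, or a length-2 numeric
#'   c(sigma_g2, sigma_e2).
#' @param g a `g_matrix`, or the average diagonal as a number (default 1).
#' @return heritability as a proportion.
#' @export
heritability <- function(vc, g = 1) {
  if (inherits(vc, "variance_components")) {
    if (length(vc$variances) != 2L)
      stop("heritability is defined for single-kernel fits")
    sg2 <- vc$variances[1]; se2 <- vc$variances[2]
  } else {
    stopifnot(length(vc) == 2L)
    sg2 <- vc[1]; se2 <- vc[2]
  }
  d <- if (is.numeric(g) && length(g) == 1L) g else g_diag_mean(g)
  if (d <= 0) stop("average G diagonal must be positive")
  if (sg2 + se2 <= 0) stop("heritability undefined: both variances are zero")
  as.numeric(d * sg2 / (d * sg2 + se2))
}

#' Extract GEBVs for target lines
#'
#' @param trained a [solve_mme()] result.
#' @param lines character ids of target lines (may be unphenotyped; must be
#'   present in the kernels).
#' @return named numeric GEBV vector.
#' @export
predict_gebv <- function(trained, lines) {
  stopifnot(inherits(trained, "blup_solution"))
  miss <- setdiff(lines, names(trained$gebv))
  if (length(miss)) stop("target line(s) absent from kernel: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  trained$gebv[lines]
}

# Internal: train on `train` lines, predict GEBVs for `val` lines, at fixed
# variance components. Used by the cross-validation engine.
fold_predict <- function(y, X, kernels, vc, train, val, ridge = 1e-6) {
  th <- vc$variances
  K <- length(kernels)
  yt <- y[train]
  Xt <- X[train, , drop = FALSE]
  # a fold may alias fixed-effect columns (e.g. leave-set-out leaves one set
  # level): drop them for the fold fit
  qx <- qr(Xt)
  if (qx$rank < ncol(Xt)) Xt <- Xt[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  V <- diag(th[K + 1], length(train))
  for (k in seq_len(K))
    V <- V + th[k] * add_ridge(as.matrix(kernels[[k]])[train, train, drop = FALSE], ridge)
  cV <- chol(V)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), yt))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), Xt))
  b <- solve(crossprod(Xt, Vi_X), crossprod(Xt, Vi_y))
  r <- backsolve(cV, forwardsolve(t(cV), yt - as.numeric(Xt %*% b)))
  gebv <- numeric(length(val))
  for (k in seq_len(K)) {
    Gk <- as.matrix(kernels[[k]])[val, train, drop = FALSE]
    gebv <- gebv + th[k] * as.numeric(Gk %*% r)
  }
  list(gebv = stats::setNames(gebv, val), b = as.numeric(b))
}
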