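#' Build a cross-validation fold plan
#'
#' Schemes: `loo` (one singleton fold per line), `lfo` (leave-family-out:
#' folds are connected components of the graph joining lines that share at
#' least one parent, so no parent crosses a training/validation boundary),
#' `lso` (one fold per breeding set), `kfold` (random equal folds, stratified
#' by set so each training fold keeps the set proportions), and `fraction`
#' (one random training subset of the given proportion; the rest validate).
#'
#' @param lines character line ids.
#' @param scheme one of `"loo"`, `"lfo"`, `"lso"`, `"kfold"`, `"fraction"`.
#' @param sets set labels per line (required for `lso`, used for `kfold`
#'   stratification when given).
#' @param pedigree data.frame with `line_id`, `parent1`, `parent2` (required
#'   for `lfo`).
#' @param k number of folds for `kfold`.
#' @param fraction training proportion for `fraction`.
#' @param seed integer seed for the random schemes.
#' @param max_family cap on LFO cluster size; oversized shared-parent
#'   clusters are split by full-sib family with a warning.
#' @return `fold_plan`: list with `scheme`, `folds` (list of validation-line
#'   id vectors), `seed` and scheme metadata.
#' @export
make_folds <- function(lines, scheme = c("loo", "lfo", "lso", "kfold", "fraction"),
                       sets = NULL, pedigree = NULL, k = NULL, fraction = NULL,
                       seed = NULL, max_family = Inf) {
  scheme <- match.arg(scheme)
  n <- length(lines)
  if (!is.null(seed)) set.seed(as.integer(seed))
  folds <- switch(scheme,
    loo = as.list(lines),
    lso = {
      if (is.null(sets)) stop("lso needs set labels")
      split(lines, as.character(sets))
    },
    lfo = {
      if (is.null(pedigree)) stop("lfo needs a pedigree")
      ped <- pedigree[match(lines, pedigree$line_id), ]
      if (anyNA(ped$line_id)) stop("pedigree missing line(s)")
      # bipartite line-parent graph; connected components are the clusters
      edges <- rbind(cbind(ped$line_id, paste0("par:", ped$parent1)),
                     cbind(ped$line_id, paste0("par:", ped$parent2)))
      gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
      comp <- igraph::components(gr)$membership
      cl <- split(lines, comp[lines])
      if (any(lengths(cl) > max_family)) {
        warning("LFO cluster(s) above max_family split by full-sib family")
        fam_key <- paste(ped$parent1, ped$parent2)
        big <- which(lengths(cl) > max_family)
        extra <- unlist(lapply(cl[big], function(ls)
          split(ls, fam_key[match(ls, lines)])), recursive = FALSE)
        cl <- c(cl[-big], extra)
      }
      unname(cl)
    },
    kfold = {
      if (is.null(k) || k < 2) stop("kfold needs k >= 2")
      if (k > n) stop("k exceeds number of lines")
      strat <- if (is.null(sets)) rep("all", n) else as.character(sets)
      fold_of <- integer(n)
      for (s in unique(strat)) {
        idx <- sample(which(strat == s))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
      split(lines, fold_of)
    },
    fraction = {
      if (is.null(fraction) || fraction <= 0 || fraction >= 1)
        stop("fraction must be in (0, 1)")
      tr <- sample(lines, round(fraction * n))
      list(setdiff(lines, tr))
    })
  structure(list(scheme = scheme, folds = folds, lines = lines,
                 k = k, fraction = fraction, seed = seed),
            class = "fold_plan")
}

# fixed-effect-corrected phenotypes: y - X b_hat with b_hat from the
# full-data GLS fit (single correction applied uniformly across folds)
corrected_phenotypes <- function(y, X, kernels = NULL, vc = NULL, ridge = 1e-6) {
  if (is.null(kernels) || is.null(vc)) {
    b <- stats::lm.fit(X, y)$coefficients
  } else {
    b <- fold_predict(y, X, kernels, vc, train = names(y),
                      val = names(y)[1], ridge = ridge)$b
  }
  as.numeric(y - X %*% b)
}

#' Run a cross-validation study
#'
#' For each fold, fits the requested model on the training lines and predicts
#' GEBVs for the validation lines; no validated line's phenotype contributes
#' to its own GEBV. Variance components for the GBLUP/feature models are by
#' default estimated once on all data and reused across folds
#' (`refit_per_fold = TRUE` re-estimates them inside every fold).
#'
#' @param y named phenotype vector.
#' @param plan a [make_folds()] plan covering `names(y)`.
#' @param model `"gblup"` (one kernel), `"feature"` (two kernels) or
#'   `"powerlasso"`.
#' @param kernels `g_matrix` or list of them (gblup/feature).
#' @param W dosage matrix 0/1/2 (powerlasso).
#' @param sets optional set labels (fixed effect).
#' @param vc optional precomputed [fit_reml()] components.
#' @param refit_per_fold re-estimate variance components per fold.
#' @param pl_config [power_lasso_config()] for `model = "powerlasso"`.
#' @return `cv_result`: `per_line` (line_id, fold, gebv, corrected),
#'   `r` (predictive ability), `slope`, `slope_se`, `bias` (= slope - 1),
#'   `scheme`, `n_train` summary, `vc`.
#' @export
run_cv <- function(y, plan, model = c("gblup", "feature", "powerlasso"),
                   kernels = NULL, W = NULL, sets = NULL, vc = NULL,
                   refit_per_fold = FALSE, pl_config = NULL, ridge = 1e-6) {
  model <- match.arg(model)
  stopifnot(inherits(plan, "fold_plan"))
  lines <- names(y)
  stopifnot(!is.null(lines), all(unlist(plan$folds) %in% lines))
  X <- if (is.null(sets)) matrix(1, length(y), 1, dimnames = list(lines, "(Intercept)"))
       else { m <- stats::model.matrix(~ factor(sets)); rownames(m) <- lines; m }

  if (model %in% c("gblup", "feature")) {
    if (inherits(kernels, "g_matrix") || (is.matrix(kernels))) kernels <- list(G = kernels)
    stopifnot(!is.null(kernels))
    if (is.null(vc))
      vc <- fit_reml(model_frame(y, kernels = kernels, X = X))
  }
  if (model == "powerlasso") {
    stopifnot(!is.null(W))
    W <- as.matrix(W)
    if (is.null(rownames(W))) rownames(W) <- lines
    if (is.null(pl_config)) pl_config <- power_lasso_config(chain = 6000L, burnin = 2000L)
  }

  rows <- list()
  n_train <- integer(0)
  for (f in seq_along(plan$folds)) {
    val <- plan$folds[[f]]
    train <- setdiff(lines, val)
    if (!length(val)) next
    if (length(train) < 2L) {
      warning("fold ", f, " skipped: fewer than 2 training lines")
      next
    }
    n_train <- c(n_train, length(train))
    if (model %in% c("gblup", "feature")) {
      vcf <- if (refit_per_fold)
        fit_reml(model_frame(y[train], kernels = kernels,
                             X = X[train, , drop = FALSE]))
      else vc
      gebv <- fold_predict(y, X, kernels, vcf, train, val, ridge)$gebv
    } else {
      cfg <- pl_config
      post <- sample_posterior(y[train], X[train, , drop = FALSE],
                               W[train, , drop = FALSE], cfg)
      gebv <- stats::setNames(as.numeric(W[val, , drop = FALSE] %*% post$u_mean), val)
    }
    rows[[length(rows) + 1L]] <- data.frame(line_id = val, fold = f,
                                            gebv = as.numeric(gebv),
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no validated lines: empty cross-validation result")
    return(structure(list(per_line = NULL, r = NA_real_, slope = NA_real_,
                          slope_se = NA_real_, bias = NA_real_,
                          scheme = plan$scheme, n_train = n_train, vc = vc),
                     class = "cv_result"))
  }
  per_line <- do.call(rbind, rows)
  corr <- corrected_phenotypes(y, X,
                               kernels = if (model != "powerlasso") kernels,
                               vc = if (model != "powerlasso") vc)
  names(corr) <- lines
  per_line$corrected <- corr[per_line$line_id]

  r <- predictive_ability(per_line$corrected, per_line$gebv)
  sl <- bias(per_line$corrected, per_line$gebv)
  structure(list(per_line = per_line, r = r, slope = sl$slope,
                 slope_se = sl$se, bias = sl$bias, scheme = plan$scheme,
                 n_train = n_train, vc = if (model != "powerlasso") vc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result [", x$scheme, "]: r =", round(x$r, 3),
      "slope =", round(x$slope, 3), "(bias", round(x$bias, 3), ")\n")
  invisible(x)
}

#' Predictive ability
#'
#' Pearson correlation between fixed-effect-corrected phenotypes and GEBVs
#' over the validated lines.
#'
#' @param corrected,gebvs aligned numeric vectors (>= 3 pairs, both
#'   non-constant).
#' @export
predictive_ability <- function(corrected, gebvs) {
  stopifnot(length(corrected) == length(gebvs), length(corrected) >= 3)
  if (stats::sd(gebvs) == 0) stop("constant GEBV vector: correlation undefined")
  if (stats::sd(corrected) == 0) stop("constant corrected phenotypes")
  stats::cor(corrected, gebvs)
}

#' Prediction bias (regression slope)
#'
#' Least-squares slope of corrected phenotypes on GEBVs; the expectation for
#' unbiased predictions is 1.0 and `bias = slope - 1`.
#'
#' @inheritParams predictive_ability
#' @return list with `slope`, `se`, `bias`.
#' @export
bias <- function(corrected, gebvs) {
  stopifnot(length(corrected) == length(gebvs), length(corrected) >= 3)
  if (stats::var(gebvs) == 0) stop("zero-variance GEBV vector")
  fit <- stats::lm(corrected ~ gebvs)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["gebvs", "Estimate"]),
       se = unname(sm["gebvs", "Std. Error"]),
       bias = unname(sm["gebvs", "Estimate"]) - 1)
}

#' Predictive ability versus training-set size
#'
#' Follows the reduced-training-set protocol of the source design: a random
#' fraction of the lines is selected, a leave-one-out cross-validation is run
#' *within* that subset, and the predictive ability is computed over the
#' selected lines; selection and prediction are repeated `reps` times per
#' fraction. Replicate `r` uses `seed + r` for auditability. The per-subset
#' LOO uses the closed-form identity `gebv_i = r_i - (V^-1 r)_i / (V^-1)_ii`
#' (fixed variance components, subset-level GLS fixed effects), which makes
#' each replicate O(n^3) once instead of per fold.
#'
#' @param y named phenotype vector; @param kernels G-matrix (or list).
#' @param sets optional set labels; @param vc optional variance components.
#' @param fractions selected proportions (default 0.1..0.9).
#' @param reps replicates per fraction (the reference design used 100;
#'   smaller values are allowed and recorded in the output).
#' @param seed base seed.
#' @param min_train fractions yielding fewer selected lines are skipped with
#'   a warning.
#' @return data.frame: fraction, mean_r, sd_r, reps.
#' @export
training_fraction_curve <- function(y, kernels, sets = NULL, vc = NULL,
                                    fractions = seq(0.1, 0.9, by = 0.1),
                                    reps = 100L, seed = 1L, min_train = 10L) {
  stopifnot(reps >= 2)
  if (inherits(kernels, "g_matrix") || is.matrix(kernels)) kernels <- list(G = kernels)
  lines <- names(y)
  X <- if (is.null(sets)) matrix(1, length(y), 1, dimnames = list(lines, "i"))
       else { m <- stats::model.matrix(~ factor(sets)); rownames(m) <- lines; m }
  if (is.null(vc)) vc <- fit_reml(model_frame(y, kernels = kernels, X = X))
  th <- vc$variances
  K <- length(kernels)

  loo_subset_r <- function(sub) {
    V <- diag(th[K + 1], length(sub))
    for (k in seq_len(K))
      V <- V + th[k] * add_ridge(as.matrix(kernels[[k]])[sub, sub, drop = FALSE])
    A <- chol2inv(chol(V))
    Xs <- X[sub, , drop = FALSE]
    qx <- qr(Xs)
    if (qx$rank < ncol(Xs)) Xs <- Xs[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    AX <- A %*% Xs
    b <- solve(crossprod(Xs, AX), crossprod(AX, y[sub]))
    r <- y[sub] - as.numeric(Xs %*% b)
    t <- as.numeric(A %*% r)
    gebv <- r - t / diag(A)
    predictive_ability(r, gebv)
  }

  out <- lapply(fractions, function(fr) {
    if (round(fr * length(lines)) < min_train) {
      warning("fraction ", fr, " skipped: selected set below ", min_train)
      return(NULL)
    }
    rs <- vapply(seq_len(reps), function(r) {
      set.seed(as.integer(seed) + r)
      loo_subset_r(sample(lines, round(fr * length(lines))))
    }, 0)
    data.frame(fraction = fr, mean_r = mean(rs), sd_r = stats::sd(rs),
               reps = reps)
  })
  do.call(rbind, out)
}

# internal: LOO predictive ability at fixed vc for a given kernel list
loo_r <- function(y, X, kernels, vc, ridge = 1e-6) {
  lines <- names(y)
  gebv <- vapply(lines, function(l)
    fold_predict(y, X, kernels, vc, setdiff(lines, l), l, ridge)$gebv, 0)
  corr <- corrected_phenotypes(y, X, kernels, vc)
  names(corr) <- lines
  predictive_ability(corr[lines], gebv[lines])
}

#' Split-half genomic feature cross-validation
#'
#' Lines are split once into two halves: half A is scanned by GWAS (LOCO
#' mixed-model scan) to rank SNPs by p-value; on half B, for each threshold
#' t the top-t SNPs build one G-matrix and the remainder the other, and a
#' two-kernel leave-one-out prediction is scored. A threshold equal to the
#' total SNP count degenerates to the single-kernel GBLUP.
#'
#' @param markers [marker_matrix()] for all lines.
#' @param y named phenotype vector; @param sets optional set labels.
#' @param thresholds counts of "significant" SNPs to test.
#' @param seed seed for the half split.
#' @return data.frame: threshold, r, plus attributes `split` and `ranking`.
#' @export
genomic_feature_cv <- function(markers, y, sets = NULL,
                               thresholds = c(5, 10, 50, 100, 500, 1000),
                               seed = 1L) {
  lines <- names(y)
  m <- ncol(markers$geno)
  if (any(thresholds < 1)) stop("threshold 0 is not allowed")
  if (any(thresholds > m)) stop("threshold exceeds SNP count")
  set.seed(as.integer(seed))
  A <- sample(lines, floor(length(lines) / 2))
  B <- setdiff(lines, A)
  setsA <- if (!is.null(sets)) sets[match(A, lines)]
  setsB <- if (!is.null(sets)) sets[match(B, lines)]

  scan <- gwas(y[A], markers, sets = setsA)
  ord <- order(scan$p_raw)  # untestable (NA) rank last
  ranking <- scan$snp_id[ord]

  mkB <- subset_markers(markers, lines = B)
  zB <- center_markers(mkB)
  XB <- if (is.null(setsB)) matrix(1, length(B), 1, dimnames = list(B, "i"))
        else { mm <- stats::model.matrix(~ factor(setsB)); rownames(mm) <- B; mm }

  rs <- vapply(thresholds, function(t) {
    if (t >= m) {
      kern <- list(G = vanraden_g(zB))
    } else {
      pg <- partition_g(zB, ranking[seq_len(t)])
      kern <- list(Gs = pg$Gs, Gn = pg$Gn)
    }
    vc <- fit_reml(model_frame(y[B], kernels = kern, X = XB))
    loo_r(y[B], XB, kern, vc)
  }, 0)

  out <- data.frame(threshold = thresholds, r = rs)
  attr(out, "split") <- list(gwas_half = A, prediction_half = B)
  attr(out, "ranking") <- ranking
  out
}
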