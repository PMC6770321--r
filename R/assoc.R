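#' Single-marker mixed-model association scan
#'
#' For each SNP, fits y = Xb + w_i a_i + u + e by generalized least squares
#' under Cov(y) = sigma_g2 * G_loco(chrom(i)) + sigma_e2 * I, where the
#' kinship excludes the tested SNP's chromosome (LOCO) so the SNP's own
#' signal is not absorbed, and the variance components are estimated once per
#' chromosome from the no-SNP model and then held fixed (EMMAX-style).
#' w_i uses codes +1/0/-1 with missing set to 0. The Wald statistic is
#' (a_i/SE)^2 on 1 df; p-values are then genomic-control corrected.
#'
#' @param frame a [model_frame()] whose single kernel is ignored for testing
#'   (LOCO kernels are supplied separately); only `y` and `X` are used.
#' @param markers [marker_matrix()] of the phenotyped lines.
#' @param loco_gs named list chromosome -> `g_matrix`; every chromosome in
#'   the map (including `"UN"`) must be present. Built automatically by
#'   [gwas()] if you start from markers.
#' @param vc_list optional named list chromosome -> `variance_components`
#'   (estimated if missing).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param clamp_lambda if `TRUE`, the inflation factor is clamped at 1 (the
#'   common convention); default applies it unconditionally.
#' @return `gwas_result`: data.frame (snp_id, chrom, maf, pos_freq, effect,
#'   se, chi2, p_raw, p_gc, significant, untestable) with attributes
#'   `lambda_if`, `threshold`, `vc_list`.
#' @export
single_marker_scan <- function(frame, markers, loco_gs, vc_list = NULL,
                               alpha = 0.05, clamp_lambda = FALSE) {
  stopifnot(inherits(frame, "model_frame"), inherits(markers, "marker_matrix"))
  obs <- frame$obs
  stopifnot(all(obs %in% rownames(markers$geno)))
  y <- frame$y
  X <- frame$X
  n <- length(y)
  W_all <- markers$geno[obs, , drop = FALSE]
  W_all[is.na(W_all)] <- 0
  chroms <- unique(markers$map$chrom)
  if (!all(chroms %in% names(loco_gs)))
    stop("missing LOCO G for chromosome(s): ",
         paste(setdiff(chroms, names(loco_gs)), collapse = ", "))

  m <- ncol(W_all)
  eff <- se <- chi2 <- rep(NA_real_, m)
  untestable <- rep(FALSE, m)
  vcs <- list()

  for (ch in chroms) {
    cols <- which(markers$map$chrom == ch)
    G <- loco_gs[[ch]]
    vc <- if (!is.null(vc_list) && ch %in% names(vc_list)) vc_list[[ch]] else
      fit_reml(model_frame(y, kernels = list(G = G), X = X))
    vcs[[ch]] <- vc
    th <- vc$variances
    V <- th[1] * add_ridge(as.matrix(G)[obs, obs, drop = FALSE]) + diag(th[2], n)
    cV <- chol(V)
    # whiten: after this transform the model has unit residual variance
    yt <- forwardsolve(t(cV), y)
    Xt <- forwardsolve(t(cV), X)
    Wt <- forwardsolve(t(cV), W_all[, cols, drop = FALSE])
    qX <- qr(Xt)
    ry <- qr.resid(qX, yt)
    rW <- qr.resid(qX, Wt)
    ss <- colSums(rW^2)
    ok <- ss > 1e-10
    num <- colSums(rW * ry)
    eff[cols[ok]] <- num[ok] / ss[ok]
    se[cols[ok]] <- 1 / sqrt(ss[ok])
    chi2[cols[ok]] <- num[ok]^2 / ss[ok]
    untestable[cols[!ok]] <- TRUE
  }

  p_raw <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  gc <- genomic_control(chi2, clamp = clamp_lambda)
  thr <- bonferroni_threshold(alpha, m)
  pos_freq <- ifelse(eff >= 0, markers$freq_pos, 1 - markers$freq_pos)

  res <- data.frame(
    snp_id = colnames(W_all), chrom = markers$map$chrom,
    maf = as.numeric(markers$maf), pos_freq = as.numeric(pos_freq),
    effect = eff, se = se, chi2 = chi2,
    p_raw = p_raw, p_gc = gc$p, significant = !is.na(gc$p) & gc$p < thr,
    untestable = untestable, stringsAsFactors = FALSE
  )
  structure(res, lambda_if = gc$lambda, threshold = thr, vc_list = vcs,
            class = c("gwas_result", "data.frame"))
}

#' Convenience GWAS from markers
#'
#' Builds the LOCO G-matrices (unmapped SNPs form pseudo-chromosome `"UN"`,
#' tested against the full-minus-unmapped kinship) and runs
#' [single_marker_scan()].
#'
#' @inheritParams single_marker_scan
#' @param y named phenotype vector; @param sets optional set labels.
#' @export
gwas <- function(y, markers, sets = NULL, alpha = 0.05, clamp_lambda = FALSE) {
  mk <- subset_markers(markers, lines = names(y))
  z <- center_markers(mk)
  chroms <- unique(mk$map$chrom)
  if (length(chroms) < 2L)
    stop("LOCO correction needs at least two chromosomes")
  loco <- lapply(chroms, function(ch) loco_g(z, ch))
  names(loco) <- chroms
  frame <- model_frame(y, kernels = list(G = loco[[1]]), sets = sets)
  single_marker_scan(frame, mk, loco, alpha = alpha, clamp_lambda = clamp_lambda)
}

#' Genomic-control correction
#'
#' lambda_IF = median(observed chi2) / median(chi-squared_1df); corrected
#' statistics are chi2 / lambda_IF with p-values recomputed from the 1-df
#' upper tail. Applied unconditionally by default (also when lambda < 1);
#' `clamp = TRUE` restricts correction to lambda >= 1.
#'
#' @param chi2 numeric vector of 1-df chi-squared statistics (NAs allowed).
#' @param clamp clamp lambda at 1.
#' @return list with `lambda`, corrected `chi2` and `p`.
#' @export
genomic_control <- function(chi2, clamp = FALSE) {
  if (all(is.na(chi2))) stop("no finite chi-squared values")
  m0 <- stats::qchisq(0.5, df = 1)
  lambda <- stats::median(chi2, na.rm = TRUE) / m0
  lam_use <- if (clamp) max(lambda, 1) else lambda
  cc <- chi2 / lam_use
  list(lambda = lambda, chi2 = cc,
       p = stats::pchisq(cc, df = 1, lower.tail = FALSE))
}

#' Bonferroni significance threshold
#' @param alpha family-wise error rate; @param m number of tests.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Explained genetic variance of a SNP
#'
#' 100 * 2p(1-p) a^2 / sigma_g2, the percentage of additive genetic variance
#' attributable to a biallelic SNP with allele frequency `p` and additive
#' effect `a`, on the reporting scale of the GBLUP variance component.
#'
#' @param p allele frequency in (0,1) (vectorized).
#' @param a additive effect in trait units per allele copy.
#' @param sigma_g2 additive genetic variance (> 0).
#' @return percentage(s).
#' @export
explained_variance <- function(p, a, sigma_g2) {
  if (any(sigma_g2 <= 0)) stop("sigma_g2 must be positive")
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  100 * 2 * p * (1 - p) * a^2 / sigma_g2
}

#' Trait means per homozygous allele combination
#'
#' Replicates the allele-combination summary tables: lines are classified by
#' their homozygous genotypes at the listed SNPs (+/- for the +1/-1 coded
#' allele); lines heterozygous or missing at any listed SNP are excluded and
#' counted separately.
#'
#' @param phenotypes data.frame with columns `line_id` and the trait column.
#' @param markers [marker_matrix()] covering the phenotyped lines.
#' @param snps up to 6 SNP ids.
#' @param trait name of the trait column (default `"y"`).
#' @return `qtl_summary`: data.frame of one row per observed combination with
#'   per-SNP allele columns, `mean`, `n`; attribute `n_excluded`.
#' @export
allele_class_means <- function(phenotypes, markers, snps, trait = "y") {
  stopifnot(inherits(markers, "marker_matrix"))
  if (length(snps) > 6L) stop("at most 6 SNPs (combinatorial table cap)")
  if (!all(snps %in% colnames(markers$geno))) stop("SNP not genotyped")
  ids <- phenotypes$line_id
  stopifnot(all(ids %in% rownames(markers$geno)))
  g <- markers$geno[ids, snps, drop = FALSE]
  homo <- rowSums(is.na(g) | g == 0) == 0L
  gg <- g[homo, , drop = FALSE]
  yv <- phenotypes[[trait]][homo]
  lab <- apply(gg, 2, function(col) ifelse(col > 0, "+", "-"))
  lab <- matrix(lab, ncol = length(snps), dimnames = list(NULL, snps))
  key <- apply(lab, 1, paste, collapse = "/")
  agg <- tapply(yv, key, mean)
  cnt <- tapply(yv, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "/", fixed = TRUE))
  out <- data.frame(parts, mean = as.numeric(agg), n = as.integer(cnt),
                    stringsAsFactors = FALSE)
  names(out)[seq_along(snps)] <- snps
  attr(out, "n_excluded") <- sum(!homo)
  class(out) <- c("qtl_summary", "data.frame")
  out
}
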