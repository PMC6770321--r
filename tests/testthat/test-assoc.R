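test_that("scan handles monomorphic SNPs and matches the GLS oracle at sigma_g2 = 0", {
  set.seed(42)
  n <- 50
  g <- vapply(runif(20, 0.2, 0.8), function(p) {
    x <- sample(c(-1L, 1L), n, replace = TRUE, prob = c(1 - p, p)); x
  }, integer(n))
  g[, 1] <- 1L  # monomorphic in sample
  colnames(g) <- paste0("s", 1:20)
  rownames(g) <- paste0("L", 1:n)
  map <- data.frame(snp_id = colnames(g), chrom = rep(c("c1", "c2"), each = 10),
                    pos_cM = rep(1:10, 2))
  mk <- marker_matrix(g, map)
  y <- stats::setNames(rnorm(n) + 0.8 * g[, 5], rownames(g))
  z <- center_markers(mk)
  loco <- list(c1 = loco_g(z, "c1"), c2 = loco_g(z, "c2"))
  se2 <- 1.3
  vcs <- lapply(loco, function(G)
    list(variances = c(G = 0, residual = se2)))
  fr <- model_frame(y, kernels = list(G = loco$c1))
  res <- single_marker_scan(fr, mk, loco, vc_list = vcs)

  expect_true(res$untestable[1])
  expect_true(is.na(res$effect[1]))

  # oracle: weighted regression by direct matrix algebra (V = se2 * I)
  X <- fr$X
  for (j in c(2, 5, 17)) {
    w <- g[, j]
    XX <- cbind(X, w)
    k <- ncol(XX)
    cf <- solve(crossprod(XX), crossprod(XX, y))
    a <- cf[k]
    cov_a <- se2 * solve(crossprod(XX))[k, k]
    expect_equal(res$effect[j], unname(a), tolerance = 1e-8)
    expect_equal(res$se[j], sqrt(cov_a), tolerance = 1e-8)
    expect_equal(res$chi2[j], unname(a^2 / cov_a), tolerance = 1e-8)
  }

  # allele-label swap flips the effect and leaves p unchanged
  g2 <- g; g2[, 5] <- -g2[, 5]
  mk2 <- marker_matrix(g2, map)
  res2 <- single_marker_scan(fr, mk2, loco, vc_list = vcs)
  expect_equal(res2$effect[5], -res$effect[5], tolerance = 1e-10)
  expect_equal(res2$p_raw[5], res$p_raw[5], tolerance = 1e-12)
})

test_that("genomic control matches its definition and is scale-equivariant", {
  m0 <- qchisq(0.5, df = 1)
  gc1 <- genomic_control(rep(m0, 100))
  expect_equal(gc1$lambda, 1)
  expect_equal(gc1$p, rep(0.5, 100))

  set.seed(1)
  chi <- rchisq(500, 1)
  a <- genomic_control(chi)
  b <- genomic_control(2 * chi)
  expect_equal(b$lambda, 2 * a$lambda)
  expect_equal(b$p, a$p, tolerance = 1e-12)

  # Monte-Carlo null: lambda near 1 (averaged over replicates to keep the
  # check inside Monte-Carlo error)
  set.seed(2)
  lam <- mean(replicate(10, genomic_control(rchisq(10000, 1))$lambda))
  expect_lt(abs(lam - 1), 0.03)

  # clamping keeps deflated statistics untouched
  defl <- genomic_control(0.5 * chi, clamp = TRUE)
  expect_equal(defl$chi2, 0.5 * chi)
  expect_error(genomic_control(c(NA_real_, NA_real_)), "finite")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(signif(bonferroni_threshold(0.05, 10802), 2), 4.6e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("explained variance follows 2p(1-p)a^2 / sigma_g2", {
  expect_equal(round(explained_variance(0.28, 0.96, 2.8), 1), 13.3)
  expect_equal(round(explained_variance(0.64, 14.58, 1108.3), 1), 8.8)
  expect_equal(explained_variance(0.4, 0, 5), 0)
  expect_error(explained_variance(0.4, 1, 0), "positive")
  expect_error(explained_variance(0, 1, 1), "p must be")
})

test_that("allele-class means reproduce brute-force group-by results", {
  g <- rbind(L1 = c(1, 1), L2 = c(1, 1), L3 = c(-1, 1),
             L4 = c(-1, -1), L5 = c(0, 1), L6 = c(1, NA))
  colnames(g) <- c("sA", "sB")
  mk <- marker_matrix(g)
  ph <- data.frame(line_id = rownames(g), y = c(2, 4, 6, 8, 10, 12))

  # single SNP, hand case: classes {2,4,12(excl NA at sB? sA only)}...
  s1 <- allele_class_means(ph, mk, "sA")
  expect_equal(s1$mean[s1$sA == "+"], mean(c(2, 4, 12)))
  expect_equal(s1$mean[s1$sA == "-"], mean(c(6, 8)))
  expect_equal(sum(s1$n) + attr(s1, "n_excluded"), 6)

  # two SNPs vs an explicit loop oracle
  s2 <- allele_class_means(ph, mk, c("sA", "sB"))
  keep <- c("L1", "L2", "L3", "L4")
  oracle <- list()
  for (l in keep) {
    key <- paste(ifelse(g[l, ] > 0, "+", "-"), collapse = "/")
    oracle[[key]] <- c(oracle[[key]], ph$y[ph$line_id == l])
  }
  for (i in seq_len(nrow(s2))) {
    key <- paste(s2$sA[i], s2$sB[i], sep = "/")
    expect_equal(s2$mean[i], mean(oracle[[key]]))
    expect_equal(s2$n[i], length(oracle[[key]]))
  }
  expect_equal(attr(s2, "n_excluded"), 2)
  expect_error(allele_class_means(ph, mk, rep("sA", 7)), "at most 6")
})

test_that("LOCO correction preserves the causal signal better than full-G", {
  chi_loco <- chi_full <- numeric(8)
  for (s in 1:8) {
    d <- small_design(n_chr = 3, snps_per_chr = 60, n_lines = 160,
                      n_families = 40)
    arch <- trait_architecture(
      genetic_var = 1, target_h2 = 0.6,
      major_qtl = data.frame(chrom = "chr2", freq = 0.3,
                             effect = qtl_effect_for_ev(0.15, 0.3, 1)))
    co <- simulate_cohort(d, arch, seed = 700 + s)
    y <- stats::setNames(co$phenotypes$y, co$phenotypes$line_id)
    z <- center_markers(co$markers)
    qtl <- co$truth$qtl$snp_id
    j <- match(qtl, co$markers$map$snp_id)

    scan_l <- gwas(y, co$markers, sets = co$phenotypes$set)
    chi_loco[s] <- scan_l$chi2[j]

    # full-G correction of the same SNP
    G <- vanraden_g(z)
    fr <- model_frame(y, kernels = list(G = G), sets = co$phenotypes$set)
    full_gs <- stats::setNames(rep(list(G), 3), paste0("chr", 1:3))
    scan_f <- single_marker_scan(fr, co$markers, full_gs)
    chi_full[s] <- scan_f$chi2[j]
  }
  expect_gt(mean(chi_loco), mean(chi_full))
})

test_that("a strong QTL is detected at the scan minimum p", {
  d <- small_design(n_chr = 3, snps_per_chr = 60, n_lines = 160, n_families = 40)
  arch <- trait_architecture(
    genetic_var = 1, target_h2 = 0.6,
    major_qtl = data.frame(chrom = "chr1", freq = 0.35,
                           effect = qtl_effect_for_ev(0.35, 0.35, 1)))
  co <- simulate_cohort(d, arch, seed = 51)
  y <- stats::setNames(co$phenotypes$y, co$phenotypes$line_id)
  scan <- gwas(y, co$markers, sets = co$phenotypes$set)
  top <- scan$snp_id[which.min(scan$p_raw)]
  j_top <- match(top, co$markers$map$snp_id)
  j_true <- match(co$truth$qtl$snp_id, co$markers$map$snp_id)
  # the top SNP is the causal one or a tight LD neighbor on its chromosome
  expect_equal(scan$chrom[j_top], "chr1")
  expect_lt(abs(co$markers$map$pos_cM[j_top] - co$markers$map$pos_cM[j_true]), 15)
  # positive-allele frequency reported for the trait-increasing allele
  expect_true(all(scan$pos_freq >= 0 & scan$pos_freq <= 1, na.rm = TRUE))
})

test_that("the scan recovers a calibrated QTL's explained variance and finds it", {
  # QTL calibrated so 2p(1-p)a^2 = 0.133 * sigma_g2 at p = 0.28;
  # short-LD mapping world at the stated 600-line scale, 10 seeds
  evs <- top_ok <- sig <- numeric(10)
  for (s in 1:10) {
    d <- breeding_design(
      n_parents = 96, n_shared_parents = 6, set_sizes = c(300, 300),
      n_full_sib_families = 150, ld_block_length = 10,
      chromosomes = data.frame(name = paste0("chr", 1:10), n_snps = 300,
                               length_cM = 160))
    arch <- trait_architecture(
      genetic_var = 2.8, residual_var = 4.6,
      major_qtl = data.frame(chrom = "chr1", freq = 0.28,
                             effect = qtl_effect_for_ev(0.133, 0.28, 2.8)))
    co <- simulate_cohort(d, arch, seed = 6000 + s)
    y <- stats::setNames(co$phenotypes$y, co$phenotypes$line_id)
    G <- vanraden_g(center_markers(co$markers))
    vc <- fit_reml(model_frame(y, kernels = list(G = G),
                               sets = co$phenotypes$set))
    scan <- gwas(y, co$markers, sets = co$phenotypes$set)
    j <- match(co$truth$qtl$snp_id, scan$snp_id)
    evs[s] <- explained_variance(scan$pos_freq[j], abs(scan$effect[j]),
                                 vc$variances[1])
    sig[s] <- scan$significant[j]
    top <- which.min(scan$p_raw)
    top_ok[s] <- scan$chrom[top] == "chr1" &&
      abs(co$markers$map$pos_cM[top] - co$markers$map$pos_cM[j]) < 15
  }
  expect_lt(abs(mean(evs) - 13.3), 3)
  # the causal SNP clears Bonferroni and tops the scan in nearly every seed
  expect_gte(sum(sig), 9)
  expect_gte(sum(top_ok), 9)
})
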