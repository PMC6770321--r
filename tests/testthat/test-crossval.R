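test_that("fold plans partition the lines per scheme", {
  lines <- sprintf("L%03d", 1:635)
  loo <- make_folds(lines, "loo")
  expect_length(loo$folds, 635)
  expect_true(all(lengths(loo$folds) == 1))
  expect_setequal(unlist(loo$folds), lines)

  l100 <- sprintf("L%03d", 1:100)
  sets <- rep(c("a", "b"), 50)
  kf <- make_folds(l100, "kfold", sets = sets, k = 5, seed = 1)
  expect_length(kf$folds, 5)
  expect_true(all(lengths(kf$folds) == 20))
  expect_setequal(unlist(kf$folds), l100)
  expect_equal(anyDuplicated(unlist(kf$folds)), 0)
  # stratified: each fold has 10 lines per set
  for (f in kf$folds)
    expect_equal(as.vector(table(sets[match(f, l100)])), c(10, 10))

  ls <- make_folds(l100, "lso", sets = sets)
  expect_length(ls$folds, 2)

  fr <- make_folds(l100, "fraction", fraction = 0.7, seed = 2)
  expect_length(fr$folds[[1]], 30)

  expect_error(make_folds(l100, "kfold", k = 200), "exceeds")
  expect_error(make_folds(l100, "lfo"), "pedigree")
})

test_that("LFO folds merge families sharing a parent", {
  ped <- data.frame(line_id = paste0("L", 1:8),
                    parent1 = c("P1", "P1", "P2", "P2", "P3", "P3", "P4", "P4"),
                    parent2 = c("P5", "P5", "P5", "P5", "P6", "P6", "P7", "P7"))
  plan <- make_folds(ped$line_id, "lfo", pedigree = ped)
  # families (P1,P5) and (P2,P5) share P5: one cluster of lines L1-L4
  sizes <- sort(lengths(plan$folds))
  expect_equal(sizes, c(2, 2, 4))
  big <- plan$folds[[which(lengths(plan$folds) == 4)]]
  expect_setequal(big, paste0("L", 1:4))
})

test_that("predictive ability and bias follow their closed forms", {
  x <- c(1.2, -0.5, 0.3, 2.2, -1.7)
  expect_equal(predictive_ability(x, x), 1)
  expect_equal(predictive_ability(x, -x), -1)

  # hand fixture vs the textbook correlation formula written out
  g <- c(0.4, -0.2, 0.1, 1.5, -1.2)
  r_hand <- sum((x - mean(x)) * (g - mean(g))) /
    sqrt(sum((x - mean(x))^2) * sum((g - mean(g))^2))
  expect_equal(predictive_ability(x, g), r_hand)
  expect_error(predictive_ability(x, rep(1, 5)), "constant")

  # noise-free fixtures trigger lm's perfect-fit warning by construction
  b0 <- suppressWarnings(bias(x, x))
  expect_equal(b0$slope, 1)
  expect_equal(b0$bias, 0)
  b2 <- suppressWarnings(bias(x, 0.5 * x))
  expect_equal(b2$slope, 2)
  expect_equal(b2$bias, 1)
  expect_error(bias(x, rep(0, 5)), "zero-variance")

  # r is invariant to affine GEBV rescaling; the slope is not
  expect_equal(predictive_ability(x, 3 * g + 2), predictive_ability(x, g))
  expect_false(isTRUE(all.equal(bias(x, 3 * g + 2)$slope, bias(x, g)$slope)))
})

test_that("run_cv audits folds and handles degenerate plans", {
  co <- small_qtl_cohort()
  plan <- make_folds(names(co$y), "kfold", sets = co$phenotypes$set, k = 4,
                     seed = 3)
  res <- run_cv(co$y, plan, model = "gblup", kernels = list(G = co$G),
                sets = co$phenotypes$set)
  # every line validated exactly once, in its planned fold
  expect_setequal(res$per_line$line_id, names(co$y))
  expect_equal(anyDuplicated(res$per_line$line_id), 0)
  for (i in seq_len(nrow(res$per_line)))
    expect_true(res$per_line$line_id[i] %in% plan$folds[[res$per_line$fold[i]]])
  expect_true(res$r > 0 && res$r <= 1)
  expect_equal(sort(unique(res$n_train)),
               length(co$y) - unname(lengths(plan$folds)[1]))

  # an all-training plan yields an empty result with a warning
  empty_plan <- structure(list(scheme = "fraction",
                               folds = list(character(0)),
                               lines = names(co$y)), class = "fold_plan")
  expect_warning(res0 <- run_cv(co$y, empty_plan, model = "gblup",
                                kernels = list(G = co$G), vc = res$vc),
                 "no validated lines")
  expect_true(is.na(res0$r))
})

test_that("per-fold REML refit runs and changes the fold fits", {
  co <- small_qtl_cohort()
  plan <- make_folds(names(co$y), "kfold", sets = co$phenotypes$set, k = 2,
                     seed = 9)
  r1 <- run_cv(co$y, plan, kernels = list(G = co$G), sets = co$phenotypes$set)
  r2 <- run_cv(co$y, plan, kernels = list(G = co$G), sets = co$phenotypes$set,
               refit_per_fold = TRUE)
  expect_true(is.finite(r2$r))
  # per-fold components differ from the shared full-data fit
  expect_false(isTRUE(all.equal(r1$per_line$gebv, r2$per_line$gebv)))
})

test_that("training-fraction curve reports means, SDs and skips tiny folds", {
  co <- small_qtl_cohort()
  curve <- training_fraction_curve(co$y, co$G, sets = co$phenotypes$set,
                                   fractions = c(0.3, 0.8), reps = 5, seed = 4)
  expect_equal(curve$fraction, c(0.3, 0.8))
  expect_true(all(is.finite(curve$mean_r)))
  expect_true(all(curve$reps == 5))
  expect_warning(
    training_fraction_curve(co$y, co$G, fractions = c(0.05), reps = 2, seed = 1,
                            min_train = 10),
    "skipped")
  # fixed seed reproducibility
  c2 <- training_fraction_curve(co$y, co$G, sets = co$phenotypes$set,
                                fractions = c(0.8), reps = 2, seed = 4)
  c3 <- training_fraction_curve(co$y, co$G, sets = co$phenotypes$set,
                                fractions = c(0.8), reps = 2, seed = 4)
  expect_identical(c2$mean_r, c3$mean_r)
})

test_that("feature CV at threshold = all SNPs reduces to single-kernel GBLUP", {
  d <- small_design(n_chr = 4, snps_per_chr = 50, n_lines = 80, n_families = 20)
  arch <- trait_architecture(genetic_var = 1, target_h2 = 0.6,
                             major_qtl = data.frame(chrom = "chr1", freq = 0.3,
                                                    effect = qtl_effect_for_ev(0.2, 0.3, 1)))
  co <- simulate_cohort(d, arch, seed = 15)
  y <- stats::setNames(co$phenotypes$y, co$phenotypes$line_id)
  m <- ncol(co$markers$geno)
  fcv <- genomic_feature_cv(co$markers, y, sets = co$phenotypes$set,
                            thresholds = c(10, m), seed = 6)
  expect_equal(nrow(fcv), 2)

  # recompute the single-kernel GBLUP LOO on the prediction half directly
  B <- attr(fcv, "split")$prediction_half
  setsB <- co$phenotypes$set[match(B, co$phenotypes$line_id)]
  GB <- vanraden_g(center_markers(subset_markers(co$markers, lines = B)))
  plan <- make_folds(B, "loo")
  ref <- run_cv(y[B], plan, model = "gblup", kernels = list(G = GB), sets = setsB)
  expect_equal(fcv$r[fcv$threshold == m], ref$r, tolerance = 1e-6)
})

test_that("powerlasso cross-validation runs through the same engine", {
  co <- small_qtl_cohort()
  W <- dosage012(co$markers)
  plan <- make_folds(names(co$y), "kfold", sets = co$phenotypes$set, k = 2,
                     seed = 13)
  res <- suppressWarnings(
    run_cv(co$y, plan, model = "powerlasso", W = W, sets = co$phenotypes$set,
           pl_config = power_lasso_config(beta = 1, chain = 1500, burnin = 500,
                                          seed = 13, store_u = FALSE)))
  expect_setequal(res$per_line$line_id, names(co$y))
  expect_true(is.finite(res$r))
})

test_that("Power Lasso LOO prediction lands in the GBLUP accuracy range", {
  # The source-scale claim (Power Lasso within 0.02 of GBLUP, mean over 10
  # seeds) needs production chain lengths and cohort size; at test budgets
  # the MCMC noise exceeds that margin (see the decisions ledger). Here the
  # engine-level property is asserted: the whole-genome regression GEBVs
  # carry most of the predictive signal GBLUP finds.
  rs <- vapply(1:3, function(s) {
    d <- small_design(n_chr = 4, snps_per_chr = 75, n_lines = 120,
                      n_families = 30)
    arch <- trait_architecture(
      genetic_var = 1, target_h2 = 0.7,
      major_qtl = data.frame(chrom = paste0("chr", 1:4),
                             freq = c(0.3, 0.4, 0.25, 0.5),
                             effect = vapply(c(0.12, 0.1, 0.08, 0.06),
                                             qtl_effect_for_ev, 0,
                                             p = 0.35, sigma_g2 = 1)))
    co <- simulate_cohort(d, arch, seed = 4000 + s)
    y <- stats::setNames(co$phenotypes$y, co$phenotypes$line_id)
    G <- vanraden_g(center_markers(co$markers))
    vc <- fit_reml(model_frame(y, kernels = list(G = G),
                               sets = co$phenotypes$set))
    plan <- make_folds(names(y), "loo")
    rg <- run_cv(y, plan, kernels = list(G = G), sets = co$phenotypes$set,
                 vc = vc)$r
    W <- dosage012(co$markers)
    rp <- suppressWarnings(
      run_cv(y, plan, model = "powerlasso", W = W, sets = co$phenotypes$set,
             pl_config = power_lasso_config(beta = 1, chain = 3000,
                                            burnin = 1000, seed = 4000 + s,
                                            store_u = FALSE))$r)
    c(rg, rp)
  }, numeric(2))
  expect_true(all(rs[2, ] > 0))
  expect_gte(mean(rs[2, ]), 0.8 * mean(rs[1, ]))
})
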