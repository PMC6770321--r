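# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# compact breeding design for unit tests
small_design <- function(n_chr = 4L, snps_per_chr = 75L, n_lines = 120L,
                         n_parents = 24L, n_families = 30L, length_cM = 120,
                         ...) {
  # module tests pin a short-LD world so mapping-resolution checks stay sharp
  breeding_design(
    n_parents = n_parents, n_shared_parents = 2L,
    set_sizes = c(ceiling(n_lines / 2), floor(n_lines / 2)),
    n_full_sib_families = n_families,
    chromosomes = data.frame(name = paste0("chr", seq_len(n_chr)),
                             n_snps = snps_per_chr, length_cM = length_cM),
    half_sib_target = 30, ld_block_length = 10, ...
  )
}

# one shared small cohort with a single major QTL (EV ~13%) for reuse
small_qtl_cohort <- function() cached("small_qtl", function() {
  d <- small_design()
  arch <- trait_architecture(
    genetic_var = 2.8, residual_var = 4.6,
    major_qtl = data.frame(chrom = "chr1", freq = 0.28,
                           effect = qtl_effect_for_ev(0.133, 0.28, 2.8)))
  co <- simulate_cohort(d, arch, seed = 11)
  co$y <- stats::setNames(co$phenotypes$y, co$phenotypes$line_id)
  co$z <- center_markers(co$markers)
  co$G <- vanraden_g(co$z)
  co
})

# tiny hand marker fixture: 4 lines x 3 SNPs, complete calls
hand_markers <- function() {
  g <- rbind(L1 = c(1, -1, 1),
             L2 = c(-1, 1, 1),
             L3 = c(1, 1, -1),
             L4 = c(-1, -1, -1))
  colnames(g) <- c("s1", "s2", "s3")
  marker_matrix(g, data.frame(snp_id = c("s1", "s2", "s3"),
                              chrom = c("c1", "c1", "c2"),
                              pos_cM = c(10, 50, 20)))
}

# independent dense REML log-likelihood (oracle; no shortcuts shared with
# the package implementation)
reml_ll_oracle <- function(y, X, G, sg2, se2, ridge = 1e-6) {
  V <- sg2 * (G + diag(ridge, nrow(G))) + se2 * diag(nrow(G))
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(B) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(B)$modulus +
                       t(y) %*% P %*% y))
}

# independent scale-mixture Bayesian Lasso Gibbs sampler in plain R
# (block-update parameterization, used as the beta = 1 oracle)
bayesian_lasso_oracle <- function(y, X, W, chain, burnin, seed,
                                  lambda_fixed = NA) {
  set.seed(seed)
  n <- length(y); p <- ncol(X); m <- ncol(W)
  b <- rep(0, p); u <- rep(0, m); tau2 <- rep(1, m)
  sigma_e2 <- stats::var(y); lambda <- if (is.na(lambda_fixed)) 1 else lambda_fixed
  XtX <- crossprod(X)
  u_acc <- matrix(0, chain - burnin, m)
  for (it in seq_len(chain)) {
    # b | rest (flat prior), joint draw
    rb <- y - W %*% u
    bhat <- solve(XtX, crossprod(X, rb))
    b <- as.numeric(bhat + t(chol(solve(XtX) * sigma_e2)) %*% rnorm(p))
    # u | rest: joint multivariate normal via full system solve
    ru <- as.numeric(y - X %*% b)
    A <- crossprod(W) / sigma_e2 + diag(1 / tau2, m)
    cA <- chol(A)
    mu <- backsolve(cA, forwardsolve(t(cA), crossprod(W, ru) / sigma_e2))
    u <- as.numeric(mu + backsolve(cA, rnorm(m)))
    # lambda | u (marginal over tau2): Gamma(m + 1, sum |u|)
    if (is.na(lambda_fixed))
      lambda <- rgamma(1, m + 1, rate = max(sum(abs(u)), 1e-12))
    # tau2 | u, lambda: inverse-Gaussian for 1/tau2
    au <- pmax(abs(u), 1e-10)
    mu_ig <- lambda / au
    nu <- rnorm(m)^2
    x1 <- mu_ig + mu_ig^2 * nu / (2 * lambda^2) -
      mu_ig / (2 * lambda^2) * sqrt(4 * mu_ig * lambda^2 * nu + mu_ig^2 * nu^2)
    x1[x1 <= 0] <- 1e-12
    use1 <- runif(m) <= mu_ig / (mu_ig + x1)
    eta <- ifelse(use1, x1, mu_ig^2 / x1)
    tau2 <- 1 / pmax(eta, 1e-12)
    # sigma_e2 | rest, flat prior
    rr <- sum((y - X %*% b - W %*% u)^2)
    sigma_e2 <- 1 / rgamma(1, max(n / 2 - 1, 0.5), rate = rr / 2)
    if (it > burnin) u_acc[it - burnin, ] <- u
  }
  u_acc
}

# Monte-Carlo standard error of a chain mean through the package's ESS
mcse <- function(draws) {
  apply(draws, 2, function(x) {
    e <- max(effective_size(x), 5)
    stats::sd(x) / sqrt(e)
  })
}
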