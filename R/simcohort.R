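#' Breeding-cohort design
#'
#' Describes the crossing and inbreeding structure of a synthetic breeding
#' cohort: a pool of crossing parents (some shared between two breeding
#' sets/years), full-sib families derived from bi-parental crosses, and
#' single-seed-descent selfing down to an advanced inbred generation
#' (`selfing_generations = 5` corresponds to F6 lines). Defaults mirror a
#' two-cycle winter wheat programme: 635 lines in sets of 321 and 314 from
#' 159 full-sib families, 96 parents with 6 used in both sets, and ~10.8k
#' mapped SNPs spread over 21 chromosomes.
#'
#' @param n_parents number of crossing parents.
#' @param n_shared_parents parents used in both breeding sets.
#' @param set_sizes integer vector of lines per breeding set.
#' @param n_full_sib_families number of bi-parental families; family sizes are
#'   as equal as the totals allow.
#' @param selfing_generations rounds of selfing after the F1 (5 gives F6).
#' @param chromosomes data.frame with columns `name`, `n_snps`, `length_cM`.
#'   If `NULL`, `n_snps` markers are spread evenly over 21 chromosomes of
#'   160 cM each.
#' @param n_snps total SNP count (used only when `chromosomes` is `NULL`).
#' @param founder_maf_range numeric interval in (0, 0.5]; realized founder
#'   allele frequencies are forced inside it.
#' @param ld_block_length expected ancestral-haplotype block length in cM;
#'   controls how fast founder LD decays with map distance.
#' @param half_sib_target target average half-sib family size (lines sharing
#'   at least one parent). Each set's parents are grouped into crossing
#'   clusters (emulating hub-parent usage) sized so the connected
#'   shared-parent clusters average about this many lines; crosses stay
#'   within a cluster.
#' @return an object of class `breeding_design`.
#' @export
breeding_design <- function(n_parents = 96L, n_shared_parents = 6L,
                            set_sizes = c(321L, 314L),
                            n_full_sib_families = 159L,
                            selfing_generations = 5L,
                            chromosomes = NULL, n_snps = 10802L,
                            founder_maf_range = c(0.05, 0.5),
                            ld_block_length = 80,
                            half_sib_target = 46) {
  if (is.null(chromosomes)) {
    nchr <- 21L
    base <- n_snps %/% nchr
    extra <- n_snps %% nchr
    chromosomes <- data.frame(
      name = paste0(rep(1:7, each = 3L), rep(c("A", "B", "D"), 7L)),
      n_snps = base + c(rep(1L, extra), rep(0L, nchr - extra)),
      length_cM = 160,
      stringsAsFactors = FALSE
    )
  }
  chromosomes <- as.data.frame(chromosomes)
  stopifnot(all(c("name", "n_snps", "length_cM") %in% names(chromosomes)))
  d <- structure(list(
    n_parents = as.integer(n_parents),
    n_shared_parents = as.integer(n_shared_parents),
    set_sizes = as.integer(set_sizes),
    n_full_sib_families = as.integer(n_full_sib_families),
    selfing_generations = as.integer(selfing_generations),
    chromosomes = chromosomes,
    n_snps = sum(chromosomes$n_snps),
    founder_maf_range = as.numeric(founder_maf_range),
    ld_block_length = as.numeric(ld_block_length),
    half_sib_target = as.numeric(half_sib_target)
  ), class = "breeding_design")
  validate_design(d)
  d
}

validate_design <- function(d) {
  if (d$selfing_generations < 0L) stop("selfing_generations must be >= 0")
  if (d$n_shared_parents > d$n_parents) stop("shared parents exceed parent pool")
  if (d$n_full_sib_families > sum(d$set_sizes))
    stop("more families than lines")
  r <- d$founder_maf_range
  if (length(r) != 2L || r[1] > r[2] || r[1] <= 0 || r[2] > 0.5)
    stop("founder_maf_range must be an interval within (0, 0.5]")
  if (any(d$chromosomes$n_snps < 1L)) stop("every chromosome needs >= 1 SNP")
  if (anyDuplicated(d$chromosomes$name)) stop("duplicated chromosome names")
  invisible(d)
}

design_map <- function(design) {
  chr <- design$chromosomes
  data.frame(
    snp_id = paste0("SNP_", seq_len(sum(chr$n_snps))),
    chrom = rep(chr$name, chr$n_snps),
    pos_cM = unlist(lapply(seq_len(nrow(chr)), function(i) {
      n <- chr$n_snps[i]
      (seq_len(n) - 0.5) * chr$length_cM[i] / n
    }), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulate founder haplotypes
#'
#' Founder haplotypes are mosaics over a small pool of ancestral haplotypes;
#' the mosaic switch rate is one switch per `ld_block_length` cM, so linkage
#' disequilibrium among founders decays with map distance (exercising the
#' leave-one-chromosome-out machinery downstream). Realized allele counts are
#' clamped into `founder_maf_range` by flipping the minimal number of
#' haplotype alleles.
#'
#' @param design a [breeding_design()].
#' @param seed integer seed; identical `(design, seed)` give identical output.
#' @param n_ancestral size of the ancestral haplotype pool.
#' @return a `founder_set`: list with `haplotypes` (2 per founder, rows) and
#'   the SNP `map`.
#' @export
simulate_founders <- function(design, seed, n_ancestral = 8L) {
  validate_design(design)
  set.seed(as.integer(seed))
  map <- design_map(design)
  m <- nrow(map)
  nh <- 2L * design$n_parents

  p_target <- stats::runif(m, design$founder_maf_range[1], design$founder_maf_range[2])
  anc <- matrix(stats::rbinom(n_ancestral * m, 1L, rep(p_target, each = n_ancestral)),
                nrow = n_ancestral, ncol = m)

  # per-SNP mosaic switch probability from the gap to the previous SNP
  gap <- c(Inf, diff(map$pos_cM))
  gap[c(TRUE, map$chrom[-1] != map$chrom[-m])] <- Inf  # chromosome starts
  p_switch <- 1 - exp(-pmin(gap, 1e6) / design$ld_block_length)

  H <- matrix(0L, nrow = nh, ncol = m)
  for (h in seq_len(nh)) {
    switches <- stats::runif(m) < p_switch
    seg <- cumsum(switches) + 1L
    donors <- sample.int(n_ancestral, max(seg), replace = TRUE)
    H[h, ] <- anc[cbind(donors[seg], seq_len(m))]
  }

  # clamp realized founder allele counts into the stated frequency range
  lo <- ceiling(design$founder_maf_range[1] * nh - 1e-9)
  hi <- floor(design$founder_maf_range[2] * nh + 1e-9)
  cnt <- colSums(H)
  for (j in which(cnt < lo | cnt > hi)) {
    if (cnt[j] < lo) {
      pick <- sample(which(H[, j] == 0L), lo - cnt[j])
      H[pick, j] <- 1L
    } else {
      pick <- sample(which(H[, j] == 1L), cnt[j] - hi)
      H[pick, j] <- 0L
    }
  }

  rownames(H) <- paste0("P", rep(seq_len(design$n_parents), each = 2L),
                        "_h", rep(1:2, design$n_parents))
  colnames(H) <- map$snp_id
  structure(list(haplotypes = H, map = map, design = design),
            class = "founder_set")
}

# family plan: assign families to sets, sizes as equal as possible, and draw
# two distinct parents per family from one of the set's crossing clusters.
# Parents are grouped into clusters so the shared-parent connected components
# (the half-sib families of the LFO scheme) average half_sib_target lines;
# the parents shared between sets all sit in each set's first cluster, so at
# most those two clusters merge across sets.
plan_families <- function(design) {
  nset <- length(design$set_sizes)
  total <- sum(design$set_sizes)
  fam_per_set <- round(design$n_full_sib_families * design$set_sizes / total)
  fam_per_set[nset] <- design$n_full_sib_families - sum(fam_per_set[-nset])
  if (any(fam_per_set < 1L)) stop("family plan leaves a set without families")

  shared <- seq_len(design$n_shared_parents)
  rest <- setdiff(seq_len(design$n_parents), shared)
  npool <- floor(length(rest) / nset)
  pools <- lapply(seq_len(nset), function(s) {
    own <- rest[seq.int((s - 1L) * npool + 1L,
                        if (s == nset) length(rest) else s * npool)]
    list(shared = shared, own = own)
  })

  fam <- 0L
  plans <- list()
  for (s in seq_len(nset)) {
    nf <- fam_per_set[s]
    sizes <- rep(design$set_sizes[s] %/% nf, nf)
    extra <- design$set_sizes[s] %% nf
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

    n_clust <- max(1L, min(round(design$set_sizes[s] / design$half_sib_target),
                           floor(length(pools[[s]]$own) / 2), nf))
    own <- sample(pools[[s]]$own)
    clusters <- split(own, rep_len(seq_len(n_clust), length(own)))
    clusters[[1]] <- c(pools[[s]]$shared, clusters[[1]])
    fam_cluster <- rep_len(seq_len(n_clust), nf)
    for (f in seq_len(nf)) {
      fam <- fam + 1L
      par <- sample(clusters[[fam_cluster[f]]], 2L)
      plans[[fam]] <- list(family = fam, set = s, size = sizes[f],
                           parent1 = par[1], parent2 = par[2])
    }
  }
  plans
}

#' Simulate F-lines by single-seed descent
#'
#' Each line descends from its own meiosis of the two family parents (an F1
#' gamete pair) followed by `selfing_generations` rounds of selfing without
#' selection; recombination follows the Haldane map function with no
#' interference. Half-sib structure arises from parent reuse across families.
#'
#' @param founders a `founder_set` from [simulate_founders()].
#' @param design the matching [breeding_design()].
#' @param seed integer seed.
#' @param missing_rate proportion of genotype calls masked at random
#'   (default 1\%), to exercise QC; set 0 for complete data.
#' @param error_rate proportion of genotype calls replaced by a random
#'   homozygote (default 0).
#' @return list with `markers` (a [marker_matrix()], codes -1/0/+1) and
#'   `pedigree` (line_id, family, parent1, parent2, set).
#' @export
simulate_cross_ssd <- function(founders, design, seed,
                               missing_rate = 0.01, error_rate = 0) {
  stopifnot(inherits(founders, "founder_set"))
  set.seed(as.integer(seed))
  map <- founders$map
  H <- founders$haplotypes
  chr <- design$chromosomes
  chr_start <- cumsum(c(0L, chr$n_snps[-nrow(chr)]))
  plan <- plan_families(design)

  total <- sum(vapply(plan, function(p) as.integer(p$size), 1L))
  geno <- matrix(0L, nrow = total, ncol = nrow(map))
  ped <- data.frame(line_id = character(total), family = integer(total),
                    parent1 = character(total), parent2 = character(total),
                    set = character(total), stringsAsFactors = FALSE)

  gam <- function(h1, h2) {
    .gamete_cpp(h1, h2, map$pos_cM, chr_start, chr$n_snps, chr$length_cM)
  }

  idx <- 0L
  for (fp in plan) {
    if (fp$parent1 > design$n_parents || fp$parent2 > design$n_parents)
      stop("family plan references unknown parent")
    p1 <- 2L * fp$parent1 - 1L
    p2 <- 2L * fp$parent2 - 1L
    for (l in seq_len(fp$size)) {
      idx <- idx + 1L
      h1 <- gam(H[p1, ], H[p1 + 1L, ])
      h2 <- gam(H[p2, ], H[p2 + 1L, ])
      for (g in seq_len(design$selfing_generations)) {
        n1 <- gam(h1, h2)
        n2 <- gam(h1, h2)
        h1 <- n1; h2 <- n2
      }
      geno[idx, ] <- h1 + h2 - 1L
      ped$line_id[idx] <- sprintf("L%04d", idx)
      ped$family[idx] <- fp$family
      ped$parent1[idx] <- paste0("P", fp$parent1)
      ped$parent2[idx] <- paste0("P", fp$parent2)
      ped$set[idx] <- paste0("set", fp$set)
    }
  }
  rownames(geno) <- ped$line_id
  colnames(geno) <- map$snp_id

  if (error_rate > 0) {
    bad <- which(stats::runif(length(geno)) < error_rate)
    geno[bad] <- sample(c(-1L, 1L), length(bad), replace = TRUE)
  }
  if (missing_rate > 0) {
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  }

  list(markers = marker_matrix(geno, map), pedigree = ped)
}

#' Trait architecture for phenotype simulation
#'
#' The additive-genetic scale is parameterized the way GBLUP reports it:
#' `genetic_var` is the per-unit-relationship variance sigma_g^2, so the
#' realized variance of true breeding values is `d(G) * genetic_var` where
#' `d(G)` is the average diagonal of the VanRaden relationship matrix
#' (about 2 for near-inbred lines). Residual variance is either given
#' directly (`residual_var`) or derived from `target_h2` through
#' h2 = d*sg2 / (d*sg2 + se2), the single-plot genomic heritability.
#'
#' @param genetic_var additive genetic variance sigma_g^2 (trait units^2,
#'   per unit of genomic relationship).
#' @param target_h2 narrow-sense genomic heritability in (0,1); ignored when
#'   `residual_var` is given.
#' @param residual_var residual variance; overrides `target_h2` when set.
#' @param major_qtl data.frame with columns `chrom`, `freq` (target frequency
#'   of the positive allele) and `effect` (additive effect in trait units per
#'   allele copy); may be empty.
#' @param polygenic_snp_fraction fraction of non-QTL SNPs carrying small
#'   normal effects, rescaled so total genetic variance hits the target.
#' @param set_effect_sd SD of the breeding-set (year) effect, a G-by-E proxy.
#' @param trait_mean intercept in trait units.
#' @return an object of class `trait_architecture`.
#' @export
trait_architecture <- function(genetic_var = 2.8, target_h2 = 0.38,
                               residual_var = NULL,
                               major_qtl = NULL,
                               polygenic_snp_fraction = 1,
                               set_effect_sd = 0, trait_mean = 70) {
  if (is.null(major_qtl))
    major_qtl <- data.frame(chrom = character(), freq = numeric(),
                            effect = numeric(), stringsAsFactors = FALSE)
  major_qtl <- as.data.frame(major_qtl)
  if (nrow(major_qtl)) stopifnot(all(c("chrom", "freq", "effect") %in% names(major_qtl)))
  if (is.null(residual_var)) {
    if (is.null(target_h2) || target_h2 <= 0 || target_h2 >= 1) {
      if (!is.null(target_h2) && target_h2 == 0 && nrow(major_qtl))
        stop("target_h2 = 0 is inconsistent with nonzero QTL effects")
      stop("target_h2 must be in (0, 1) unless residual_var is given")
    }
  }
  if (nrow(major_qtl) && any(!is.finite(major_qtl$effect)))
    stop("major QTL effects must be finite")
  if (polygenic_snp_fraction < 0 || polygenic_snp_fraction > 1)
    stop("polygenic_snp_fraction must be in [0, 1]")
  structure(list(genetic_var = genetic_var, target_h2 = target_h2,
                 residual_var = residual_var, major_qtl = major_qtl,
                 polygenic_snp_fraction = polygenic_snp_fraction,
                 set_effect_sd = set_effect_sd, trait_mean = trait_mean),
            class = "trait_architecture")
}

#' Effect size for a target explained-variance fraction
#'
#' Returns the additive effect `a` such that a biallelic SNP at frequency `p`
#' explains fraction `ev` of the additive genetic variance, i.e.
#' 2p(1-p)a^2 = ev * sigma_g2 on the reporting scale where the cohort's
#' average relationship diagonal is `d` (2 for fully inbred lines).
#'
#' @param ev explained-variance fraction in (0,1).
#' @param p allele frequency in (0,1).
#' @param sigma_g2 additive genetic variance.
#' @param d average diagonal of the relationship matrix (default 2, inbred).
#' @export
qtl_effect_for_ev <- function(ev, p, sigma_g2, d = 2) {
  stopifnot(ev > 0, ev < 1, p > 0, p < 1, sigma_g2 > 0)
  sqrt(ev * d * sigma_g2 / (2 * d * p * (1 - p)))
}

#' Simulate phenotypes with ground truth
#'
#' Phenotype = mean + set effect + sum(dosage x effect) + residual. Major QTL
#' are placed on the SNP of the requested chromosome whose realized positive
#' allele frequency is closest to the target; polygenic effects are drawn
#' normal and rescaled so the realized variance of breeding values equals
#' `d(G) * genetic_var` exactly (major-QTL effects are kept at face value).
#'
#' @param markers a [marker_matrix()] (missing codes treated as the SNP mean).
#' @param arch a [trait_architecture()].
#' @param set_assignment factor/character of breeding-set labels per line.
#' @param seed integer seed.
#' @return list with `phenotypes` (line_id, set, y) and `truth`
#'   (class `truth_record`: tbv, snp_effects, qtl table, realized_h2,
#'   realized frequencies, variance components used).
#' @export
simulate_phenotypes <- function(markers, arch, set_assignment, seed) {
  stopifnot(inherits(markers, "marker_matrix"), inherits(arch, "trait_architecture"))
  set.seed(as.integer(seed))
  n <- nrow(markers$geno)
  m <- ncol(markers$geno)
  q <- markers$freq_pos  # frequency of the +1-coded allele
  Wc <- center_dosage(markers)
  denom <- 2 * sum(q * (1 - q))
  d_real <- sum(Wc^2) / n / denom  # average diagonal of the VanRaden G

  sg2 <- arch$genetic_var
  target_var <- d_real * sg2

  eff <- numeric(m)
  qtl_idx <- integer(0)
  qtl_tab <- NULL
  if (nrow(arch$major_qtl)) {
    qtl_tab <- arch$major_qtl
    qtl_tab$snp_id <- NA_character_
    qtl_tab$realized_freq <- NA_real_
    for (i in seq_len(nrow(arch$major_qtl))) {
      ch <- arch$major_qtl$chrom[i]
      on_chr <- setdiff(which(markers$map$chrom == ch), qtl_idx)
      if (!length(on_chr)) stop("no free SNP on chromosome ", ch, " for QTL placement")
      tfreq <- arch$major_qtl$freq[i]
      # the positive allele may be either coding; pick the closer orientation
      dplus <- abs(q[on_chr] - tfreq)
      dminus <- abs((1 - q[on_chr]) - tfreq)
      j <- on_chr[which.min(pmin(dplus, dminus))]
      sign_flip <- dminus[which(on_chr == j)] < dplus[which(on_chr == j)]
      eff[j] <- if (sign_flip) -arch$major_qtl$effect[i] else arch$major_qtl$effect[i]
      qtl_idx <- c(qtl_idx, j)
      qtl_tab$snp_id[i] <- markers$map$snp_id[j]
      qtl_tab$realized_freq[i] <- if (sign_flip) 1 - q[j] else q[j]
    }
  }
  g_major <- as.numeric(Wc[, qtl_idx, drop = FALSE] %*% eff[qtl_idx])
  v_major <- if (n > 1) stats::var(g_major) else 0

  free <- setdiff(seq_len(m), qtl_idx)
  n_poly <- round(arch$polygenic_snp_fraction * length(free))
  if (n_poly > 0 && v_major < target_var) {
    poly_idx <- sample(free, n_poly)
    b0 <- stats::rnorm(n_poly)
    g_poly0 <- as.numeric(Wc[, poly_idx, drop = FALSE] %*% b0)
    vP <- stats::var(g_poly0)
    cPM <- if (length(qtl_idx)) stats::cov(g_poly0, g_major) else 0
    # var(g_major + s*g_poly0) = target_var; positive root
    disc <- cPM^2 - vP * (v_major - target_var)
    s <- if (vP > 0) (-cPM + sqrt(max(disc, 0))) / vP else 0
    eff[poly_idx] <- s * b0
  } else if (v_major > target_var) {
    warning("major QTL variance alone exceeds the genetic-variance target")
  }

  g <- as.numeric(Wc %*% eff)
  v_g <- stats::var(g)

  se2 <- if (!is.null(arch$residual_var)) arch$residual_var else
    target_var * (1 - arch$target_h2) / arch$target_h2

  set_assignment <- as.character(set_assignment)
  stopifnot(length(set_assignment) == n)
  sets <- sort(unique(set_assignment))
  set_eff <- stats::rnorm(length(sets), 0, arch$set_effect_sd)
  names(set_eff) <- sets

  e <- stats::rnorm(n, 0, sqrt(se2))
  y <- arch$trait_mean + set_eff[set_assignment] + g + e

  truth <- structure(list(
    tbv = stats::setNames(g, rownames(markers$geno)),
    snp_effects = stats::setNames(eff, markers$map$snp_id),
    qtl = qtl_tab,
    realized_h2 = if (v_g + stats::var(e) > 0) v_g / (v_g + stats::var(e)) else 0,
    realized_freq = stats::setNames(q, markers$map$snp_id),
    sigma_g2 = sg2, sigma_e2 = se2, d = d_real,
    set_effects = set_eff
  ), class = "truth_record")

  list(
    phenotypes = data.frame(line_id = rownames(markers$geno),
                            set = set_assignment, y = as.numeric(y),
                            stringsAsFactors = FALSE),
    truth = truth
  )
}

#' One-call cohort simulation
#'
#' Convenience wrapper chaining [simulate_founders()], [simulate_cross_ssd()]
#' and [simulate_phenotypes()] with sub-seeds derived from `seed`.
#'
#' @inheritParams simulate_founders
#' @inheritParams simulate_cross_ssd
#' @param arch a [trait_architecture()]; `NULL` skips phenotypes.
#' @return list: `markers`, `pedigree`, `phenotypes`, `truth`, `design`.
#' @export
simulate_cohort <- function(design, arch = NULL, seed = 1L,
                            missing_rate = 0, error_rate = 0) {
  seed <- as.integer(seed)
  fo <- simulate_founders(design, seed)
  cr <- simulate_cross_ssd(fo, design, seed + 1000L,
                           missing_rate = missing_rate, error_rate = error_rate)
  out <- list(markers = cr$markers, pedigree = cr$pedigree, design = design)
  if (!is.null(arch)) {
    ph <- simulate_phenotypes(cr$markers, arch, cr$pedigree$set, seed + 2000L)
    out$phenotypes <- ph$phenotypes
    out$truth <- ph$truth
  }
  out
}
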