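#' Write a genotype matrix and map to tab-delimited files
#'
#' External coding is allele dosage 0/1/2 (`NA` for missing); the internal
#' -1/0/+1 codes are shifted at the boundary. The map file has columns
#' snp_id, chrom, pos_cM.
#'
#' @param markers a [marker_matrix()].
#' @param geno_path,map_path output paths.
#' @export
write_genotypes <- function(markers, geno_path, map_path) {
  stopifnot(inherits(markers, "marker_matrix"))
  g <- markers$geno + 1
  dt <- data.table::data.table(line_id = rownames(g))
  for (j in colnames(g)) dt[[j]] <- g[, j]
  data.table::fwrite(dt, geno_path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(markers$map, map_path, sep = "\t", quote = FALSE)
  invisible(c(geno_path, map_path))
}

#' Read genotypes (tab-delimited matrix or VCF)
#'
#' TSV: rows = lines, first column line ids, remaining columns dosage 0/1/2
#' with `NA` for missing; a 3-column map (snp_id, chrom, pos_cM) assigns
#' chromosomes, and SNPs absent from the map land on pseudo-chromosome
#' `"UN"`. VCF (needs the VariantAnnotation package): unphased diploid GT,
#' 0/0 -> -1, 0/1 -> 0, 1/1 -> +1, ./. -> missing; multi-allelic records are
#' skipped with a message.
#'
#' @param path genotype file.
#' @param map_path map file (TSV format only).
#' @param format `"tsv"` or `"vcf"`.
#' @return a [marker_matrix()].
#' @export
read_genotypes <- function(path, map_path = NULL, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
    ids <- as.character(dt[[1]])
    if (anyDuplicated(ids)) stop("duplicated line id in ", path)
    g <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(g)) stop("non-numeric genotype entries (truncated file?)")
    storage.mode(g) <- "integer"
    rownames(g) <- ids
    map <- if (!is.null(map_path))
      as.data.frame(data.table::fread(map_path, sep = "\t")) else NULL
    marker_matrix(g - 1L, map)
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("VCF input needs the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    multi <- lengths(VariantAnnotation::alt(vcf)) > 1L
    if (any(multi)) {
      message("skipped ", sum(multi), " multi-allelic record(s)")
      vcf <- vcf[!multi]
    }
    gt <- VariantAnnotation::geno(vcf)$GT
    code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    code[gt %in% c("0/0", "0|0")] <- -1L
    code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 0L
    code[gt %in% c("1/1", "1|1")] <- 1L
    g <- t(code)
    if (anyDuplicated(rownames(g))) stop("duplicated line id in ", path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    map <- data.frame(snp_id = rownames(gt),
                      chrom = as.character(GenomeInfoDb::seqnames(rr)),
                      pos_cM = BiocGenerics::start(rr),
                      stringsAsFactors = FALSE)
    marker_matrix(g, map)
  }
}

#' Write a minimal VCF (unphased diploid GT)
#'
#' @param markers a [marker_matrix()]; REF/ALT are placeholders A/B since the
#'   simulator tracks abstract alleles. Positions use the cM map scaled to
#'   integer coordinates.
#' @param path output path.
#' @export
write_vcf <- function(markers, path) {
  stopifnot(inherits(markers, "marker_matrix"))
  g <- markers$geno
  gt <- matrix("./.", ncol(g), nrow(g))
  gt[t(g) == -1] <- "0/0"
  gt[t(g) == 0] <- "0/1"
  gt[t(g) == 1] <- "1/1"
  pos <- markers$map$pos_cM
  pos <- if (all(is.na(pos))) seq_len(ncol(g)) else round(pos * 1e4) + 1
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- paste(markers$map$chrom, pos, markers$map$snp_id, "A", "T", ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a G-matrix as TSV with line-id headers
#' @param g a `g_matrix`; @param path output path.
#' @export
write_gmatrix <- function(g, path) {
  dt <- data.table::data.table(line_id = rownames(g))
  G <- as.matrix(g)
  for (j in seq_len(ncol(G))) dt[[colnames(G)[j]]] <- G[, j]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Phenotype summary table
#'
#' Per trait: mean, min, max and coefficient of variation
#' CV\% = 100 * SD / mean (sample SD, n-1 denominator). Traits with
#' non-positive means get `NA` CV and a degenerate flag.
#'
#' @param phenotypes data.frame of line records.
#' @param traits trait column names (default: all numeric columns except ids).
#' @return data.frame: trait, mean, min, max, cv_pct, degenerate.
#' @export
summarize_phenotypes <- function(phenotypes, traits = NULL) {
  if (is.null(traits))
    traits <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric, TRUE)],
                      c("line_id", "fold"))
  out <- lapply(traits, function(tr) {
    v <- phenotypes[[tr]]
    v <- v[!is.na(v)]
    if (length(v) < 2L) stop("need >= 2 observations for trait ", tr)
    mu <- mean(v)
    cv <- if (mu > 0) 100 * stats::sd(v) / mu else NA_real_
    data.frame(trait = tr, mean = mu, min = min(v), max = max(v),
               cv_pct = cv, degenerate = mu <= 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config needs the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(maf_min = 0.01, max_missing = 0.10, alpha = 0.05,
                   trait = "y", cv_schemes = c("loo", "kfold"), k = 5L,
                   seed = 1L, out_dir = "wheatgp_run")
  config <- utils::modifyList(defaults, config)
  for (p in c("genotypes", "map", "phenotypes")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop("config path does not exist: ", p, " = ", config[[p]])
  }
  if (config$maf_min < 0 || config$maf_min > 1 ||
      config$max_missing < 0 || config$max_missing > 1)
    stop("QC thresholds must lie in [0, 1]")
  config
}

#' Run the full analysis pipeline
#'
#' QC filtering, G-matrix construction (full + LOCO), REML variance
#' components and heritability, the LOCO mixed-model GWAS with genomic
#' control and Bonferroni thresholding, and the requested GBLUP
#' cross-validation schemes; writes result tables and a machine-readable run
#' manifest under `out_dir`.
#'
#' @param config a list or a JSON/YAML path with entries: `genotypes`, `map`,
#'   `phenotypes` (paths), `trait`, QC thresholds `maf_min`/`max_missing`,
#'   `alpha`, `cv_schemes` (subset of loo/lso/kfold), `k`, `seed`, `out_dir`.
#' @return (invisibly) list of in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  log_stage("read", "genotypes=%s", config$genotypes)
  raw <- read_genotypes(config$genotypes, config$map)
  ph <- as.data.frame(data.table::fread(config$phenotypes))
  stopifnot(all(c("line_id", config$trait) %in% names(ph)))
  y <- stats::setNames(ph[[config$trait]], ph$line_id)
  y <- y[!is.na(y)]
  sets <- if ("set" %in% names(ph)) ph$set[match(names(y), ph$line_id)]

  log_stage("qc", "maf>%g, missing<%g on %d SNPs", config$maf_min,
            config$max_missing, ncol(raw$geno))
  mk <- filter_markers(raw, config$maf_min, config$max_missing)
  mk <- subset_markers(mk, lines = names(y))
  z <- center_markers(mk)
  G <- vanraden_g(z)
  write_gmatrix(G, file.path(config$out_dir, "gmatrix_full.tsv"))

  log_stage("reml", "n=%d lines, %d SNPs", length(y), ncol(mk$geno))
  frame <- model_frame(y, kernels = list(G = G), sets = sets)
  vc <- fit_reml(frame)
  h2 <- heritability(vc, G)
  vcs <- data.frame(component = names(vc$variances),
                    variance = as.numeric(vc$variances),
                    se = as.numeric(vc$se))
  data.table::fwrite(vcs, file.path(config$out_dir, "variance_components.csv"))

  log_stage("gwas", "LOCO scan, alpha=%g", config$alpha)
  scan <- gwas(y, mk, sets = sets, alpha = config$alpha)
  data.table::fwrite(as.data.frame(scan),
                     file.path(config$out_dir, "gwas.tsv"), sep = "\t")
  manh <- data.frame(chrom = scan$chrom,
                     index = seq_len(nrow(scan)),
                     neglog10_p = -log10(scan$p_gc))
  data.table::fwrite(manh, file.path(config$out_dir, "manhattan.tsv"), sep = "\t")

  cv_out <- list()
  for (sc in config$cv_schemes) {
    log_stage("cv", "scheme=%s", sc)
    plan <- make_folds(names(y), scheme = sc, sets = sets,
                       k = config$k, seed = config$seed)
    res <- run_cv(y, plan, model = "gblup", kernels = list(G = G),
                  sets = sets, vc = vc)
    cv_out[[sc]] <- list(r = res$r, slope = res$slope, bias = res$bias)
    data.table::fwrite(res$per_line,
                       file.path(config$out_dir, paste0("gebv_", sc, ".csv")))
  }

  manifest <- list(
    package = "wheatgp",
    version = as.character(utils::packageVersion("wheatgp")),
    seed = config$seed, parameters = config[setdiff(names(config), "out_dir")],
    n_lines = length(y), n_snps_raw = ncol(raw$geno),
    n_snps_qc = ncol(mk$geno),
    lambda_if = attr(scan, "lambda_if"), h2 = h2,
    cv = cv_out
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(markers = mk, vc = vc, h2 = h2, gwas = scan, cv = cv_out,
                 manifest = manifest, out_dir = config$out_dir))
}

#' @useDynLib wheatgp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
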