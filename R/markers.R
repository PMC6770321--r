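#' Marker matrix container
#'
#' Genotype codes are -1/0/+1 for the two homozygotes and the heterozygote
#' (near-inbred lines make heterozygotes rare but nonzero); missing calls are
#' `NA`. Allele frequencies are computed from non-missing calls: `freq_pos`
#' is the frequency of the +1-coded allele (the centering frequency, VanRaden
#' convention) and `maf = min(freq_pos, 1 - freq_pos)`.
#'
#' @param geno integer/numeric matrix, lines x SNPs, codes -1/0/+1/NA, with
#'   row and column names.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_cM`; SNPs absent
#'   from the map are assigned pseudo-chromosome `"UN"`.
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(geno, map = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) && nrow(geno))
    rownames(geno) <- paste0("L", seq_len(nrow(geno)))
  if (is.null(colnames(geno)) && ncol(geno))
    colnames(geno) <- paste0("SNP_", seq_len(ncol(geno)))
  if (anyDuplicated(rownames(geno))) stop("duplicated line ids")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(-1, 0, 1)))
    stop("genotype codes must be -1, 0, +1 or NA")

  ids <- colnames(geno)
  if (is.null(map)) {
    map <- data.frame(snp_id = ids, chrom = rep("UN", length(ids)),
                      pos_cM = rep(NA_real_, length(ids)),
                      stringsAsFactors = FALSE)
  } else {
    map <- as.data.frame(map)
    stopifnot(all(c("snp_id", "chrom") %in% names(map)))
    if (!"pos_cM" %in% names(map)) map$pos_cM <- NA_real_
    mi <- match(ids, map$snp_id)
    map <- data.frame(snp_id = ids,
                      chrom = ifelse(is.na(mi), "UN", as.character(map$chrom)[mi]),
                      pos_cM = ifelse(is.na(mi), NA_real_, map$pos_cM[mi]),
                      stringsAsFactors = FALSE)
    if (!length(ids)) map <- map[0, ]
  }

  nonmiss <- colSums(!is.na(geno))
  freq_pos <- (colSums(geno == 1, na.rm = TRUE) +
                 0.5 * colSums(geno == 0, na.rm = TRUE)) / pmax(nonmiss, 1)
  freq_pos[nonmiss == 0] <- NA_real_

  structure(list(
    geno = geno, map = map,
    freq_pos = stats::setNames(freq_pos, ids),
    maf = stats::setNames(pmin(freq_pos, 1 - freq_pos), ids),
    missing_rate = stats::setNames(1 - nonmiss / nrow(geno), ids)
  ), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$geno), "lines x", ncol(x$geno), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  cat("  median MAF", round(stats::median(x$maf, na.rm = TRUE), 3),
      "| mean missing", round(mean(x$missing_rate), 4), "\n")
  invisible(x)
}

#' Subset a marker matrix by lines and/or SNPs
#' @param x a [marker_matrix()].
#' @param lines,snps character ids or indices; `NULL` keeps all.
#' @export
subset_markers <- function(x, lines = NULL, snps = NULL) {
  stopifnot(inherits(x, "marker_matrix"))
  g <- x$geno
  if (!is.null(lines)) g <- g[lines, , drop = FALSE]
  if (!is.null(snps)) g <- g[, snps, drop = FALSE]
  marker_matrix(g, x$map)
}

#' Marker quality control
#'
#' Retains SNPs with MAF strictly above `maf_min` and missing rate strictly
#' below `max_missing` (both thresholds are exclusive, reading the editing
#' rule "MAF > 1% and missing < 10%" literally). SNP order is preserved. The
#' removal report is attached as attribute `"qc_report"`.
#'
#' @param raw a [marker_matrix()].
#' @param maf_min minimum minor allele frequency (exclusive), default 0.01.
#' @param max_missing maximum missing rate (exclusive), default 0.10.
#' @return filtered [marker_matrix()]; a warning (not an error) if all SNPs
#'   are removed.
#' @export
filter_markers <- function(raw, maf_min = 0.01, max_missing = 0.10) {
  stopifnot(inherits(raw, "marker_matrix"))
  if (ncol(raw$geno) == 0L) stop("empty marker matrix")
  maf <- ifelse(is.na(raw$maf), 0, raw$maf)
  keep <- maf > maf_min & raw$missing_rate < max_missing
  reason <- rep("", length(keep))
  reason[maf <= maf_min] <- "maf"
  reason[raw$missing_rate >= max_missing] <-
    paste0(reason[raw$missing_rate >= max_missing], "+missing")
  report <- data.frame(snp_id = colnames(raw$geno)[!keep],
                       reason = sub("^\\+", "", reason[!keep]),
                       stringsAsFactors = FALSE)
  if (!any(keep)) warning("all SNPs removed by QC filters")
  out <- marker_matrix(raw$geno[, keep, drop = FALSE], raw$map)
  attr(out, "qc_report") <- report
  out
}

# centered dosage with missing set to 0, used by both the G construction and
# the simulator; column i is centered by 2*(freq_pos_i - 0.5)
center_dosage <- function(markers) {
  g <- markers$geno
  P <- matrix(2 * (markers$freq_pos - 0.5), nrow = nrow(g), ncol = ncol(g),
              byrow = TRUE)
  z <- g - P
  z[is.na(g)] <- 0
  dimnames(z) <- dimnames(g)
  z
}

#' Center markers for G-matrix construction
#'
#' Z2 = M - P where column i of P is 2(p_i - 0.5) with p_i the frequency of
#' the +1-coded allele; missing genotypes are set to exactly 0 in Z2. The
#' VanRaden scaling denominator 2*sum p_i (1-p_i) is attached.
#'
#' @param markers a [marker_matrix()].
#' @return object of class `centered_markers` with elements `Z`, `freq`,
#'   `denom`, `map`.
#' @export
center_markers <- function(markers) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (any(markers$missing_rate >= 1))
    stop("SNP(s) with all calls missing: frequency undefined")
  q <- markers$freq_pos
  structure(list(
    Z = center_dosage(markers),
    freq = q,
    denom = 2 * sum(q * (1 - q)),
    map = markers$map
  ), class = "centered_markers")
}

new_g_matrix <- function(G, provenance, n_snps) {
  structure(G, provenance = provenance, n_snps = n_snps,
            d = mean(diag(G)), class = c("g_matrix", "matrix"))
}

#' Average diagonal of a G-matrix
#' @param g a `g_matrix` (or plain square matrix).
#' @export
g_diag_mean <- function(g) {
  d <- attr(g, "d")
  if (is.null(d)) d <- mean(diag(as.matrix(g)))
  d
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' G = Z2 Z2' / (2 * sum p_i(1-p_i)) over the chosen SNPs. When `subset` is
#' given, the scaling denominator is recomputed over that subset so each G is
#' internally VanRaden-consistent.
#'
#' @param z a [center_markers()] result.
#' @param subset optional character vector of SNP ids (or indices).
#' @param provenance provenance tag stored on the result.
#' @return a `g_matrix`: symmetric lines x lines matrix with attributes
#'   `provenance`, `n_snps` and `d` (average diagonal).
#' @export
vanraden_g <- function(z, subset = NULL, provenance = "full") {
  stopifnot(inherits(z, "centered_markers"))
  ids <- colnames(z$Z)
  if (is.null(subset)) {
    cols <- seq_along(ids)
  } else {
    cols <- if (is.character(subset)) match(subset, ids) else as.integer(subset)
    if (!length(cols)) stop("empty SNP subset")
    if (anyNA(cols)) stop("subset contains SNPs absent from the map")
  }
  q <- z$freq[cols]
  denom <- 2 * sum(q * (1 - q))
  if (denom <= 0) stop("subset has zero total heterozygosity 2*sum p(1-p)")
  G <- tcrossprod(z$Z[, cols, drop = FALSE]) / denom
  new_g_matrix(G, provenance, length(cols))
}

#' Leave-one-chromosome-out G-matrix
#'
#' G built from all SNPs except those mapped to `chromosome`; SNPs on
#' pseudo-chromosome `"UN"` (unmapped) are retained unless `"UN"` itself is
#' excluded.
#'
#' @param z a [center_markers()] result.
#' @param chromosome chromosome name to exclude.
#' @export
loco_g <- function(z, chromosome) {
  stopifnot(inherits(z, "centered_markers"))
  if (!chromosome %in% z$map$chrom) stop("unknown chromosome: ", chromosome)
  keep <- which(z$map$chrom != chromosome)
  if (!length(keep)) stop("no SNPs remain after excluding ", chromosome)
  vanraden_g(z, keep, provenance = paste0("loco(", chromosome, ")"))
}

#' Significance-partitioned G-matrices
#'
#' Splits the SNPs into a significant set and its complement and builds one
#' VanRaden G from each (frequencies and denominators per subset).
#'
#' @param z a [center_markers()] result.
#' @param significant_snps nonempty strict subset of SNP ids.
#' @return list with `Gs` (significant) and `Gn` (remainder).
#' @export
partition_g <- function(z, significant_snps) {
  stopifnot(inherits(z, "centered_markers"))
  ids <- colnames(z$Z)
  sig <- unique(as.character(significant_snps))
  if (!length(sig)) stop("significant set is empty")
  if (!all(sig %in% ids)) stop("significant set contains unknown SNPs")
  if (length(sig) >= length(ids)) stop("significant set must be a strict subset")
  rest <- setdiff(ids, sig)
  list(Gs = vanraden_g(z, sig, provenance = "subset(significant)"),
       Gn = vanraden_g(z, rest, provenance = "subset(nonsignificant)"))
}

# small diagonal ridge so duplicated inbred genotypes cannot make V singular
add_ridge <- function(G, ridge = 1e-6) {
  G <- as.matrix(G)
  G + diag(ridge, nrow(G))
}
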