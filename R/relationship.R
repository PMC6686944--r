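#' Genotype quality control
#'
#' Applies the standard chip-QC filters in a fixed, documented order:
#' (1) samples with call rate below `call_rate_min`; then, on the retained
#' samples, SNPs failing (2) call rate, (3) minor allele frequency
#' (`MAF < maf_min`, which also removes monomorphic SNPs), and (4) the
#' Hardy-Weinberg 1-df chi-square goodness-of-fit test at
#' `p < hwe_p_min`.
#'
#' @param geno a [GenotypeData-class].
#' @param hwe_p_min HWE p-value threshold (default `1e-6`).
#' @param maf_min minor-allele-frequency threshold (default `0.05`).
#' @param call_rate_min call-rate threshold for SNPs and samples
#'   (default `0.95`).
#' @return list with elements `genotypes` (filtered [GenotypeData-class])
#'   and `report` (a [QCReport-class]).
#' @examples
#' g <- genotypeData(matrix(c(0, 0, 0, 0, 0, 1, 2, 1), 4,
#'                          dimnames = list(paste0("a", 1:4), NULL)),
#'                   data.frame(snp = c("s1", "s2"), chr = "1",
#'                              pos = c(100, 200)))
#' qcFilter(g)$report  # s1 is monomorphic: removed by the MAF filter
#' @export
qcFilter <- function(geno, hwe_p_min = 1e-6, maf_min = 0.05,
                     call_rate_min = 0.95) {
  d <- geno@dosage
  if (!length(d)) stop("empty genotype matrix")
  sample_cr <- rowMeans(!is.na(d))
  keep_samp <- sample_cr >= call_rate_min
  if (!any(keep_samp)) stop("all samples removed by call-rate filter")
  d2 <- d[keep_samp, , drop = FALSE]

  snp_cr <- colMeans(!is.na(d2))
  fail_cr <- snp_cr < call_rate_min
  p <- colMeans(d2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_maf <- !fail_cr & (is.na(maf) | maf < maf_min)
  hwe_p <- hwePvalue(d2)
  fail_hwe <- !fail_cr & !fail_maf & hwe_p < hwe_p_min
  keep_snp <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep_snp)) stop("all SNPs removed by QC filters")
  report <- new("QCReport",
                n_snps_in = ncol(d), n_samples_in = nrow(d),
                removed = c(samples_callrate = sum(!keep_samp),
                            snp_callrate = sum(fail_cr),
                            snp_maf = sum(fail_maf),
                            snp_hwe = sum(fail_hwe)),
                kept_snps = colnames(d)[keep_snp],
                kept_samples = rownames(d)[keep_samp],
                thresholds = c(hwe_p_min = hwe_p_min, maf_min = maf_min,
                               call_rate_min = call_rate_min))
  list(genotypes = geno[rownames(d)[keep_samp], colnames(d)[keep_snp]],
       report = report)
}

#' Hardy-Weinberg chi-square p-values
#'
#' 1-df goodness-of-fit test of the observed genotype counts against
#' Hardy-Weinberg proportions at the observed allele frequency, per SNP.
#' Monomorphic SNPs get p-value 1.
#'
#' @param d dosage matrix (animals x SNPs) or a [GenotypeData-class].
#' @return numeric vector of p-values.
#' @export
hwePvalue <- function(d) {
  if (is(d, "GenotypeData")) d <- d@dosage
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  stat <- ifelse(p > 0 & p < 1,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2,
                 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Genomic relationship matrix (VanRaden, with SNP weights)
#'
#' `G = Z D Z' / (2 * sum(p_j (1 - p_j)))` with `Z` the dosage matrix
#' centered at twice the observed allele frequencies and `D` the diagonal
#' of per-SNP weights (unit weights give the plain VanRaden method-1
#' matrix). Missing dosages are mean-imputed per SNP before centering.
#' When `A22` is supplied, `G` is first tuned so its mean diagonal and
#' mean off-diagonal match those of `A22` (two-parameter adjustment
#' `a + b G`), then blended as `(1 - blend) G + blend A22` to guarantee
#' invertibility.
#'
#' @param geno a [GenotypeData-class] (post-QC).
#' @param weights per-SNP non-negative weights; default unit. Internally
#'   rescaled to sum to the SNP count.
#' @param A22 pedigree relationship sub-matrix over the same animals (in
#'   the same order), or `NULL` to skip tuning/blending.
#' @param blend proportion of `A22` blended in (default 0.05; 0 disables).
#' @param tune match the means of `G` to `A22` before blending
#'   (default `TRUE`; ignored without `A22`).
#' @return dense symmetric matrix with animal-id dimnames; the allele
#'   frequencies used are attached as `attr(, "p")` and the normalizer as
#'   `attr(, "scale")`.
#' @export
makeG <- function(geno, weights = NULL, A22 = NULL, blend = 0.05,
                  tune = TRUE) {
  d <- geno@dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  if (all(p <= 0 | p >= 1))
    stop("all SNPs are monomorphic; G is undefined")
  if (anyNA(d)) {
    mu <- rep(2 * p, each = nrow(d))
    d[is.na(d)] <- mu[is.na(d)]
  }
  nsnp <- ncol(d)
  if (is.null(weights)) weights <- rep(1, nsnp)
  if (length(weights) != nsnp) stop("one weight per SNP required")
  if (any(weights < 0)) stop("SNP weights must be non-negative")
  if (sum(weights) > 0) weights <- weights * nsnp / sum(weights)
  Z <- sweep(d, 2L, 2 * p)
  k <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z %*% diag(sqrt(weights), nsnp)) / k
  if (!is.null(A22)) {
    A22 <- as.matrix(A22)
    if (!identical(dim(A22), dim(G)))
      stop("A22 must conform to G")
    if (isTRUE(tune)) {
      off <- !diag(nrow(G))
      mdG <- mean(diag(G)); moG <- mean(G[off])
      mdA <- mean(diag(A22)); moA <- mean(A22[off])
      b <- if (abs(mdG - moG) > 1e-12) (mdA - moA) / (mdG - moG) else 1
      a <- mdA - b * mdG
      G <- a + b * G
    }
    if (blend > 0) G <- (1 - blend) * G + blend * A22
  }
  dimnames(G) <- list(rownames(geno@dosage), rownames(geno@dosage))
  attr(G, "p") <- p
  attr(G, "scale") <- k
  G
}

#' Combined relationship inverse for single-step evaluation
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`, with the correction added into
#' the genotyped-by-genotyped block of the pedigree inverse. With no
#' genotyped animals, or with `G = A22`, the result is exactly `A^-1`.
#'
#' @param Ainv pedigree relationship inverse over the full pedigree
#'   (from [makeAInverse()]), with id dimnames.
#' @param Ginv inverse of the (blended) genomic relationship matrix.
#' @param A22inv inverse of the pedigree sub-matrix for the genotyped
#'   animals.
#' @param genotyped_ids ids indexing the genotyped block (row order of
#'   `Ginv`/`A22inv`).
#' @return sparse symmetric `Matrix` over the full pedigree.
#' @export
makeHInverse <- function(Ainv, Ginv, A22inv, genotyped_ids = rownames(Ginv)) {
  H <- as(as(Ainv, "generalMatrix"), "CsparseMatrix")
  if (length(genotyped_ids) == 0L) return(Matrix::forceSymmetric(H))
  if (is.null(rownames(H))) stop("Ainv needs id dimnames")
  idx <- match(genotyped_ids, rownames(H))
  if (anyNA(idx)) stop("genotyped ids missing from Ainv")
  Ginv <- as.matrix(Ginv)
  A22inv <- as.matrix(A22inv)
  if (!identical(dim(Ginv), dim(A22inv)) || length(idx) != nrow(Ginv))
    stop("dimension mismatch between G inverse, A22 inverse and the ",
         "genotyped ids")
  delta <- Ginv - A22inv
  if (!all(is.finite(delta))) stop("non-finite entries in G inverse")
  H[idx, idx] <- H[idx, idx] + delta
  Matrix::forceSymmetric(H)
}
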