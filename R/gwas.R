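#' Back-solve SNP effects from genomic breeding values
#'
#' Converts GEBV of the genotyped animals into per-SNP effects:
#' `u = D M' G*^-1 a / k`, with `M` the dosage matrix centered at twice
#' the observed allele frequencies, `D` the diagonal of (normalized) SNP
#' weights, `k = 2 * sum(p q)` the VanRaden normalizer and `G*` the same
#' blended/tuned weighted genomic matrix the evaluation used. Without
#' blending, `M u` reproduces the GEBV exactly; the default 0.05 blend
#' leaves a small documented discrepancy.
#'
#' @param gebv named GEBV vector of the genotyped animals, or a
#'   [MixedModelFit-class] (its `u` is subset to the genotyped ids).
#' @param geno genotyped-animal [GenotypeData-class] (no missing dosages).
#' @param weights per-SNP weights; default unit.
#' @param A22,blend,tune G-construction options, as in [makeG()]; use
#'   `A22 = NULL` for the raw weighted VanRaden matrix.
#' @param G optionally, the precomputed matrix from [makeG()] (must carry
#'   its `p`/`scale` attributes); overrides the construction options.
#' @return named per-SNP effect vector.
#' @export
backsolveSnpEffects <- function(gebv, geno, weights = NULL, A22 = NULL,
                                blend = 0.05, tune = TRUE, G = NULL) {
  if (is(gebv, "MixedModelFit")) gebv <- gebv@u[rownames(geno@dosage)]
  ids <- rownames(geno@dosage)
  if (!all(ids %in% names(gebv))) stop("GEBV missing for genotyped animals")
  a <- gebv[ids]
  if (is.null(G))
    G <- makeG(geno, weights = weights, A22 = A22, blend = blend,
               tune = tune)
  p <- attr(G, "p"); k <- attr(G, "scale")
  if (is.null(p) || is.null(k)) stop("G must come from makeG()")
  nsnp <- ncol(geno@dosage)
  if (is.null(weights)) weights <- rep(1, nsnp)
  if (sum(weights) > 0) weights <- weights * nsnp / sum(weights)
  Z <- sweep(geno@dosage, 2L, 2 * p)
  ## a G centered at observed frequencies is singular (the ones vector is
  ## in its null space); without blending, invert on the row space
  Ga <- tryCatch(solve(G, a), error = function(e) {
    ev <- eigen(G, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    if (!any(pos)) stop("weighted G has no positive eigenvalues")
    drop(ev$vectors[, pos] %*%
           (crossprod(ev$vectors[, pos], a) / ev$values[pos]))
  })
  setNames(weights * drop(crossprod(Z, Ga)) / k, colnames(geno@dosage))
}

#' Update SNP weights from estimated effects
#'
#' The weighted-ssGBLUP iteration: `d_j = u_j^2 * 2 p_j (1 - p_j)` (the
#' estimated marker variance), then normalized so the weights sum to the
#' SNP count, preserving the trace of the weighted genomic matrix.
#'
#' @param u per-SNP effects.
#' @param p per-SNP allele frequencies.
#' @return named weight vector summing to `length(u)` (all zero, with a
#'   warning, if every effect is zero).
#' @export
updateSnpWeights <- function(u, p) {
  if (length(u) != length(p)) stop("u and p lengths differ")
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  d <- u^2 * 2 * p * (1 - p)
  s <- sum(d)
  if (s > 0) d <- d * length(d) / s
  else warning("all SNP effects are zero; weights left at zero")
  if (!is.null(names(u))) names(d) <- names(u)
  d
}

#' Genetic variance explained by SNP windows
#'
#' Partitions each chromosome's SNPs into consecutive non-overlapping
#' windows of `window_size` (the last window may be shorter) and reports
#' `100 * var(M_w u_w) / var(M u)` over the genotyped animals: the
#' percentage of the genetic variance explained by each window, including
#' within-window LD covariance. `method = "sum"` instead sums per-SNP
#' variances within the window.
#'
#' @param u per-SNP effects (order matching the map).
#' @param geno genotyped-animal [GenotypeData-class] with a position-sorted
#'   map.
#' @param window_size SNPs per window (default 20).
#' @param method `"cov"` (default; includes LD covariance) or `"sum"`.
#' @return data.frame: `chr`, `first_bp`, `last_bp`, `n_snps`,
#'   `length_bp`, `pct_var`, `first_snp`, `last_snp`, sorted by genomic
#'   position.
#' @export
windowVariance <- function(u, geno, window_size = 20L,
                           method = c("cov", "sum")) {
  method <- match.arg(method)
  map <- geno@map
  if (is.unsorted(order(match(map$chr, unique(map$chr)), map$pos)))
    stop("SNP map must be sorted by chromosome and position")
  p <- colMeans(geno@dosage, na.rm = TRUE) / 2
  Z <- sweep(geno@dosage, 2L, 2 * p)
  g_all <- drop(Z %*% u)
  vtot <- var(g_all)
  if (!is.finite(vtot) || vtot <= 0)
    stop("total genetic variance is zero; cannot form window percentages")
  out <- do.call(rbind, lapply(unique(map$chr), function(cc) {
    j <- which(map$chr == cc)
    win <- ceiling(seq_along(j) / window_size)
    do.call(rbind, lapply(split(j, win), function(jj) {
      vw <- if (method == "cov")
        var(drop(Z[, jj, drop = FALSE] %*% u[jj]))
      else sum(apply(Z[, jj, drop = FALSE], 2L, var) * u[jj]^2)
      data.frame(chr = cc, first_bp = map$pos[jj[1L]],
                 last_bp = map$pos[jj[length(jj)]],
                 n_snps = length(jj),
                 length_bp = map$pos[jj[length(jj)]] - map$pos[jj[1L]],
                 pct_var = 100 * vw / vtot,
                 first_snp = map$snp[jj[1L]],
                 last_snp = map$snp[jj[length(jj)]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Weighted single-step GBLUP association analysis
#'
#' Runs the iterative weighted-ssGBLUP scheme: iteration 1 is plain
#' ssGBLUP (unit SNP weights); each further iteration rebuilds the
#' weighted genomic matrix, refits the model, back-solves SNP effects and
#' re-weights each SNP by its estimated variance. Window percentages of
#' genetic variance are reported per iteration; the second iteration is
#' the conventional reporting choice and is flagged.
#'
#' @param ped a [Pedigree-class] (full pedigree).
#' @param geno post-QC [GenotypeData-class] of the genotyped animals.
#' @param phenotypes phenotype data.frame (see [mmeDesign()]).
#' @param trait response column.
#' @param cg,covariate,common_env model structure, as in [mmeDesign()].
#' @param vc variance components ([VarianceComponents-class] or named
#'   vector); estimated once by [remlVC()] under unit weights when `NULL`.
#' @param n_iterations weight iterations (default 3; 1 = ssGBLUP).
#' @param window_size SNPs per window (default 20).
#' @param blend,tune G-construction options (see [makeG()]).
#' @return list with one element per iteration, each holding `weights`,
#'   `fit`, `snp_effects`, `windows`, and `reporting` (`TRUE` on the
#'   default reporting iteration); plus attributes `vc`.
#' @export
runWssGBLUP <- function(ped, geno, phenotypes, trait, cg = "cg",
                        covariate = NULL, common_env = TRUE, vc = NULL,
                        n_iterations = 3L, window_size = 20L,
                        blend = 0.05, tune = TRUE) {
  design <- mmeDesign(phenotypes, trait, ped, cg = cg,
                      covariate = covariate, common_env = common_env)
  gids <- rownames(geno@dosage)
  Ainv <- makeAInverse(ped)
  A22 <- makeA(ped, subset = gids)
  A22inv <- solve(A22)
  nsnp <- ncol(geno@dosage)
  weights <- rep(1, nsnp)
  out <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    G <- makeG(geno, weights = weights, A22 = A22, blend = blend,
               tune = tune)
    Ginv <- solve(G)
    Hinv <- makeHInverse(Ainv, Ginv, A22inv, gids)
    if (it == 1L && is.null(vc))
      vc <- remlVC(design, Hinv)
    fit <- solveMME(design, Hinv, vc, kinship = "H-inverse")
    u_snp <- backsolveSnpEffects(fit, geno, weights = weights, G = G)
    win <- windowVariance(u_snp, geno, window_size = window_size)
    out[[it]] <- list(iteration = it, weights = weights, fit = fit,
                      snp_effects = u_snp, windows = win,
                      reporting = it == min(2L, n_iterations))
    if (it < n_iterations)
      weights <- updateSnpWeights(u_snp, attr(G, "p"))
  }
  attr(out, "vc") <- vc
  out
}

#' Top windows by percentage of genetic variance
#'
#' Orders windows by `pct_var` (descending), breaking ties by genomic
#' order (chromosome, then first bp).
#'
#' @param windows a window table from [windowVariance()].
#' @param k how many windows (default 5).
#' @return the top-`k` rows.
#' @export
topWindows <- function(windows, k = 5L) {
  ord <- order(-windows$pct_var,
               match(windows$chr, unique(windows$chr)), windows$first_bp)
  head(windows[ord, , drop = FALSE], k)
}
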